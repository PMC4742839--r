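#' Metabolic function catalogues
#'
#' A metabolic function is a (target reaction, constraint set) pair: the
#' target is usually the reaction producing the end-product of the function
#' (glucose export for gluconeogenesis, urea export for ureagenesis, a
#' glycogen sink for glycogen synthesis), and the constraints restrict the
#' nutrient environment (e.g. lactate as the only carbon source for
#' gluconeogenesis from lactate). The shipped default catalogue covers 22
#' key liver functions and is an editable YAML file; its constraint sets are
#' written against Recon 1 reaction identifiers.
#'
#' @param id function id.
#' @param target_reaction reaction id whose flux realizes the function.
#' @param constraints [bound_overrides()] data.frame (the constraint set).
#' @param description free-text description.
#' @return `metabolic_function()` returns a list of class
#'   `metabolic_function`; `function_catalogue()` a list of class
#'   `function_catalogue`.
#' @export
metabolic_function <- function(id, target_reaction, constraints = NULL,
                               description = "") {
  if (is.null(constraints)) {
    constraints <- bound_overrides(character(0))
  }
  structure(list(id = id, target_reaction = target_reaction,
                 constraints = constraints, description = description),
            class = "metabolic_function")
}

#' @rdname metabolic_function
#' @param functions list of `metabolic_function` objects.
#' @export
function_catalogue <- function(functions) {
  ids <- vapply(functions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate function ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(functions) <- ids
  structure(functions, class = "function_catalogue")
}

#' @export
print.function_catalogue <- function(x, ...) {
  cat("function_catalogue with", length(x), "metabolic functions\n")
  for (f in x) cat(" -", f$id, "->", f$target_reaction, "\n")
  invisible(x)
}

#' Read / write a function catalogue (YAML)
#'
#' The YAML layout is a top-level `functions` list; each entry has `id`,
#' `description`, `target_reaction` and a `constraints` list of
#' `{reaction, lower, upper}` overrides.
#'
#' @param path YAML file path.
#' @return A `function_catalogue`.
#' @export
read_function_catalogue <- function(path) {
  obj <- yaml::read_yaml(path)
  entries <- obj$functions %||% obj
  funs <- lapply(entries, function(e) {
    cons <- if (length(e$constraints)) {
      do.call(rbind, lapply(e$constraints, function(cc) {
        bound_overrides(cc$reaction,
                        lower = cc$lower %||% NA_real_,
                        upper = cc$upper %||% NA_real_)
      }))
    } else {
      NULL
    }
    metabolic_function(e$id, e$target_reaction, cons,
                       description = e$description %||% "")
  })
  function_catalogue(funs)
}

#' @rdname read_function_catalogue
#' @param catalogue a `function_catalogue`.
#' @export
write_function_catalogue <- function(catalogue, path) {
  entries <- lapply(unclass(catalogue), function(f) {
    cons <- f$constraints
    cons_list <- if (nrow(cons)) {
      lapply(seq_len(nrow(cons)), function(i) {
        e <- list(reaction = cons$reaction[i])
        if (!is.na(cons$lower[i])) e$lower <- cons$lower[i]
        if (!is.na(cons$upper[i])) e$upper <- cons$upper[i]
        e
      })
    } else {
      list()
    }
    list(id = f$id, description = f$description,
         target_reaction = f$target_reaction, constraints = cons_list)
  })
  yaml::write_yaml(list(functions = unname(entries)), path)
  invisible(path)
}

#' The default liver function catalogue
#'
#' 22 key liver metabolic functions (gluconeogenesis from several
#' substrates, glyceroneogenesis, ureagenesis, ketogenesis, bile-acid,
#' glycogen, lipid and amino-acid related functions), shipped as editable
#' YAML with Recon 1-style identifiers.
#'
#' @return A `function_catalogue` with exactly 22 entries.
#' @export
default_function_catalogue <- function() {
  read_function_catalogue(
    system.file("extdata", "liver_function_catalogue.yaml",
                package = "hepaflux", mustWork = TRUE))
}

#' Validate a catalogue against a model
#'
#' Checks that every target reaction and constrained reaction exists and
#' that each constraint set is feasible on the model.
#'
#' @param catalogue a `function_catalogue`.
#' @param model a `metabolic_model`.
#' @return `TRUE` invisibly, or an error naming the offending function.
#' @export
validate_catalogue <- function(catalogue, model) {
  for (f in catalogue) {
    if (!(f$target_reaction %in% model$reactions$id)) {
      stop("function ", f$id, ": target reaction ", f$target_reaction,
           " not in model")
    }
    unknown <- setdiff(f$constraints$reaction, model$reactions$id)
    if (length(unknown)) {
      stop("function ", f$id, ": unknown constrained reaction(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!check_feasibility(model, f$constraints)) {
      stop("function ", f$id, ": constraint set infeasible on the model")
    }
  }
  invisible(TRUE)
}

# internal: tri-states for one expression profile mapped to reactions
profile_reaction_states <- function(model, profile,
                                    settings = imat_settings()) {
  gene_states <- discretize_expression(profile, settings)
  overlap <- intersect(names(gene_states), model$genes)
  if (length(overlap) == 0) {
    stop("expression profile shares no genes with the model")
  }
  suppressWarnings(reaction_expression_states(model, gene_states))
}

#' Activity score of a metabolic function
#'
#' `A_i` is the maximal flux through the target reaction under the
#' function's constraint set `C_i`; `A_ij` is that maximum when, in
#' addition, the flux state must attain the optimal iMAT consistency with
#' sample `j`'s expression. The activity score is `A_ij / A_i`: the fraction
#' of the function's capacity that survives pinning the expression fit at
#' its optimum. Functions whose unconstrained capacity is (numerically)
#' zero are reported as blocked with an `NA` score.
#'
#' @param model a `metabolic_model`.
#' @param fun a `metabolic_function`.
#' @param profile named numeric expression vector (one sample), or a
#'   precomputed named character vector of reaction tri-states (detected by
#'   values in low/moderate/high).
#' @param settings [imat_settings()].
#' @param alpha required fraction of the optimal consistency (default 1:
#'   consistency pinned at optimum).
#' @return List with `score` (`A_ij / A_i`, `NA` if blocked), `A_i`, `A_ij`,
#'   `F` (optimal consistency) and `blocked`.
#' @export
function_activity_score <- function(model, fun, profile,
                                    settings = imat_settings(), alpha = 1) {
  states <- as_reaction_states(model, profile, settings)
  A_i <- maximize_flux(model, fun$target_reaction, fun$constraints)$optimum
  if (A_i <= settings$epsilon * 1e-3) {
    return(list(score = NA_real_, A_i = A_i, A_ij = NA_real_, F = NA_integer_,
                blocked = TRUE))
  }
  fit <- imat_max_consistency(model, states, fun$constraints, settings)
  A_ij <- imat_max_flux_at_consistency(
    model, states, fun$target_reaction,
    min_consistency = ceiling(alpha * fit$F - 1e-9),
    extra_constraints = fun$constraints, settings = settings)$optimum
  list(score = A_ij / A_i, A_i = A_i, A_ij = A_ij, F = fit$F,
       blocked = FALSE)
}

#' Adaptability score of a metabolic function
#'
#' The metabolic-phenotype (MPA) score. `F_ji` is the optimal iMAT
#' consistency with sample `j`'s expression under the function's constraint
#' set; `Fa_ji` is the optimal consistency when the target reaction is in
#' addition forced active, by bounding its flux at half of the maximal rate
#' it can carry in the expression-unconstrained model. The adaptability
#' score `Fa_ji / F_ji` is the fraction of the expression fit that survives
#' forcing the function on: low values mean the function can only run after
#' substantial (post-)transcriptional rerouting.
#'
#' For a reversible target the enforcement direction is the one with the
#' larger absolute flux capacity (ties broken forward). If enforcement is
#' infeasible the score is 0 (with a warning); if `F_ji` is 0 the score is
#' undefined (`NA`).
#'
#' @inheritParams function_activity_score
#' @param enforce_fraction fraction of the maximal rate enforced
#'   (default 0.5).
#' @return List with `score` (`Fa_ji / F_ji` or `NA`), `F` (= `F_ji`),
#'   `Fa` (= `Fa_ji`), `enforced_bound` and `infeasible_enforcement`.
#' @export
function_adaptability_score <- function(model, fun, profile,
                                        settings = imat_settings(),
                                        enforce_fraction = 0.5) {
  states <- as_reaction_states(model, profile, settings)
  fit <- imat_max_consistency(model, states, fun$constraints, settings)
  F_ji <- fit$F
  if (F_ji == 0) {
    return(list(score = NA_real_, F = 0L, Fa = NA_integer_,
                enforced_bound = NA_real_, infeasible_enforcement = FALSE))
  }
  # enforcement is calibrated on the original model, without the
  # function's constraint set or expression: half the flux the target can
  # carry at all. Under C_i this demand can be unattainable, which is
  # exactly the "cannot adapt" signal (score 0).
  vmax <- maximize_flux(model, fun$target_reaction, sense = "max")$optimum
  vmin <- maximize_flux(model, fun$target_reaction, sense = "min")$optimum
  forward <- abs(vmax) >= abs(vmin)
  enforce <- if (forward) {
    bound_overrides(fun$target_reaction, lower = enforce_fraction * vmax)
  } else {
    bound_overrides(fun$target_reaction, upper = enforce_fraction * vmin)
  }
  bound_val <- if (forward) enforce_fraction * vmax else enforce_fraction * vmin
  ov <- combine_overrides(fun$constraints, enforce)
  Fa_ji <- tryCatch(
    imat_max_consistency(model, states, ov, settings)$F,
    hepaflux_infeasible = function(e) {
      warning("enforcement of ", fun$target_reaction,
              " infeasible; adaptability set to 0")
      NA_integer_
    })
  if (is.na(Fa_ji)) {
    return(list(score = 0, F = F_ji, Fa = NA_integer_,
                enforced_bound = bound_val, infeasible_enforcement = TRUE))
  }
  list(score = Fa_ji / F_ji, F = F_ji, Fa = Fa_ji,
       enforced_bound = bound_val, infeasible_enforcement = FALSE)
}

# internal: accept either an expression profile or ready reaction tri-states
as_reaction_states <- function(model, profile, settings) {
  vals <- if (is.list(profile) && !is.null(profile$values)) {
    unlist(profile$values)
  } else {
    unlist(profile)
  }
  if (is.character(vals) && all(vals %in% TRISTATE_LEVELS)) {
    return(vals)
  }
  profile_reaction_states(model, vals, settings)
}

#' Metabolic functionality profiles for a cohort
#'
#' Computes the activity and adaptability score of every catalogue function
#' for every sample.
#'
#' @param model a `metabolic_model`.
#' @param catalogue a `function_catalogue` (validated against the model).
#' @param cohort named list of expression profiles (named numeric vectors),
#'   or a genes x samples matrix.
#' @param settings [imat_settings()].
#' @return data.frame in long format: `sample_id`, `function_id`,
#'   `activity`, `adaptability` (undefined scores are `NA`).
#' @export
profile_functionality <- function(model, catalogue, cohort,
                                  settings = imat_settings()) {
  if (is.matrix(cohort)) {
    cohort <- stats::setNames(
      lapply(seq_len(ncol(cohort)), function(j) cohort[, j]),
      colnames(cohort))
  }
  if (length(cohort) == 0) {
    return(data.frame(sample_id = character(0), function_id = character(0),
                      activity = numeric(0), adaptability = numeric(0),
                      stringsAsFactors = FALSE))
  }
  validate_catalogue(catalogue, model)
  rows <- list()
  for (sid in names(cohort)) {
    states <- profile_reaction_states(model, cohort[[sid]], settings)
    for (f in catalogue) {
      act <- function_activity_score(model, f, states, settings)
      ada <- function_adaptability_score(model, f, states, settings)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, function_id = f$id,
        activity = act$score, adaptability = ada$score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a functionality table as TSV
#'
#' Wide layout: one row per sample, two columns per function
#' (`<id>_activity`, `<id>_adaptability`).
#'
#' @param profiles long data.frame from [profile_functionality()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_functionality_tsv <- function(profiles, path) {
  wide <- functionality_wide(profiles)
  utils::write.table(cbind(sample_id = rownames(wide), as.data.frame(wide)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reshape functionality profiles to a samples x features matrix
#'
#' @param profiles long data.frame from [profile_functionality()].
#' @return Numeric matrix, samples in rows, `<function>_activity` and
#'   `<function>_adaptability` columns.
#' @export
functionality_wide <- function(profiles) {
  samples <- unique(profiles$sample_id)
  funs <- unique(profiles$function_id)
  cols <- c(paste0(funs, "_activity"), paste0(funs, "_adaptability"))
  out <- matrix(NA_real_, length(samples), length(cols),
                dimnames = list(samples, cols))
  for (i in seq_len(nrow(profiles))) {
    s <- profiles$sample_id[i]; f <- profiles$function_id[i]
    out[s, paste0(f, "_activity")] <- profiles$activity[i]
    out[s, paste0(f, "_adaptability")] <- profiles$adaptability[i]
  }
  out
}
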