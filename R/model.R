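#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` bundles a stoichiometric network: metabolites,
#' reactions with flux bounds, pathway labels and gene--protein--reaction
#' (GPR) boolean rules. It is the container every analysis in the package
#' operates on.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `pathway`, `gpr` (boolean expression over gene ids as a
#'   string; `""` for none) and optionally `is_exchange` (recomputed from the
#'   stoichiometry when missing).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   consumed, positive = produced). Exchange reactions touch exactly one
#'   metabolite.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   appearing in the GPR rules.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  required_met <- c("id", "name", "compartment")
  if (!all(required_met %in% names(metabolites))) {
    stop("metabolites must have columns id, name, compartment")
  }
  required_rxn <- c("id", "lower_bound", "upper_bound")
  if (!all(required_rxn %in% names(reactions))) {
    stop("reactions must have columns id, lower_bound, upper_bound")
  }
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""

  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "))
  }
  if (any(metabolites$compartment == "" | is.na(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    bad <- reactions$id[reactions$lower_bound > reactions$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "))
  }
  if (!setequal(names(stoichiometry), reactions$id)) {
    stop("stoichiometry must have exactly one entry per reaction id")
  }
  stoichiometry <- stoichiometry[reactions$id]
  for (rid in reactions$id) {
    st <- stoichiometry[[rid]]
    if (length(st) == 0) {
      stop("reaction ", rid, " has empty stoichiometry")
    }
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown) > 0) {
      stop("reaction ", rid, " references undeclared metabolites: ",
           paste(unknown, collapse = ", "))
    }
  }

  gpr_genes <- unique(unlist(lapply(reactions$gpr, gpr_gene_ids)))
  if (is.null(genes)) {
    genes <- gpr_genes
  } else {
    missing_genes <- setdiff(gpr_genes, genes)
    if (length(missing_genes) > 0) {
      stop("GPR rules use genes absent from the gene set: ",
           paste(missing_genes, collapse = ", "))
    }
  }

  reactions$is_exchange <- vapply(
    stoichiometry, function(st) length(st) == 1L, logical(1)
  )[reactions$id]

  structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = as.character(genes)),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:",
      nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions",
      sprintf("(%d exchange),", sum(x$reactions$is_exchange)),
      length(x$genes), "genes\n")
  pws <- unique(stats::na.omit(x$reactions$pathway))
  if (length(pws)) {
    cat("pathways:", paste(utils::head(pws, 8), collapse = ", "),
        if (length(pws) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(n)) {
    st <- model$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

# internal: index of a reaction id, with a helpful error
reaction_index <- function(model, id) {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(id[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Bound overrides
#'
#' Constraint sets (the `C_i` of a metabolic function, measurement fixings,
#' enforcement bounds) are expressed as a data.frame of per-reaction bound
#' overrides. `NA` leaves the model's bound untouched.
#'
#' @param reaction character vector of reaction ids.
#' @param lower,upper numeric vectors (recycled) of replacement bounds.
#' @return data.frame with columns `reaction`, `lower`, `upper`.
#' @export
bound_overrides <- function(reaction, lower = NA_real_, upper = NA_real_) {
  n <- length(reaction)
  data.frame(reaction = as.character(reaction),
             lower = rep_len(as.numeric(lower), n),
             upper = rep_len(as.numeric(upper), n),
             stringsAsFactors = FALSE)
}

# internal: apply overrides to the model's bound vectors
apply_overrides <- function(model, overrides = NULL) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  names(lb) <- names(ub) <- model$reactions$id
  if (!is.null(overrides) && nrow(overrides) > 0) {
    idx <- reaction_index(model, overrides$reaction)
    take_l <- !is.na(overrides$lower)
    take_u <- !is.na(overrides$upper)
    lb[idx[take_l]] <- overrides$lower[take_l]
    ub[idx[take_u]] <- overrides$upper[take_u]
    if (any(lb > ub)) {
      bad <- model$reactions$id[lb > ub]
      stop("overrides make lower > upper for: ", paste(bad, collapse = ", "))
    }
  }
  list(lb = lb, ub = ub)
}

# internal: combine two override sets (later rows win)
combine_overrides <- function(a, b) {
  if (is.null(a) || nrow(a) == 0) return(b)
  if (is.null(b) || nrow(b) == 0) return(a)
  rbind(a, b)
}
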