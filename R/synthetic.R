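#' Toy network fixtures and synthetic cohorts
#'
#' The synthetic-data generator stands in for the study cohorts: a small
#' stoichiometric network with GPRs and pathway labels, a two-group
#' expression cohort with planted functionality/adaptability differences,
#' and noisy flux measurements drawn from a feasible flux state. It writes
#' and reads the same formats as the real pipeline, so synthetic runs
#' exercise the full I/O path.
#'
#' @name synthetic_data
NULL

#' The TM1 five-reaction fixture
#'
#' Metabolites A, B, C; reactions `EX_A` (uptake of A, bounds \[0, 10\]),
#' `R_AB` (A to B, gene g1), `R_AC` (A to C, gene g2), `R_BC` (B to C, gene
#' g3), `EX_C` (secretion of C); internal bounds \[0, 100\]; pathway labels
#' `upper` (R_AB, R_BC) and `lower` (R_AC). A minimal network with two
#' alternative routes from uptake to secretion, used throughout the tests.
#'
#' @return A `metabolic_model`.
#' @export
tm1_model <- function() {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "R_AB", "R_AC", "R_BC", "EX_C"),
    lower_bound = c(0, 0, 0, 0, 0),
    upper_bound = c(10, 100, 100, 100, 100),
    pathway = c("exchange", "upper", "lower", "upper", "exchange"),
    gpr = c("", "g1", "g2", "g3", ""),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A = c(A = 1),
    R_AB = c(A = -1, B = 1),
    R_AC = c(A = -1, C = 1),
    R_BC = c(B = -1, C = 1),
    EX_C = c(C = -1))
  metabolic_model(mets, rxns, stoich, genes = c("g1", "g2", "g3"))
}

#' Generate a toy metabolic network of parallel linear pathways
#'
#' Builds a connected network running from one uptake exchange (`EX_A`,
#' bounds \[0, 10\]) to secretion: `n_linear_pathways` parallel chains, the
#' k-th of length `max(1, pathway_length - (k - 1))`, one gene per internal
#' reaction, pathway labels `pathway1..k`. With `separate_sinks = TRUE`
#' every chain ends in its own sink metabolite and exchange (`EX_P<k>`), so
#' exchange measurements pin down the pathway fluxes; otherwise all chains
#' converge on a single secreted metabolite `C` (`EX_C`). The (2, 2) case
#' is isomorphic to [tm1_model()].
#'
#' @param n_linear_pathways number of parallel chains (>= 1).
#' @param pathway_length length of the first chain (>= 1).
#' @param seed recorded in the model construction for reproducibility of
#'   callers that derive randomness from it (the topology itself is
#'   deterministic).
#' @param separate_sinks give each pathway its own secretion exchange.
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(n_linear_pathways, pathway_length, seed = 0,
                           separate_sinks = FALSE) {
  stopifnot(n_linear_pathways >= 1, pathway_length >= 1)
  mets <- data.frame(id = "A", name = "A", compartment = "c",
                     stringsAsFactors = FALSE)
  rxn_rows <- list(data.frame(id = "EX_A", lower_bound = 0, upper_bound = 10,
                              pathway = "exchange", gpr = "",
                              stringsAsFactors = FALSE))
  stoich <- list(EX_A = c(A = 1))
  gene_n <- 0L
  add_met <- function(id) {
    if (!(id %in% mets$id)) {
      mets <<- rbind(mets, data.frame(id = id, name = id, compartment = "c",
                                      stringsAsFactors = FALSE))
    }
  }
  if (!separate_sinks) add_met("C")
  for (k in seq_len(n_linear_pathways)) {
    len <- max(1L, pathway_length - (k - 1L))
    sink_met <- if (separate_sinks) sprintf("P%d", k) else "C"
    add_met(sink_met)
    chain <- c("A",
               if (len > 1) sprintf("M%d_%d", k, seq_len(len - 1L)),
               sink_met)
    for (s in seq_len(len)) {
      add_met(chain[s + 1])
      gene_n <- gene_n + 1L
      rid <- sprintf("R%d_%d", k, s)
      rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
        id = rid, lower_bound = 0, upper_bound = 100,
        pathway = sprintf("pathway%d", k), gpr = sprintf("g%d", gene_n),
        stringsAsFactors = FALSE)
      stoich[[rid]] <- stats::setNames(c(-1, 1), c(chain[s], chain[s + 1]))
    }
    if (separate_sinks) {
      rid <- sprintf("EX_P%d", k)
      rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
        id = rid, lower_bound = 0, upper_bound = 100,
        pathway = "exchange", gpr = "", stringsAsFactors = FALSE)
      stoich[[rid]] <- stats::setNames(-1, sink_met)
    }
  }
  if (!separate_sinks) {
    rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
      id = "EX_C", lower_bound = 0, upper_bound = 100,
      pathway = "exchange", gpr = "", stringsAsFactors = FALSE)
    stoich$EX_C <- c(C = -1)
  }
  rxns <- do.call(rbind, rxn_rows)
  metabolic_model(mets, rxns, stoich)
}

#' Function catalogue for a toy model
#'
#' One metabolic function per internal pathway: the target is the last
#' reaction of the chain (the one producing the pathway's end-product), the
#' constraint set is empty.
#'
#' @param model a toy `metabolic_model` from [make_toy_model()].
#' @return A `function_catalogue` with one entry per pathway label.
#' @export
toy_function_catalogue <- function(model) {
  labels <- setdiff(unique(model$reactions$pathway), "exchange")
  funs <- lapply(labels, function(p) {
    rids <- model$reactions$id[model$reactions$pathway == p]
    metabolic_function(
      id = paste0("f_", p), target_reaction = rids[length(rids)],
      description = paste("flux through", p))
  })
  function_catalogue(funs)
}

#' Specification of a synthetic cohort
#'
#' @param n_high,n_low samples per group (the study contrasts a high and a
#'   low liver-fat group).
#' @param planted_functions `NULL`, or data.frame with columns
#'   `function_id`, `effect` (additive shift, log-intensity units, applied
#'   to the genes of the function's pathway; negative = down-regulated) and
#'   `group` (`"high"` or `"low"`: which group carries the shift).
#' @param expression_noise_sd per-sample log-intensity noise (sd).
#' @param flux_noise_sd measurement noise on fluxes (model units, sd).
#' @param n_background_genes decoy genes added to the expression universe so
#'   that within-sample ranking behaves like a genome-wide profile.
#' @param seed master RNG seed; everything derives from it.
#' @return List of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_high = 8, n_low = 8,
                                  planted_functions = NULL,
                                  expression_noise_sd = 1,
                                  flux_noise_sd = 0.25,
                                  n_background_genes = 60, seed = 1) {
  stopifnot(n_high >= 1, n_low >= 1, expression_noise_sd >= 0,
            flux_noise_sd >= 0)
  structure(list(n_high = n_high, n_low = n_low,
                 planted_functions = planted_functions,
                 expression_noise_sd = expression_noise_sd,
                 flux_noise_sd = flux_noise_sd,
                 n_background_genes = n_background_genes, seed = seed),
            class = "synthetic_cohort_spec")
}

# internal: genes belonginging to a function's pathway
function_pathway_genes <- function(model, catalogue, function_id) {
  f <- catalogue[[function_id]]
  if (is.null(f)) stop("unknown planted function: ", function_id)
  p <- model$reactions$pathway[reaction_index(model, f$target_reaction)]
  rids <- model$reactions$id[model$reactions$pathway %in% p]
  unique(unlist(lapply(model$reactions$gpr[model$reactions$id %in% rids],
                       gpr_gene_ids)))
}

#' Simulate a two-group expression cohort
#'
#' Per gene a baseline log-intensity is drawn once per cohort
#' (`Normal(8, 1)`), and each sample observes it plus
#' `Normal(0, expression_noise_sd)` noise. Planted effects shift the
#' expression of the designated function's pathway genes by `effect` in the
#' designated group. Sample ids are `high_1..n_high`, `low_1..n_low`; the
#' liver-fat covariate is uniform on 20-80% for the high group and 0-10%
#' for the low group.
#'
#' @param model a `metabolic_model`.
#' @param spec a [synthetic_cohort_spec()].
#' @param catalogue `function_catalogue` used to resolve planted function
#'   ids (default: [toy_function_catalogue()] of the model).
#' @return List: `profiles` (named list of named expression vectors),
#'   `groups` (named character), `covariate` (named numeric, liver-fat %),
#'   `truth` (planted effects).
#' @export
simulate_expression_cohort <- function(model, spec,
                                       catalogue =
                                         toy_function_catalogue(model)) {
  set.seed(spec$seed)
  genes <- c(model$genes,
             if (spec$n_background_genes > 0) {
               sprintf("bg%d", seq_len(spec$n_background_genes))
             })
  mu <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)
  ids <- c(sprintf("high_%d", seq_len(spec$n_high)),
           sprintf("low_%d", seq_len(spec$n_low)))
  groups <- stats::setNames(
    rep(c("high", "low"), c(spec$n_high, spec$n_low)), ids)
  shift <- matrix(0, length(genes), length(ids),
                  dimnames = list(genes, ids))
  if (!is.null(spec$planted_functions) &&
      nrow(spec$planted_functions) > 0) {
    for (i in seq_len(nrow(spec$planted_functions))) {
      pf <- spec$planted_functions[i, ]
      gs <- function_pathway_genes(model, catalogue, pf$function_id)
      shift[gs, groups == pf$group] <-
        shift[gs, groups == pf$group] + pf$effect
    }
  }
  profiles <- stats::setNames(lapply(ids, function(sid) {
    mu + shift[, sid] +
      stats::rnorm(length(genes), 0, spec$expression_noise_sd)
  }), ids)
  covariate <- stats::setNames(ifelse(groups == "high",
                                      stats::runif(length(ids), 20, 80),
                                      stats::runif(length(ids), 0, 10)),
                               ids)
  list(profiles = profiles, groups = groups, covariate = covariate,
       truth = spec$planted_functions)
}

#' Simulate noisy flux measurements from a feasible state
#'
#' @param model a `metabolic_model`.
#' @param true_state named feasible flux vector covering all reactions.
#' @param noise_sd Gaussian measurement noise (model units).
#' @param measured_subset reaction ids actually measured.
#' @param seed RNG seed.
#' @param condition condition label.
#' @return A [flux_measurements()] data.frame.
#' @export
simulate_flux_measurements <- function(model, true_state, noise_sd,
                                       measured_subset, seed = 1,
                                       condition = "basal") {
  if (length(measured_subset) == 0) stop("measured subset must be nonempty")
  validate_flux_vector(model, true_state)
  set.seed(seed)
  vals <- true_state[measured_subset] +
    stats::rnorm(length(measured_subset), 0, noise_sd)
  flux_measurements(measured_subset, unname(vals), condition = condition)
}

#' Simulate a functionality score table directly
#'
#' Generates a samples x (2 x functions) matrix of activity/adaptability
#' scores in \[0, 1\] with a prescribed group separation on a subset of
#' informative functions, bypassing the solver. With `separation = 1` the
#' informative columns do not overlap between groups, so the table is
#' linearly separable; with `separation = 0` the table carries no group
#' signal.
#'
#' @param n_high,n_low samples per group.
#' @param n_functions number of functions (column pairs).
#' @param n_informative functions whose adaptability differs between groups.
#' @param separation in \[0, 1\]: distance between the group score bands of
#'   informative columns.
#' @param seed RNG seed.
#' @return List: `features` (matrix with rownames `high_*`/`low_*`),
#'   `groups` (named character).
#' @export
simulate_functionality_table <- function(n_high = 8, n_low = 8,
                                         n_functions = 22,
                                         n_informative = 11,
                                         separation = 1, seed = 1) {
  stopifnot(separation >= 0, separation <= 1,
            n_informative <= n_functions)
  set.seed(seed)
  ids <- c(sprintf("high_%d", seq_len(n_high)),
           sprintf("low_%d", seq_len(n_low)))
  groups <- stats::setNames(rep(c("high", "low"), c(n_high, n_low)), ids)
  fn <- sprintf("fn%02d", seq_len(n_functions))
  cols <- c(paste0(fn, "_activity"), paste0(fn, "_adaptability"))
  X <- matrix(stats::runif(length(ids) * length(cols)),
              length(ids), length(cols), dimnames = list(ids, cols))
  # informative columns: high ~ U(0, 1 - separation), low ~ U(separation,
  # 1); identical at separation 0, disjoint at separation 1
  for (k in seq_len(n_informative)) {
    col <- paste0(fn[k], "_adaptability")
    X[groups == "high", col] <- stats::runif(n_high, 0,
                                             max(1 - separation, 1e-9))
    X[groups == "low", col] <- stats::runif(n_low,
                                            min(separation, 1 - 1e-9), 1)
  }
  list(features = X, groups = groups)
}

#' Simulate a flux-measurement cohort with a fat-coupled pathway
#'
#' Builds a toy model with per-pathway sinks, draws a liver-fat value per
#' sample, and constructs per-sample feasible flux states in which the flux
#' of pathway 1 increases monotonically with liver fat while the other
#' pathways fluctuate independently. Exchange fluxes are then measured with
#' Gaussian noise. The pathway-1 chain and its sink exchange are the
#' planted fat-coupled reactions.
#'
#' @param n_samples number of patients.
#' @param n_pathways,pathway_length toy-model geometry.
#' @param flux_noise_sd measurement noise sd (model units).
#' @param seed RNG seed.
#' @return List: `model`, `measurements` (named list per sample),
#'   `true_states`, `covariate` (liver-fat %), `truth` (coupled reaction
#'   ids).
#' @export
simulate_flux_cohort <- function(n_samples = 9, n_pathways = 6,
                                 pathway_length = 2, flux_noise_sd = 0.25,
                                 seed = 1) {
  model <- make_toy_model(n_pathways, pathway_length, seed = seed,
                          separate_sinks = TRUE)
  set.seed(seed)
  fat <- stats::runif(n_samples, 5, 75)
  ids <- sprintf("patient_%d", seq_len(n_samples))
  sinks <- sprintf("EX_P%d", seq_len(n_pathways))
  states <- list()
  meas <- list()
  for (j in seq_len(n_samples)) {
    f <- c(1 + 7 * (fat[j] - 5) / 70,
           stats::runif(n_pathways - 1, 0.1, 0.4))
    # keep total uptake within the EX_A capacity of 10
    total <- sum(f)
    if (total > 10) f <- f * 10 / total
    v <- stats::setNames(rep(0, n_reactions(model)), model$reactions$id)
    v["EX_A"] <- sum(f)
    for (k in seq_len(n_pathways)) {
      chain <- model$reactions$id[model$reactions$pathway ==
                                    sprintf("pathway%d", k)]
      v[chain] <- f[k]
      v[sinks[k]] <- f[k]
    }
    states[[ids[j]]] <- v
    meas[[ids[j]]] <- simulate_flux_measurements(
      model, v, flux_noise_sd, c("EX_A", sinks), seed = seed + j,
      condition = "basal")
  }
  coupled <- c(model$reactions$id[model$reactions$pathway == "pathway1"],
               "EX_P1")
  list(model = model, measurements = meas, true_states = states,
       covariate = stats::setNames(fat, ids),
       truth = list(fat_coupled_reactions = coupled))
}

#' Assemble a full synthetic study
#'
#' Bundles a toy model, its function catalogue, a two-group expression
#' cohort and a flux-measurement cohort, mirroring the transcriptomics
#' (8 + 8 samples) and splanchnic-flux (9 patients) arms of a liver study.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param n_pathways,pathway_length geometry of the expression-arm model.
#' @return List: `model`, `catalogue`, `expression` (see
#'   [simulate_expression_cohort()]), `flux` (see [simulate_flux_cohort()]),
#'   `truth`.
#' @export
make_synthetic_cohort <- function(spec = synthetic_cohort_spec(),
                                  n_pathways = 3, pathway_length = 3) {
  model <- make_toy_model(n_pathways, pathway_length, seed = spec$seed)
  catalogue <- toy_function_catalogue(model)
  expr <- simulate_expression_cohort(model, spec, catalogue)
  flux <- simulate_flux_cohort(flux_noise_sd = spec$flux_noise_sd,
                               seed = spec$seed)
  list(model = model, catalogue = catalogue, expression = expr,
       flux = flux,
       truth = list(planted_functions = spec$planted_functions,
                    fat_coupled_reactions = flux$truth$fat_coupled_reactions))
}
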