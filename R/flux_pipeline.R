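#' Flux measurements
#'
#' Measured splanchnic exchange fluxes for one condition (e.g. basal or
#' insulin). Sign convention: uptake is negative, secretion positive, in
#' model units; harmonizing measurement units to model units (and metabolite
#' names to exchange-reaction ids) is the caller's responsibility, typically
#' via a mapping table.
#'
#' @param reaction_id character vector of exchange-reaction ids.
#' @param value numeric measured fluxes.
#' @param condition single condition label.
#' @param sd optional per-measurement standard deviations.
#' @return data.frame of class `flux_measurements`.
#' @export
flux_measurements <- function(reaction_id, value, condition = "basal",
                              sd = NA_real_) {
  if (length(reaction_id) == 0) stop("at least one measurement is required")
  if (any(!is.finite(value))) stop("measurement values must be finite")
  structure(
    data.frame(reaction_id = as.character(reaction_id),
               value = as.numeric(value),
               condition = condition, sd = as.numeric(sd),
               stringsAsFactors = FALSE),
    class = c("flux_measurements", "data.frame"))
}

#' Read measurements from TSV
#'
#' Expected columns: `reaction_id`, `value`, optionally `condition` and
#' `sd`. Lines starting with `#` are ignored.
#'
#' @param path TSV file.
#' @return Named list of `flux_measurements`, one per condition.
#' @export
read_flux_measurements <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "value") %in% names(df))) {
    stop("measurements TSV needs columns reaction_id and value: ", path)
  }
  if (is.null(df$condition)) df$condition <- "basal"
  if (is.null(df$sd)) df$sd <- NA_real_
  lapply(split(df, df$condition), function(d) {
    flux_measurements(d$reaction_id, d$value, d$condition[1], d$sd)
  })
}

#' Fit measured fluxes by quadratic programming
#'
#' Finds the steady-state flux vector minimizing the Euclidean distance to
#' the measurements over the measured reactions (unweighted; optionally
#' 1/sd^2-weighted). The minimal distance is the consistency score: 0 iff
#' the measurements are jointly feasible. A tiny ridge on all fluxes makes
#' the quadratic form positive definite and selects a minimum-norm
#' representative among alternate optima; its effect on the measured
#' coordinates is far below the reported tolerances.
#'
#' @param model a `metabolic_model`.
#' @param measurements a [flux_measurements()] data.frame (one condition).
#' @param weighted if `TRUE`, weight squared residuals by `1/sd^2`
#'   (measurements with missing `sd` get weight 1).
#' @param ridge Tikhonov regularization constant (relative).
#' @return List of class `consistency_result`: `fitted` (named flux vector),
#'   `consistency_score` (Euclidean misfit), `measured_ids`, `residuals`.
#' @export
fit_fluxes_qp <- function(model, measurements, weighted = FALSE,
                          ridge = 1e-8) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    stop("empty measurement set")
  }
  unknown <- setdiff(measurements$reaction_id, model$reactions$id)
  if (length(unknown) > 0) {
    stop("measurements reference unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(measurements$reaction_id)) {
    stop("duplicate measured reaction ids within one condition")
  }
  n <- n_reactions(model)
  idx <- reaction_index(model, measurements$reaction_id)
  w <- rep(1, nrow(measurements))
  if (weighted) {
    ok <- is.finite(measurements$sd) & measurements$sd > 0
    w[ok] <- 1 / measurements$sd[ok]^2
  }

  scale_ref <- max(1, max(abs(measurements$value)))
  eps <- ridge * scale_ref
  # objective: sum_k w_k (v_mk - m_k)^2 + eps * ||v||^2
  Dmat <- diag(rep(2 * eps, n))
  for (k in seq_along(idx)) {
    Dmat[idx[k], idx[k]] <- Dmat[idx[k], idx[k]] + 2 * w[k]
  }
  dvec <- rep(0, n)
  dvec[idx] <- 2 * w * measurements$value

  S <- stoichiometric_matrix(model)
  # drop linearly dependent steady-state rows (quadprog requires full rank)
  qrS <- qr(t(S))
  S_red <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  Amat <- cbind(t(S_red), diag(n), -diag(n))
  bvec <- c(rep(0, nrow(S_red)), lb, -ub)
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(S_red))
  fitted <- stats::setNames(sol$solution, model$reactions$id)
  resid <- fitted[idx] - measurements$value
  structure(
    list(fitted = fitted,
         consistency_score = sqrt(sum(w * resid^2)),
         measured_ids = measurements$reaction_id,
         residuals = stats::setNames(resid, measurements$reaction_id),
         condition = measurements$condition[1]),
    class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("consistency_result:", length(x$measured_ids), "measured reactions,",
      "consistency score", format(x$consistency_score, digits = 6), "\n")
  invisible(x)
}

#' FVA with measured reactions fixed to their fitted values
#'
#' @param model a `metabolic_model`.
#' @param fit a `consistency_result` from [fit_fluxes_qp()].
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame of flux ranges (`reaction`, `v_min`, `v_max`).
#' @export
constrained_fva <- function(model, fit, reactions = NULL) {
  fixed <- fit$fitted[fit$measured_ids]
  flux_variability(model, reactions = reactions, fixed = fixed)
}

#' Classify reactions as active or inactive
#'
#' A reaction is active when its flux range allows an absolute flux greater
#' than `threshold` (default 0.001).
#'
#' @param ranges data.frame from [flux_variability()]/[constrained_fva()].
#' @param threshold activity threshold (flux units).
#' @return data.frame of class `activity_classification` with columns
#'   `reaction`, `active`, and the threshold as attribute `threshold`.
#' @export
classify_activity <- function(ranges, threshold = 0.001) {
  if (nrow(ranges) == 0) stop("empty flux ranges")
  active <- pmax(abs(ranges$v_min), abs(ranges$v_max)) > threshold
  structure(
    data.frame(reaction = ranges$reaction, active = active,
               stringsAsFactors = FALSE),
    threshold = threshold,
    class = c("activity_classification", "data.frame"))
}

#' Pathway enrichment of active / inactive reactions
#'
#' Upper-tail hypergeometric test per pathway: is the pathway's overlap with
#' the active (resp. inactive) reaction set larger than expected when
#' drawing that many reactions at random from the model?
#'
#' @param classification an `activity_classification`.
#' @param model a `metabolic_model` (source of pathway labels; unlabeled
#'   reactions fall in pathway `"other"`).
#' @return data.frame with one row per non-empty pathway: `pathway`,
#'   `n_pathway`, `overlap_active`, `p_active`, `overlap_inactive`,
#'   `p_inactive`.
#' @export
pathway_enrichment <- function(classification, model) {
  pw <- stats::setNames(model$reactions$pathway, model$reactions$id)
  labels <- pw[classification$reaction]
  labels[is.na(labels) | labels == ""] <- "other"
  N <- nrow(classification)
  n_active <- sum(classification$active)
  n_inactive <- N - n_active
  rows <- lapply(unique(labels), function(p) {
    in_p <- labels == p
    k <- sum(in_p)
    ov_a <- sum(in_p & classification$active)
    ov_i <- sum(in_p & !classification$active)
    data.frame(
      pathway = p, n_pathway = k,
      overlap_active = ov_a,
      p_active = stats::phyper(ov_a - 1, n_active, N - n_active, k,
                               lower.tail = FALSE),
      overlap_inactive = ov_i,
      p_inactive = stats::phyper(ov_i - 1, n_inactive, N - n_inactive, k,
                                 lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate per-sample maximal fluxes with a covariate
#'
#' For every reaction, Spearman correlation between its per-sample `v_max`
#' (from per-sample constrained FVA) and a covariate such as liver-fat
#' percentage, with a label-shuffling empirical p-value and Benjamini-
#' Hochberg FDR across reactions. A row is flagged significant when the
#' empirical and the asymptotic Spearman p-value are both below `alpha` and
#' the BH q-value is at most `fdr_rate`.
#'
#' @param per_sample_ranges named list (sample id -> FVA data.frame).
#' @param covariate named numeric vector (sample id -> covariate value).
#' @param n_perm number of label shuffles.
#' @param fdr_rate FDR level.
#' @param alpha per-test significance level.
#' @param seed RNG seed for the shuffles.
#' @param use `"v_max"` (default) or `"v_min"`.
#' @return data.frame: `reaction`, `rho`, `p_spearman`, `p_empirical`,
#'   `q_fdr`, `significant`.
#' @export
covariate_correlation <- function(per_sample_ranges, covariate,
                                  n_perm = 1000, fdr_rate = 0.1,
                                  alpha = 0.05, seed = 1, use = "v_max") {
  samples <- names(per_sample_ranges)
  if (length(samples) < 4) stop("need at least 4 samples")
  if (!all(samples %in% names(covariate))) {
    stop("covariate missing for sample(s): ",
         paste(setdiff(samples, names(covariate)), collapse = ", "))
  }
  cov <- covariate[samples]
  if (length(unique(cov)) == 1) stop("constant covariate")

  rxns <- per_sample_ranges[[1]]$reaction
  V <- vapply(per_sample_ranges, function(r) {
    stats::setNames(r[[use]], r$reaction)[rxns]
  }, numeric(length(rxns)))

  rho <- apply(V, 1, function(x) {
    if (length(unique(x)) == 1) NA_real_ else
      suppressWarnings(stats::cor(x, cov, method = "spearman"))
  })
  p_sp <- apply(V, 1, function(x) {
    if (length(unique(x)) == 1) NA_real_ else
      suppressWarnings(stats::cor.test(x, cov, method = "spearman")$p.value)
  })

  set.seed(seed)
  exceed <- rep(0L, length(rxns))
  for (b in seq_len(n_perm)) {
    cov_p <- sample(cov)
    rho_p <- suppressWarnings(
      apply(V, 1, function(x) stats::cor(x, cov_p, method = "spearman")))
    exceed <- exceed + as.integer(!is.na(rho) & !is.na(rho_p) &
                                    abs(rho_p) >= abs(rho))
  }
  p_emp <- ifelse(is.na(rho), NA_real_, (exceed + 1) / (n_perm + 1))
  q <- stats::p.adjust(p_emp, method = "BH")
  data.frame(
    reaction = rxns, rho = rho, p_spearman = p_sp, p_empirical = p_emp,
    q_fdr = q,
    significant = !is.na(rho) & p_emp < alpha & p_sp < alpha & q <= fdr_rate,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical p-value of the consistency score
#'
#' Evaluates how well the model fits the real measurements compared with
#' random ones: draws `n_random` random measurement sets, each value uniform
#' on the global [min, max] envelope of the observed measurement values
#' (the scale of the data), computes the consistency score of each and
#' reports the fraction of random sets fitting at least as well as the
#' observed data, i.e. `p = (#{score_random <= score_observed} + 1) /
#' (n_random + 1)`.
#'
#' @param model a `metabolic_model`.
#' @param measurements a [flux_measurements()] data.frame (>= 2 entries).
#' @param n_random number of random measurement sets.
#' @param seed RNG seed.
#' @return List: `p_value`, `observed_score`, `random_scores`.
#' @export
consistency_pvalue <- function(model, measurements, n_random = 1000,
                               seed = 1) {
  if (nrow(measurements) < 2) stop("need at least 2 measurements")
  observed <- fit_fluxes_qp(model, measurements)$consistency_score
  lo <- min(measurements$value); hi <- max(measurements$value)
  set.seed(seed)
  rand <- numeric(n_random)
  k <- nrow(measurements)
  for (b in seq_len(n_random)) {
    mm <- measurements
    mm$value <- stats::runif(k, lo, hi)
    rand[b] <- fit_fluxes_qp(model, mm)$consistency_score
  }
  list(p_value = (sum(rand <= observed) + 1) / (n_random + 1),
       observed_score = observed, random_scores = rand)
}

#' Leave-one-out cross-validation of flux predictions
#'
#' Each measured reaction is held out in turn; the remaining measurements
#' are refit by QP, the model is constrained to the refit values, and the
#' held-out flux is predicted as the midpoint of its FVA range. Reported is
#' the Spearman correlation between observed and predicted values.
#'
#' @param model a `metabolic_model`.
#' @param measurements a [flux_measurements()] data.frame (>= 3 entries).
#' @return List: `pairs` (data.frame `reaction`, `observed`, `predicted`,
#'   `range_width`), `rho`, `p_value`.
#' @export
loocv_fluxes <- function(model, measurements) {
  if (nrow(measurements) < 3) stop("need at least 3 measurements for LOOCV")
  k <- nrow(measurements)
  predicted <- numeric(k)
  width <- numeric(k)
  for (i in seq_len(k)) {
    rest <- measurements[-i, , drop = FALSE]
    fit <- fit_fluxes_qp(model, rest)
    rng <- constrained_fva(model, fit,
                           reactions = measurements$reaction_id[i])
    predicted[i] <- (rng$v_min + rng$v_max) / 2
    width[i] <- rng$v_max - rng$v_min
  }
  ct <- suppressWarnings(
    stats::cor.test(measurements$value, predicted, method = "spearman"))
  list(pairs = data.frame(reaction = measurements$reaction_id,
                          observed = measurements$value,
                          predicted = predicted, range_width = width,
                          stringsAsFactors = FALSE),
       rho = unname(ct$estimate), p_value = ct$p.value)
}
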