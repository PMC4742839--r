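#' iMAT settings
#'
#' Parameters of the expression-integration MILP: discretization quantiles,
#' the activation flux epsilon (a "high" reaction is satisfied when it
#' carries |v| >= epsilon), and the MILP gap.
#'
#' @param q_low fraction of lowest-expressed genes called `low` (in (0, 0.5)).
#' @param q_high quantile above which genes are called `high` (in (0.5, 1)).
#' @param epsilon activation flux, model units; must be > 0.
#' @param milp_gap relative MILP optimality gap.
#' @return List of class `imat_settings`.
#' @export
imat_settings <- function(q_low = 0.25, q_high = 0.75, epsilon = 1,
                          milp_gap = 1e-9) {
  stopifnot(q_low > 0, q_low < 0.5, q_high > 0.5, q_high < 1, epsilon > 0)
  structure(list(q_low = q_low, q_high = q_high, epsilon = epsilon,
                 milp_gap = milp_gap), class = "imat_settings")
}

#' Discretize an expression profile into tri-states
#'
#' Genes are ranked within the sample; the lowest `q_low` fraction is called
#' `low`, the highest `1 - q_high` fraction `high`, the rest `moderate`.
#' Ties are broken by gene id so the call is reproducible.
#'
#' @param profile named numeric vector of normalized intensities (one
#'   sample), or a list with fields `sample_id` and `values`.
#' @param settings an [imat_settings()] object.
#' @return Named character vector of `"low"`/`"moderate"`/`"high"`.
#' @export
discretize_expression <- function(profile, settings = imat_settings()) {
  values <- if (is.list(profile) && !is.null(profile$values)) {
    unlist(profile$values)
  } else {
    unlist(profile)
  }
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("need at least 4 genes with finite values")
  out <- stats::setNames(rep("moderate", n), names(values))
  if (length(unique(values)) == 1) {
    warning("constant expression profile; all genes set to moderate")
    return(out)
  }
  ord <- order(values, names(values))  # ascending, stable by gene id
  n_low <- floor(settings$q_low * n)
  n_high <- floor((1 - settings$q_high) * n)
  if (n_low > 0) out[ord[seq_len(n_low)]] <- "low"
  if (n_high > 0) out[ord[seq(n - n_high + 1, n)]] <- "high"
  out
}

# internal: assemble the iMAT MILP for a model + reaction tri-states.
# Variables: v (n fluxes), then y+ / y- per "high" reaction (flux forced
# through in forward/backward direction), then z per "low" reaction (flux
# forced to zero). Big-M constants come from the reaction bounds.
imat_build <- function(parts, reaction_states, epsilon) {
  n <- length(parts$lb)
  rxn_ids <- parts$rxn_ids
  states <- stats::setNames(rep("moderate", n), rxn_ids)
  known <- intersect(names(reaction_states), rxn_ids)
  states[known] <- unlist(reaction_states)[known]
  tristate_rank(states)

  hi <- which(states == "high")
  lo <- which(states == "low")
  n_hi <- length(hi); n_lo <- length(lo)
  nv <- n + 2 * n_hi + n_lo
  yp <- n + seq_len(n_hi)
  ym <- n + n_hi + seq_len(n_hi)
  zz <- n + 2 * n_hi + seq_len(n_lo)

  m <- nrow(parts$S)
  rows <- list()
  lbs <- c(); ubs <- c()
  add_row <- function(row, lo_, hi_) {
    rows[[length(rows) + 1L]] <<- row
    lbs <<- c(lbs, lo_); ubs <<- c(ubs, hi_)
  }
  # steady state
  if (m > 0) {
    Ss <- cbind(parts$S, matrix(0, m, nv - n))
    for (i in seq_len(m)) add_row(Ss[i, ], 0, 0)
  }
  for (k in seq_along(hi)) {
    r <- hi[k]
    # y+ = 1  =>  v_r >= epsilon :  v_r - (epsilon - lb_r) y+ >= lb_r
    row <- rep(0, nv); row[r] <- 1; row[yp[k]] <- -(epsilon - parts$lb[r])
    add_row(row, parts$lb[r], Inf)
    # y- = 1  =>  v_r <= -epsilon :  v_r + (epsilon + ub_r) y- <= ub_r
    row <- rep(0, nv); row[r] <- 1; row[ym[k]] <- epsilon + parts$ub[r]
    add_row(row, -Inf, parts$ub[r])
    # at most one direction
    row <- rep(0, nv); row[yp[k]] <- 1; row[ym[k]] <- 1
    add_row(row, -Inf, 1)
  }
  for (k in seq_along(lo)) {
    r <- lo[k]
    # z = 1  =>  v_r = 0 : lb_r (1 - z) <= v_r <= ub_r (1 - z)
    row <- rep(0, nv); row[r] <- 1; row[zz[k]] <- parts$ub[r]
    add_row(row, -Inf, parts$ub[r])
    row <- rep(0, nv); row[r] <- 1; row[zz[k]] <- parts$lb[r]
    add_row(row, parts$lb[r], Inf)
  }
  A <- do.call(rbind, rows)
  lb <- c(parts$lb, rep(0, nv - n))
  ub <- c(parts$ub, rep(1, nv - n))
  list(A = A, con_lb = lbs, con_ub = ubs, lb = lb, ub = ub, nv = nv, n = n,
       hi = hi, lo = lo, yp = yp, ym = ym, zz = zz, rxn_ids = rxn_ids)
}

# internal: extract indicator assignment from a MILP solution
imat_indicators <- function(prob, x) {
  ind <- stats::setNames(logical(length(prob$hi) + length(prob$lo)),
                         prob$rxn_ids[c(prob$hi, prob$lo)])
  if (length(prob$hi)) {
    ind[prob$rxn_ids[prob$hi]] <-
      x[prob$yp] > 0.5 | x[prob$ym] > 0.5
  }
  if (length(prob$lo)) {
    ind[prob$rxn_ids[prob$lo]] <- x[prob$zz] > 0.5
  }
  ind
}

#' Maximum consistency with discretized expression (iMAT)
#'
#' Solves the iMAT MILP: find a steady-state flux vector maximizing the
#' number of satisfied expression states, where a highly-expressed reaction
#' is satisfied iff it carries |v| >= epsilon (in either direction) and a
#' lowly-expressed reaction is satisfied iff v = 0. Moderate reactions do
#' not enter the objective.
#'
#' @param model a `metabolic_model`.
#' @param reaction_states named character vector of reaction tri-states
#'   (from [reaction_expression_states()]); reactions not named are
#'   `moderate`.
#' @param extra_constraints [bound_overrides()] or `NULL`.
#' @param settings [imat_settings()].
#' @return List with `F` (optimal count of satisfied states), `witness`
#'   (named flux vector attaining it) and `indicators` (named logical: which
#'   high/low reactions are satisfied in the witness).
#' @export
imat_max_consistency <- function(model, reaction_states,
                                 extra_constraints = NULL,
                                 settings = imat_settings()) {
  parts <- lp_parts(model, extra_constraints)
  prob <- imat_build(parts, reaction_states, settings$epsilon)
  n_ind <- prob$nv - prob$n
  if (n_ind == 0) {
    sol <- lp_solve(parts, rep(0, prob$n), "min")
    if (sol$status == "infeasible") stop_infeasible("infeasible constraints")
    return(list(F = 0L, witness = sol$x,
                indicators = stats::setNames(logical(0), character(0))))
  }
  c_vec <- c(rep(0, prob$n), rep(-1, n_ind))
  sol <- milp_solve(c_vec, prob$A, prob$con_lb, prob$con_ub,
                    prob$lb, prob$ub, int_idx = prob$n + seq_len(n_ind))
  if (sol$status == "infeasible") {
    stop_infeasible("infeasible constraints in iMAT MILP",
                    data = infeasibility_hint(model, extra_constraints))
  }
  list(F = as.integer(round(-sol$objective)),
       witness = stats::setNames(sol$x[seq_len(prob$n)], prob$rxn_ids),
       indicators = imat_indicators(prob, sol$x))
}

# internal: maximize flux through a target reaction while keeping iMAT
# consistency >= min_consistency (used for the activity score A_ij).
imat_max_flux_at_consistency <- function(model, reaction_states, target,
                                         min_consistency,
                                         extra_constraints = NULL,
                                         settings = imat_settings(),
                                         sense = c("max", "min")) {
  sense <- match.arg(sense)
  idx <- reaction_index(model, target)
  parts <- lp_parts(model, extra_constraints)
  prob <- imat_build(parts, reaction_states, settings$epsilon)
  n_ind <- prob$nv - prob$n
  sgn <- if (sense == "max") -1 else 1
  c_vec <- rep(0, prob$nv); c_vec[idx] <- sgn
  A <- prob$A; con_lb <- prob$con_lb; con_ub <- prob$con_ub
  if (n_ind > 0 && min_consistency > 0) {
    row <- c(rep(0, prob$n), rep(1, n_ind))
    A <- rbind(A, row)
    con_lb <- c(con_lb, min_consistency)
    con_ub <- c(con_ub, Inf)
  }
  sol <- milp_solve(c_vec, A, con_lb, con_ub, prob$lb, prob$ub,
                    int_idx = if (n_ind) prob$n + seq_len(n_ind) else integer(0))
  if (sol$status == "infeasible") {
    stop_infeasible("no flux state attains the required consistency")
  }
  list(optimum = sgn * sol$objective,
       witness = stats::setNames(sol$x[seq_len(prob$n)], prob$rxn_ids))
}
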