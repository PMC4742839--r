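#' @name solver_layer
#' @title LP/MILP solver layer
#'
#' @description All constraint-based calculations (FBA, FVA, feasibility,
#' iMAT MILPs) go through a single solver interface backed by the HiGHS
#' solver (via scipy). HiGHS is deterministic for a fixed problem, so
#' identical inputs give identical optima. Tolerances: steady state and
#' bound slack 1e-6, LP optimality 1e-9 (see [hepaflux_tolerances()]).
NULL

.solver <- new.env(parent = emptyenv())

solver_backend <- function() {
  if (is.null(.solver$sp)) {
    .solver$sp <- reticulate::import("scipy.optimize", convert = FALSE)
    .solver$np <- reticulate::import("numpy", convert = FALSE)
  }
  .solver
}

#' Numerical tolerances
#'
#' @param steady_state maximum allowed |S v| entry for a flux vector.
#' @param bound_slack allowed bound violation when validating fluxes.
#' @param lp_tol LP optimality/feasibility tolerance passed to the solver.
#' @param milp_gap relative MILP gap.
#' @return List of tolerances; pass to solver functions or set via
#'   `options(hepaflux.tolerances = ...)`.
#' @export
hepaflux_tolerances <- function(steady_state = 1e-6, bound_slack = 1e-6,
                                lp_tol = 1e-9, milp_gap = 1e-9) {
  list(steady_state = steady_state, bound_slack = bound_slack,
       lp_tol = lp_tol, milp_gap = milp_gap)
}

tolerances <- function() {
  getOption("hepaflux.tolerances", hepaflux_tolerances())
}

stop_infeasible <- function(message, data = NULL) {
  cond <- structure(class = c("hepaflux_infeasible", "error", "condition"),
                    list(message = message, call = sys.call(-1), data = data))
  stop(cond)
}

# internal: assemble LP data for a model + overrides
lp_parts <- function(model, extra_constraints = NULL) {
  b <- apply_overrides(model, extra_constraints)
  list(S = stoichiometric_matrix(model), lb = b$lb, ub = b$ub,
       rxn_ids = model$reactions$id)
}

# internal: solve min/max c'v s.t. S v = 0, lb <= v <= ub
# returns list(status, objective (in the requested sense), x)
lp_solve <- function(parts, obj, sense = c("max", "min")) {
  sense <- match.arg(sense)
  be <- solver_backend()
  sgn <- if (sense == "max") -1 else 1
  m <- nrow(parts$S)
  res <- be$sp$linprog(
    c = be$np$array(sgn * obj),
    A_eq = be$np$array(parts$S),
    b_eq = be$np$array(rep(0, m)),
    bounds = be$np$array(cbind(parts$lb, parts$ub)),
    method = "highs"
  )
  status <- reticulate::py_to_r(res$status)
  if (status == 0) {
    list(status = "optimal",
         objective = sgn * reticulate::py_to_r(res$fun),
         x = stats::setNames(as.numeric(reticulate::py_to_r(res$x)),
                             parts$rxn_ids))
  } else if (status == 2) {
    list(status = "infeasible", objective = NA_real_, x = NULL)
  } else if (status == 3) {
    list(status = "unbounded", objective = sgn * -Inf, x = NULL)
  } else {
    stop("LP solver failure (status ", status, ")")
  }
}

# internal: hint at which overrides bind an infeasible constraint set
infeasibility_hint <- function(model, extra_constraints) {
  if (is.null(extra_constraints) || nrow(extra_constraints) == 0) {
    return(character(0))
  }
  keep <- rep(TRUE, nrow(extra_constraints))
  for (i in seq_len(nrow(extra_constraints))) {
    trial <- keep
    trial[i] <- FALSE
    if (!check_feasibility(model, extra_constraints[trial, , drop = FALSE])) {
      keep[i] <- FALSE  # still infeasible without row i: not needed
    }
  }
  unique(extra_constraints$reaction[keep])
}

#' Maximize (or minimize) flux through a reaction (FBA)
#'
#' Linear program: optimize the flux of `objective` subject to steady state
#' `S v = 0` and the model's bounds, optionally tightened by
#' `extra_constraints`.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize.
#' @param extra_constraints [bound_overrides()] data.frame or `NULL`.
#' @param sense `"max"` (default) or `"min"`.
#' @return List with `optimum` (numeric) and `witness` (named flux vector
#'   attaining it). Alternate optima may exist; only the optimum value is
#'   contractual.
#' @export
maximize_flux <- function(model, objective, extra_constraints = NULL,
                          sense = "max") {
  idx <- reaction_index(model, objective)
  parts <- lp_parts(model, extra_constraints)
  obj <- rep(0, length(parts$lb))
  obj[idx] <- 1
  sol <- lp_solve(parts, obj, sense)
  if (sol$status == "infeasible") {
    hint <- infeasibility_hint(model, extra_constraints)
    stop_infeasible(
      paste0("infeasible constraint set for objective ", objective,
             if (length(hint)) paste0(" (binding overrides: ",
                                      paste(hint, collapse = ", "), ")")),
      data = hint)
  }
  list(optimum = sol$objective, witness = sol$x)
}

#' Flux variability analysis (FVA)
#'
#' Per-reaction LP minimum and maximum flux under the model constraints,
#' optionally with some reactions fixed to given values (e.g. QP-fitted
#' measurements).
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param fixed named numeric vector of reaction fluxes to pin
#'   (`lower = upper = value`), or `NULL`.
#' @param extra_constraints additional [bound_overrides()].
#' @return data.frame with columns `reaction`, `v_min`, `v_max`. Fixed
#'   reactions report `v_min = v_max =` their fixed value.
#' @export
flux_variability <- function(model, reactions = NULL, fixed = NULL,
                             extra_constraints = NULL) {
  if (is.null(reactions)) reactions <- model$reactions$id
  fix_ov <- NULL
  if (!is.null(fixed) && length(fixed) > 0) {
    fix_ov <- bound_overrides(names(fixed), lower = unname(fixed),
                              upper = unname(fixed))
  }
  ov <- combine_overrides(extra_constraints, fix_ov)
  parts <- lp_parts(model, ov)
  if (!check_feasibility(model, ov)) {
    stop_infeasible("infeasible fixed/override set in FVA",
                    data = infeasibility_hint(model, ov))
  }
  idx <- reaction_index(model, reactions)
  v_min <- v_max <- numeric(length(reactions))
  for (k in seq_along(idx)) {
    rid <- reactions[k]
    if (!is.null(fixed) && rid %in% names(fixed)) {
      v_min[k] <- v_max[k] <- fixed[[rid]]
      next
    }
    obj <- rep(0, length(parts$lb))
    obj[idx[k]] <- 1
    v_min[k] <- lp_solve(parts, obj, "min")$objective
    v_max[k] <- lp_solve(parts, obj, "max")$objective
  }
  data.frame(reaction = reactions, v_min = v_min, v_max = v_max,
             stringsAsFactors = FALSE)
}

#' Steady-state feasibility check
#'
#' @param model a `metabolic_model`.
#' @param extra_constraints [bound_overrides()] or `NULL`.
#' @return `TRUE` iff a steady-state flux vector exists within bounds.
#' @export
check_feasibility <- function(model, extra_constraints = NULL) {
  parts <- tryCatch(lp_parts(model, extra_constraints),
                    error = function(e) NULL)
  if (is.null(parts)) return(FALSE)  # overrides with lower > upper
  sol <- lp_solve(parts, rep(0, length(parts$lb)), "min")
  sol$status != "infeasible"
}

#' Validate a flux vector against a model
#'
#' @param model a `metabolic_model`.
#' @param v named flux vector covering every reaction.
#' @param tol tolerances from [hepaflux_tolerances()].
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_flux_vector <- function(model, v, tol = tolerances()) {
  if (!setequal(names(v), model$reactions$id)) {
    stop("flux vector must cover every model reaction")
  }
  v <- v[model$reactions$id]
  resid <- max(abs(stoichiometric_matrix(model) %*% v))
  if (resid > tol$steady_state) {
    stop("flux vector violates steady state (max |S v| = ",
         format(resid), ")")
  }
  lo <- v - model$reactions$lower_bound
  hi <- model$reactions$upper_bound - v
  if (min(lo, hi) < -tol$bound_slack) {
    stop("flux vector violates reaction bounds")
  }
  invisible(TRUE)
}

# ------------------------------------------------------------- MILP ------

# internal: generic MILP  min c'x  s.t.  A x in [con_lb, con_ub],
# x in [lb, ub], x[int_idx] integer. Returns list(status, objective, x).
milp_solve <- function(c_vec, A, con_lb, con_ub, lb, ub, int_idx) {
  be <- solver_backend()
  integrality <- rep(0L, length(c_vec))
  integrality[int_idx] <- 1L
  res <- be$sp$milp(
    c = be$np$array(c_vec),
    constraints = be$sp$LinearConstraint(
      be$np$array(A), be$np$array(con_lb), be$np$array(con_ub)),
    integrality = be$np$array(integrality),
    bounds = be$sp$Bounds(be$np$array(lb), be$np$array(ub))
  )
  status <- reticulate::py_to_r(res$status)
  if (status == 0) {
    list(status = "optimal", objective = reticulate::py_to_r(res$fun),
         x = as.numeric(reticulate::py_to_r(res$x)))
  } else if (status == 2) {
    list(status = "infeasible", objective = NA_real_, x = NULL)
  } else {
    stop("MILP solver failure (status ", status, ")")
  }
}
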