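# Independent brute-force oracles used to pin expected values.

# iMAT by enumeration: every satisfied-state assignment (high reactions can
# be satisfied forward or backward, low reactions by zero flux) is checked
# for LP feasibility; the optimum is the largest feasible satisfied count.
oracle_imat_enumerate <- function(model, states, overrides = NULL, eps = 1) {
  hi <- names(states)[states == "high"]
  lo <- names(states)[states == "low"]
  hi_opts <- rep(list(c("off", "fwd", "bwd")), length(hi))
  lo_opts <- rep(list(c("off", "on")), length(lo))
  grid <- expand.grid(c(hi_opts, lo_opts), stringsAsFactors = FALSE)
  if (nrow(grid) == 0) return(0L)
  best <- 0L
  for (g in seq_len(nrow(grid))) {
    asg <- unlist(grid[g, ], use.names = FALSE)
    ov <- overrides
    sat <- 0L
    for (k in seq_along(hi)) {
      if (asg[k] == "fwd") {
        ov <- rbind(ov, bound_overrides(hi[k], lower = eps))
        sat <- sat + 1L
      } else if (asg[k] == "bwd") {
        ov <- rbind(ov, bound_overrides(hi[k], upper = -eps))
        sat <- sat + 1L
      }
    }
    for (k in seq_along(lo)) {
      if (asg[length(hi) + k] == "on") {
        ov <- rbind(ov, bound_overrides(lo[k], lower = 0, upper = 0))
        sat <- sat + 1L
      }
    }
    if (sat <= best) next
    ok <- tryCatch(check_feasibility(model, ov), error = function(e) FALSE)
    if (ok) best <- sat
  }
  best
}

# FVA by vertex enumeration (pure linear algebra, no LP solver): vertices
# of {S v = 0, lb <= v <= ub} have n - rank(S) coordinates at a bound.
oracle_fva_vertices <- function(model, fixed = NULL, tol = 1e-9) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  names(lb) <- names(ub) <- model$reactions$id
  if (!is.null(fixed)) {
    lb[names(fixed)] <- ub[names(fixed)] <- unlist(fixed)
  }
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  vertices <- list()
  add_vertex <- function(v) vertices[[length(vertices) + 1L]] <<- v
  subsets <- if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  for (nb in subsets) {
    basis <- setdiff(seq_len(n), nb)
    Sb <- S[, basis, drop = FALSE]
    combos <- if (k == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    for (ci in seq_len(nrow(combos))) {
      v <- numeric(n)
      v[nb] <- ifelse(combos[ci, ] == 0, lb[nb], ub[nb])
      rhs <- -S[, nb, drop = FALSE] %*% v[nb]
      sol <- tryCatch(qr.solve(Sb, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[basis] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      add_vertex(v)
    }
  }
  if (length(vertices) == 0) stop("no feasible vertex found")
  V <- do.call(rbind, vertices)
  data.frame(reaction = model$reactions$id,
             v_min = apply(V, 2, min), v_max = apply(V, 2, max),
             stringsAsFactors = FALSE)
}

# upper-tail hypergeometric P(X >= overlap) by exhaustive enumeration of
# all active-set draws
oracle_hyper_enum <- function(N, n_active, n_pathway, overlap) {
  draws <- utils::combn(N, n_active, simplify = FALSE)
  pathway <- seq_len(n_pathway)
  hits <- vapply(draws, function(d) length(intersect(d, pathway)) >= overlap,
                 logical(1))
  mean(hits)
}

# random small toy network with a random reversible/irreversible mix,
# used for property tests
random_toy_states <- function(model, seed) {
  set.seed(seed)
  internal <- model$reactions$id[!model$reactions$is_exchange]
  stats::setNames(sample(c("low", "moderate", "high"), length(internal),
                         replace = TRUE), internal)
}

expect_feasible_scores <- function(sc) {
  if (!is.na(sc)) {
    expect_gte(sc, -1e-6)
    expect_lte(sc, 1 + 1e-6)
  }
}
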