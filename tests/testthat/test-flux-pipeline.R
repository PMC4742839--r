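test_that("QP fitting matches closed-form projections on TM1", {
  m <- tm1_model()
  fit0 <- fit_fluxes_qp(m, flux_measurements("EX_C", 7))
  expect_equal(fit0$consistency_score, 0, tolerance = 1e-4)
  expect_equal(fit0$fitted[["EX_C"]], 7, tolerance = 1e-4)

  fit1 <- fit_fluxes_qp(m, flux_measurements("EX_C", 12))
  expect_equal(fit1$fitted[["EX_C"]], 10, tolerance = 1e-4)
  expect_equal(fit1$consistency_score, 2, tolerance = 1e-4)

  fit2 <- fit_fluxes_qp(m, flux_measurements(c("EX_A", "EX_C"), c(10, 12)))
  expect_equal(fit2$fitted[["EX_A"]], 10, tolerance = 1e-4)
  expect_equal(fit2$fitted[["EX_C"]], 10, tolerance = 1e-4)
  expect_equal(fit2$consistency_score, 2, tolerance = 1e-4)

  expect_error(fit_fluxes_qp(m, flux_measurements("GHOST", 1)), "unknown")
  expect_error(flux_measurements(character(0), numeric(0)), "at least one")
  expect_error(flux_measurements("EX_C", NaN), "finite")
})

test_that("QP agrees with a dense grid search on the TM1 polytope", {
  # flux space: upper-path flux a (R_AB = R_BC), lower-path flux c (R_AC),
  # EX_A = EX_C = a + c, a, c >= 0, a + c <= 10
  grid <- expand.grid(a = seq(0, 10, 0.01), c = seq(0, 10, 0.01))
  grid <- grid[grid$a + grid$c <= 10, ]
  d2 <- (grid$a + grid$c - 10)^2 + (grid$a + grid$c - 12)^2
  want <- sqrt(min(d2))
  got <- fit_fluxes_qp(tm1_model(),
                       flux_measurements(c("EX_A", "EX_C"), c(10, 12)))
  expect_equal(got$consistency_score, want, tolerance = 1e-3)
})

test_that("consistency is zero exactly when measurements are feasible", {
  m <- tm1_model()
  feasible <- list(c(EX_C = 0), c(EX_C = 10), c(EX_A = 3, EX_C = 3),
                   c(EX_A = 10, EX_C = 10))
  for (mm in feasible) {
    fit <- fit_fluxes_qp(m, flux_measurements(names(mm), unname(mm)))
    expect_lt(fit$consistency_score, 1e-3)
  }
  infeasible <- list(c(EX_C = 11), c(EX_A = 2, EX_C = 9),
                     c(EX_A = -1, EX_C = 0))
  for (mm in infeasible) {
    fit <- fit_fluxes_qp(m, flux_measurements(names(mm), unname(mm)))
    expect_gt(fit$consistency_score, 1e-3)
  }
})

test_that("constrained FVA fixes measured reactions at fitted values", {
  m <- tm1_model()
  fit <- fit_fluxes_qp(m, flux_measurements("EX_C", 10))
  rng <- constrained_fva(m, fit)
  rr <- function(id) rng[rng$reaction == id, ]
  expect_equal(c(rr("EX_C")$v_min, rr("EX_C")$v_max),
               rep(fit$fitted[["EX_C"]], 2), tolerance = 1e-4)
  expect_equal(c(rr("R_AB")$v_min, rr("R_AB")$v_max), c(0, 10),
               tolerance = 1e-3)

  fit0 <- fit_fluxes_qp(m, flux_measurements("EX_C", 0))
  rng0 <- constrained_fva(m, fit0)
  internal <- rng0[rng0$reaction %in% c("R_AB", "R_AC", "R_BC"), ]
  expect_true(all(abs(internal$v_min) < 1e-3 & abs(internal$v_max) < 1e-3))
})

test_that("activity classification applies the |v| > threshold rule", {
  rng <- data.frame(reaction = c("a", "b", "c"),
                    v_min = c(-0.0005, 0, -2),
                    v_max = c(0.0009, 0.5, -0.1))
  cls <- classify_activity(rng, threshold = 0.001)
  expect_equal(cls$active, c(FALSE, TRUE, TRUE))
  expect_equal(attr(cls, "threshold"), 0.001)
  # monotone in the threshold: raising it never activates a reaction
  for (thr in c(0.01, 0.2, 1)) {
    cls2 <- classify_activity(rng, threshold = thr)
    expect_true(all(!cls2$active | cls$active))
  }
  expect_error(classify_activity(rng[0, ]), "empty")
})

test_that("pathway enrichment matches exhaustive enumeration", {
  # 10 reactions, pathway = first 4, 5 active, overlap 4
  cls <- structure(
    data.frame(reaction = paste0("r", 1:10),
               active = c(TRUE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5))),
    threshold = 0.001, class = c("activity_classification", "data.frame"))
  m <- make_toy_model(1, 1)  # only labels are used; build labels directly
  model_stub <- list(reactions = data.frame(
    id = paste0("r", 1:10),
    pathway = c(rep("P", 4), rep("other", 6)),
    stringsAsFactors = FALSE))
  enr <- pathway_enrichment(cls, model_stub)
  row <- enr[enr$pathway == "P", ]
  expect_equal(row$overlap_active, 4)
  expect_equal(row$p_active, 6 / 252, tolerance = 1e-12)
  expect_equal(row$p_active, oracle_hyper_enum(10, 5, 4, 4),
               tolerance = 1e-12)

  # same geometry with overlap 2
  cls2 <- cls
  cls2$active <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                   FALSE, FALSE, FALSE)
  enr2 <- pathway_enrichment(cls2, model_stub)
  expect_equal(enr2[enr2$pathway == "P", "p_active"], 186 / 252,
               tolerance = 1e-12)
  expect_equal(oracle_hyper_enum(10, 5, 4, 2), 186 / 252, tolerance = 1e-12)

  # random small cases against the enumeration oracle
  set.seed(11)
  for (rep in 1:6) {
    N <- sample(6:12, 1)
    k <- sample(2:(N - 2), 1)
    n_act <- sample(2:(N - 1), 1)
    act <- rep(FALSE, N); act[sample(N, n_act)] <- TRUE
    stub <- list(reactions = data.frame(
      id = paste0("r", 1:N),
      pathway = c(rep("P", k), rep("other", N - k)),
      stringsAsFactors = FALSE))
    cls3 <- structure(data.frame(reaction = paste0("r", 1:N), active = act),
                      threshold = 0.001,
                      class = c("activity_classification", "data.frame"))
    enr3 <- pathway_enrichment(cls3, stub)
    ov <- sum(act[1:k])
    expect_equal(enr3[enr3$pathway == "P", "p_active"],
                 oracle_hyper_enum(N, n_act, k, ov), tolerance = 1e-10)
  }
})

test_that("covariate correlation recovers a monotone association", {
  # v_max perfectly increasing with fat: rho = 1
  samples <- sprintf("s%d", 1:9)
  fat <- stats::setNames(seq(5, 75, length.out = 9), samples)
  ranges <- lapply(seq_along(samples), function(j) {
    data.frame(reaction = c("rx_up", "rx_flat"),
               v_min = 0, v_max = c(j, 1), stringsAsFactors = FALSE)
  })
  names(ranges) <- samples
  cc <- covariate_correlation(ranges, fat, n_perm = 199, seed = 4)
  expect_equal(cc$rho[cc$reaction == "rx_up"], 1)
  expect_true(is.na(cc$rho[cc$reaction == "rx_flat"]))
  expect_gte(min(cc$p_empirical, na.rm = TRUE), 1 / 200)

  expect_error(covariate_correlation(ranges[1:3], fat), "at least 4")
  expect_error(covariate_correlation(ranges, fat * 0 + 1), "constant")
})

test_that("the planted fat-coupled reaction ranks first in the fat screen", {
  sim <- simulate_flux_cohort(n_samples = 9, seed = 7)
  per_sample <- lapply(names(sim$measurements), function(sid) {
    fit <- fit_fluxes_qp(sim$model, sim$measurements[[sid]])
    constrained_fva(sim$model, fit)
  })
  names(per_sample) <- names(sim$measurements)
  cc <- covariate_correlation(per_sample, sim$covariate, n_perm = 199,
                              seed = 7)
  cc <- cc[!is.na(cc$rho), ]
  top <- cc$reaction[cc$q_fdr == min(cc$q_fdr)]
  # the planted pathway (and the total uptake it drives) owns the top of
  # the ranking; no uncoupled pathway reaction reaches it
  expect_true(all(sim$truth$fat_coupled_reactions %in% top))
  expect_true(all(top %in% c(sim$truth$fat_coupled_reactions, "EX_A")))
})

test_that("noise-free measurements give a significant consistency fit", {
  m <- tm1_model()
  true_state <- c(EX_A = 6, R_AB = 4, R_AC = 2, R_BC = 4, EX_C = 6)
  mm <- simulate_flux_measurements(m, true_state, noise_sd = 0,
                                   measured_subset = c("EX_A", "EX_C",
                                                       "R_AC"),
                                   seed = 11)
  res <- consistency_pvalue(m, mm, n_random = 200, seed = 11)
  expect_lt(res$observed_score, 1e-4)
  # random uniform sets are almost never exactly feasible (they must hit
  # the EX_A = EX_C coupling), so only the observed set fits perfectly
  expect_lte(res$p_value, 0.01)
  # degenerate envelope: every random set equals the observed one
  mm2 <- flux_measurements(c("EX_A", "EX_C"), c(5, 5))
  res2 <- consistency_pvalue(m, mm2, n_random = 50, seed = 1)
  expect_equal(res2$p_value, 1)
})

test_that("LOOCV predicts chain fluxes exactly and degrades gracefully", {
  # a chain with amplifying stoichiometry (A -> 2B -> 6C): every flux is
  # uniquely determined by any one of them, with distinct measured values
  chain <- metabolic_model(
    data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
               compartment = "c"),
    data.frame(id = c("EX_A", "R1", "R2", "EX_C"),
               lower_bound = 0, upper_bound = c(10, 100, 100, 100),
               pathway = c("exchange", "chain", "chain", "exchange"),
               gpr = ""),
    list(EX_A = c(A = 1), R1 = c(A = -1, B = 2), R2 = c(B = -1, C = 3),
         EX_C = c(C = -1)))
  v <- c(EX_A = 2, R1 = 2, R2 = 4, EX_C = 12)
  mm <- simulate_flux_measurements(chain, v, 0, c("R1", "R2", "EX_C"),
                                   seed = 2)
  cv <- loocv_fluxes(chain, mm)
  expect_equal(cv$pairs$predicted, cv$pairs$observed, tolerance = 1e-4)
  expect_equal(cv$rho, 1)
  expect_error(loocv_fluxes(chain, mm[1:2, ]), "at least 3")
})

test_that("dropping a measurement never worsens the QP fit", {
  m <- tm1_model()
  mm <- flux_measurements(c("EX_A", "EX_C", "R_AC"), c(10, 12, 8))
  full <- fit_fluxes_qp(m, mm)$consistency_score
  for (i in 1:3) {
    sub <- fit_fluxes_qp(m, mm[-i, ])$consistency_score
    expect_lte(sub, full + 1e-6)
  }
})
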