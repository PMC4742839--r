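test_that("activity score reproduces the enumeration-derived TM1 cases", {
  f <- metabolic_function("secrete_C", "EX_C")
  m <- tm1_model()
  a <- function_activity_score(m, f, c(R_AB = "high", R_AC = "low",
                                       R_BC = "high"))
  expect_equal(a$A_i, 10, tolerance = 1e-6)
  expect_equal(a$A_ij, 10, tolerance = 1e-6)
  expect_equal(a$score, 1.0, tolerance = 1e-6)

  m2 <- tm1_model()
  m2$reactions$upper_bound[m2$reactions$id == "R_AC"] <- 4
  a2 <- function_activity_score(m2, f, c(R_AB = "low", R_AC = "high",
                                         R_BC = "low"))
  expect_equal(a2$A_i, 10, tolerance = 1e-6)
  # any optimally consistent state shuts the upper pathway, leaving the
  # capacity-4 route
  expect_equal(a2$A_ij, 4, tolerance = 1e-6)
  expect_equal(a2$score, 0.4, tolerance = 1e-6)

  blocked <- metabolic_function("blocked", "EX_C",
                                bound_overrides("EX_C", upper = 0))
  b <- function_activity_score(m, blocked, c(R_AB = "high"))
  expect_true(b$blocked)
  expect_true(is.na(b$score))
})

test_that("adaptability score reproduces the enumeration-derived TM1 cases", {
  f <- metabolic_function("secrete_C", "EX_C")
  m2 <- tm1_model()
  m2$reactions$upper_bound[m2$reactions$id == "R_AC"] <- 4
  # enforcement EX_C >= 5 exceeds the lower pathway's capacity, so the
  # 'low' upper pathway must fire: only 1 of 3 states stays satisfied
  ad <- function_adaptability_score(m2, f, c(R_AB = "low", R_AC = "high",
                                             R_BC = "low"))
  expect_equal(ad$F, 3L)
  expect_equal(ad$Fa, 1L)
  expect_equal(ad$score, 1 / 3, tolerance = 1e-9)
  expect_equal(ad$enforced_bound, 5)

  m <- tm1_model()
  ad2 <- function_adaptability_score(m, f, c(R_AB = "high", R_AC = "low",
                                             R_BC = "high"))
  expect_equal(ad2$score, 1.0)

  ad3 <- function_adaptability_score(m, f, c(R_AB = "moderate"))
  expect_true(is.na(ad3$score))  # F = 0 guard

  # the enforcement bound comes from the unconstrained model (EX_C >= 5);
  # a constraint set capping uptake below that makes enforcement
  # infeasible: score 0 with a warning
  f_cap <- metabolic_function("capped", "EX_C",
                              bound_overrides("EX_A", upper = 3))
  expect_warning(
    ad4 <- function_adaptability_score(
      m, f_cap, c(R_AB = "high", R_AC = "low", R_BC = "high")),
    "infeasible")
  expect_equal(ad4$score, 0)
  expect_true(ad4$infeasible_enforcement)
})

test_that("scores are ratios in [0, 1] on randomized triples", {
  seed <- 3000
  for (rep in 1:40) {
    seed <- seed + 1
    set.seed(seed)
    m <- make_toy_model(sample(2:3, 1), sample(2:3, 1))
    cat_ <- toy_function_catalogue(m)
    f <- cat_[[sample(length(cat_), 1)]]
    states <- random_toy_states(m, seed)
    a <- function_activity_score(m, f, states)
    ad <- function_adaptability_score(m, f, states)
    expect_feasible_scores(a$score)
    expect_feasible_scores(ad$score)
    if (!is.na(a$score)) expect_lte(a$A_ij, a$A_i + 1e-6)
    if (!is.na(ad$score) && !ad$infeasible_enforcement) {
      expect_lte(ad$Fa, ad$F)
    }
  }
})

test_that("adaptability is monotone in enforcement severity", {
  f <- metabolic_function("secrete_C", "EX_C")
  m2 <- tm1_model()
  m2$reactions$upper_bound[m2$reactions$id == "R_AC"] <- 4
  states <- c(R_AB = "low", R_AC = "high", R_BC = "low")
  prev <- Inf
  for (frac in c(0.3, 0.5, 0.7, 0.9)) {
    sc <- suppressWarnings(function_adaptability_score(
      m2, f, states, enforce_fraction = frac))$score
    expect_lte(sc, prev + 1e-9)
    prev <- sc
  }
})

test_that("catalogue YAML round-trips and validates", {
  m <- make_toy_model(3, 2)
  cat_ <- toy_function_catalogue(m)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_function_catalogue(cat_, path)
  cat2 <- read_function_catalogue(path)
  expect_equal(length(cat2), length(cat_))
  expect_equal(names(cat2), names(cat_))
  expect_equal(cat2$f_pathway1$target_reaction,
               cat_$f_pathway1$target_reaction)
  expect_no_error(validate_catalogue(cat2, m))

  bad <- function_catalogue(list(metabolic_function("x", "NOPE")))
  expect_error(validate_catalogue(bad, m), "not in model")
  bad2 <- function_catalogue(list(
    metabolic_function("x", "EX_C", bound_overrides("EX_C", lower = 11))))
  expect_error(validate_catalogue(bad2, m), "infeasible")
  expect_error(
    function_catalogue(list(metabolic_function("x", "EX_C"),
                            metabolic_function("x", "EX_A"))),
    "duplicate")
})

test_that("the shipped liver catalogue has 22 uniquely named functions", {
  cat_ <- default_function_catalogue()
  expect_length(cat_, 22)
  expect_equal(anyDuplicated(names(cat_)), 0)
  for (f in cat_) {
    expect_true(nzchar(f$target_reaction))
    expect_true(nzchar(f$description))
  }
  # the gluconeogenesis-from-lactate entry allows only lactate uptake
  gng <- cat_$gng_from_lactate
  expect_true("EX_lac_L(e)" %in% gng$constraints$reaction)
  closed <- gng$constraints[gng$constraints$reaction != "EX_lac_L(e)", ]
  expect_true(all(closed$lower == 0))
})

test_that("profile_functionality emits one row per sample and function", {
  m <- make_toy_model(2, 2)
  cat_ <- toy_function_catalogue(m)
  spec <- synthetic_cohort_spec(n_high = 2, n_low = 2, seed = 5,
                                n_background_genes = 20)
  cohort <- simulate_expression_cohort(m, spec, cat_)
  prof <- profile_functionality(m, cat_, cohort$profiles)
  expect_equal(nrow(prof), 4 * length(cat_))
  expect_true(all(prof$activity >= -1e-6 & prof$activity <= 1 + 1e-6,
                  na.rm = TRUE))
  wide <- functionality_wide(prof)
  expect_equal(dim(wide), c(4, 2 * length(cat_)))

  empty <- profile_functionality(m, cat_, list())
  expect_equal(nrow(empty), 0)
})
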