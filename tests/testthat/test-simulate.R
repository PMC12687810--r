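test_that("name generator honors parity, uniqueness and feasibility", {
  nm <- generate_lipid_names(5, 0, classes = "LPG", seed = 2)
  expect_length(nm, 5L)
  expect_true(all(vapply(nm, chain_parity, character(1L)) == "odd"))

  nm0 <- generate_lipid_names(0, 0, seed = 2)
  expect_length(nm0, 0L)

  expect_error(
    generate_lipid_names(3, 0, classes = "cholesterol", seed = 2),
    "cannot yield odd-parity"
  )
  expect_error(generate_lipid_names(1, 1, classes = "QQQ"), "unknown class")

  # exclusion lets batches combine without key collisions
  a <- generate_lipid_names(0, 20, classes = c("LPC", "LPE"), seed = 3)
  b <- generate_lipid_names(0, 10,
    classes = c("LPC", "LPE"), seed = 4,
    exclude = vapply(a, canonical_key, character(1L))
  )
  expect_equal(anyDuplicated(vapply(c(a, b), canonical_key, character(1L))), 0L)
})

test_that("identical config and seed give identical datasets", {
  cfg <- sim_config("origin", seed = 77)
  s1 <- simulate_origin_experiment(cfg)
  s2 <- simulate_origin_experiment(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)

  cfgp <- sim_config("perturbation", seed = 78)
  p1 <- simulate_perturbation_experiment(cfgp)
  p2 <- simulate_perturbation_experiment(cfgp)
  expect_identical(p1$matrix$values, p2$matrix$values)
  expect_identical(p1$truth, p2$truth)
})

test_that("noise-free limit reproduces configured group means exactly", {
  cfg <- sim_config("origin",
    n_diet = 5, n_host = 5, n_microbial = 5, cv = 0,
    missing_rate = 0, sample_scaling_cv = 0, include_standards = FALSE,
    seed = 5
  )
  sim <- simulate_origin_experiment(cfg)
  x <- sim$matrix
  conv <- x$values[, x$samples$group == "Conv", drop = FALSE]
  gf <- x$values[, x$samples$group == "GF", drop = FALSE]
  diet <- x$values[, x$samples$group == "Diet", drop = FALSE]
  expect_equal(unname(log(rowMeans(conv))), sim$truth$log_mean_conv)
  expect_equal(unname(log(rowMeans(gf))), sim$truth$log_mean_gf)
  expect_equal(unname(log(rowMeans(diet))), sim$truth$log_mean_diet)
  # microbial features carry the configured fold difference
  micro <- sim$truth$origin == "microbial"
  expect_equal(
    unname(rowMeans(conv)[micro] / rowMeans(gf)[micro]),
    rep(cfg$microbial_fd, sum(micro))
  )
})

test_that("realized log-SD matches the configured noise model", {
  cfg <- sim_config("origin",
    n_diet = 1000, n_host = 0, n_microbial = 0,
    odd_fraction = c(diet = 0.5, host = 0, microbial = 0),
    n_per_group = 2, cv = 0.2, missing_rate = 0,
    sample_scaling_cv = 0, include_standards = FALSE, seed = 19
  )
  sim <- simulate_origin_experiment(cfg)
  x <- sim$matrix
  conv <- x$values[, x$samples$group == "Conv"]
  resid <- log(conv) - sim$truth$log_mean_conv
  expect_equal(sd(as.numeric(resid)), log(1 + 0.2), tolerance = 0.1)
})

test_that("restoration fraction anchors are exact in the noise-free limit", {
  base_cfg <- function(frac) {
    sim_config("perturbation",
      n_decreased = 5, n_increased = 3, n_null = 2,
      restoration_fraction = frac, cv = 0, missing_rate = 0,
      sample_scaling_cv = 0, include_standards = FALSE, seed = 8
    )
  }
  full <- simulate_perturbation_experiment(base_cfg(1))
  expect_equal(full$truth$log_mean_r, full$truth$log_mean_c)
  none <- simulate_perturbation_experiment(base_cfg(0))
  expect_equal(none$truth$log_mean_r, none$truth$log_mean_t)
  # emitted values follow the truth exactly at cv = 0
  x <- full$matrix
  r <- x$values[, x$samples$group == "CMT", drop = FALSE]
  expect_equal(unname(log(rowMeans(r))), full$truth$log_mean_r)
})

test_that("missingness is biased toward low abundances", {
  cfg <- sim_config("origin",
    n_diet = 300, n_host = 0, n_microbial = 300,
    odd_fraction = c(diet = 0.5, host = 0, microbial = 0.5),
    missing_rate = 0.15, include_standards = FALSE, seed = 33
  )
  sim <- simulate_origin_experiment(cfg)
  x <- sim$matrix
  rate <- mean(is.na(x$values))
  expect_equal(rate, 0.15, tolerance = 0.25)
  # cells in the low half of the expected-abundance range go missing more
  lm_mat <- cbind(
    matrix(sim$truth$log_mean_conv, nrow(x$values), 6),
    matrix(sim$truth$log_mean_gf, nrow(x$values), 6),
    matrix(sim$truth$log_mean_diet, nrow(x$values), 6)
  )
  lo <- lm_mat < median(lm_mat)
  expect_gt(mean(is.na(x$values[lo])), mean(is.na(x$values[!lo])))
})

test_that("unrestored plants keep the treated level", {
  cfg <- sim_config("perturbation",
    n_decreased = 10, n_increased = 4, n_null = 6,
    n_decreased_unrestored = 4, n_increased_unrestored = 2,
    cv = 0, missing_rate = 0, sample_scaling_cv = 0,
    include_standards = FALSE, seed = 13
  )
  sim <- simulate_perturbation_experiment(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$restored), 8L)
  un <- !tr$restored & tr$direction != "null"
  expect_equal(tr$log_mean_r[un], tr$log_mean_t[un])
  expect_equal(
    sort(unique(tr$expected_category)),
    sort(c(
      "decreased_restored", "decreased_not_restored",
      "increased_restored", "increased_not_restored", "unchanged"
    ))
  )
})
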