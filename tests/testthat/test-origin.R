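test_that("fold differences are pseudocounted ratios", {
  expect_equal(fold_difference(10, 1), 10)
  expect_equal(fold_difference(7, 7), 1)
  expect_equal(fold_difference(10, 0, pseudocount = 0.1), 10.1 / 0.1)
  expect_error(fold_difference(-1, 2), "non-negative")
  expect_error(fold_difference(10, 0), "pseudocount")
})

test_that("welch_test matches the textbook formula and flags degeneracy", {
  a <- c(1, 1.1, 0.9)
  b <- c(10, 10.5, 9.8)
  p <- welch_test(a, b, on_log = FALSE)
  expect_equal(as.numeric(p), oracle_welch_p(a, b), tolerance = 1e-6)
  expect_false(attr(p, "degenerate"))

  p_log <- welch_test(a, b, on_log = TRUE)
  expect_equal(as.numeric(p_log), oracle_welch_p(log(a), log(b)),
    tolerance = 1e-6
  )

  same <- welch_test(c(1, 2, 3), c(1, 2, 3), on_log = FALSE)
  expect_equal(as.numeric(same), 1, tolerance = 1e-12)

  degen <- welch_test(c(5, 5, 5), c(5, 5, 5), on_log = FALSE)
  expect_equal(as.numeric(degen), 1)
  expect_true(attr(degen, "degenerate"))

  expect_error(welch_test(1, c(1, 2)), "2 present values")
})

test_that("call_gmpl flags planted microbial features and not flat ones", {
  withr::local_seed(101)
  feats <- generate_lipid_names(2, 2)
  lm <- cbind(
    conv = c(log(1000), log(50), log(1000), log(50)),
    gf = c(log(100), log(50), log(100), log(50)),
    diet = c(log(100), log(50), log(100), log(50))
  )
  x <- make_group_matrix(lm, c("Conv", "GF", "Diet"), 6, feats, sdlog = 0.1)
  calls <- call_gmpl(x, pseudocount = 0.01)
  planted <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(calls$significant_gmpl, planted)
  expect_equal(calls$parity_stratum, c("odd", "odd", "even", "even"))
  # parity bookkeeping: odd + even significant counts equal the total
  s <- gmpl_summary(calls)
  expect_equal(
    s$n_significant_odd + s$n_significant_even, s$n_significant_gmpl
  )
  expect_error(
    call_gmpl(x, groups = c(conv = "Conv", gf = "GF", diet = "Chow")),
    "Chow"
  )
})

test_that("call_gmpl equals the brute-force oracle on small instances", {
  withr::local_seed(42)
  for (trial in 1:25) {
    n_feat <- sample(3:8, 1)
    feats <- generate_lipid_names(0, n_feat)
    vals <- matrix(rlnorm(n_feat * 12, meanlog = 2, sdlog = 1), n_feat)
    rownames(vals) <- feats
    groups <- rep(c("Conv", "GF", "Diet"), each = 4)
    x <- make_lipidome(vals, groups)
    calls <- call_gmpl(x, fd_threshold = 2, alpha = 0.1, pseudocount = 0.5)
    orc <- oracle_gmpl(vals, groups, "Conv", "GF", "Diet",
      fd_threshold = 2, alpha = 0.1, pseudocount = 0.5
    )
    expect_equal(calls$fd_conv_gf, unname(orc[, "fd_cg"]), tolerance = 1e-12)
    expect_equal(calls$p_value, unname(orc[, "p"]), tolerance = 1e-9)
    expect_equal(calls$significant_gmpl, orc[, "sig"] == 1)
  }
})

test_that("GMPL counts are monotone in the thresholds", {
  sim <- simulate_origin_experiment(sim_config("origin", seed = 9))
  xn <- normalize_to_standards(sim$matrix)
  counts_fd <- vapply(
    c(1, 2, 5, 10, 20),
    function(fd) sum(call_gmpl(xn, fd_threshold = fd)$significant_gmpl),
    numeric(1L)
  )
  expect_true(all(diff(counts_fd) <= 0))
  counts_alpha <- vapply(
    c(0.1, 0.05, 0.01, 0.001, 1e-4),
    function(a) sum(call_gmpl(xn, alpha = a)$significant_gmpl),
    numeric(1L)
  )
  expect_true(all(diff(counts_alpha) <= 0))
})

test_that("tripartition labels constructed signature blocks exactly", {
  withr::local_seed(7)
  feats <- generate_lipid_names(9, 9)
  # z-signatures: diet block high in diet; host high in both cecal groups;
  # microbial high only in conventional
  lm <- rbind(
    matrix(rep(c(log(30), log(30), log(1000)), each = 6), 6, byrow = FALSE),
    matrix(rep(c(log(1000), log(1000), log(30)), each = 6), 6, byrow = FALSE),
    matrix(rep(c(log(1000), log(30), log(30)), each = 6), 6, byrow = FALSE)
  )
  x <- make_group_matrix(lm, c("Conv", "GF", "Diet"), 6, feats, sdlog = 0.05)
  xt <- transform_for_clustering(x)
  labels <- cluster_tripartition(xt)
  truth <- rep(c("diet_derived", "host_produced", "microbial"), each = 6)
  expect_equal(as.character(labels), truth)
})

test_that("tripartition is invariant to feature and sample permutations", {
  sim <- simulate_origin_experiment(
    sim_config("origin",
      n_diet = 12, n_host = 8, n_microbial = 8, missing_rate = 0, seed = 15
    )
  )
  xn <- normalize_to_standards(sim$matrix)
  xt <- transform_for_clustering(xn)
  lab1 <- cluster_tripartition(xt)

  withr::local_seed(1)
  fperm <- sample.int(nrow(xt$values))
  sperm <- sample.int(ncol(xt$values))
  xp <- make_lipidome(
    xt$values[fperm, sperm],
    xt$samples$group[sperm],
    feature_names = rownames(xt$values)[fperm],
    log_scale = TRUE
  )
  lab2 <- cluster_tripartition(xp)
  expect_equal(
    as.character(lab2[names(lab1)]),
    as.character(lab1)
  )
})

test_that("tripartition validates k", {
  sim <- simulate_origin_experiment(
    sim_config("origin", n_diet = 4, n_host = 4, n_microbial = 4, seed = 2)
  )
  xt <- transform_for_clustering(normalize_to_standards(sim$matrix))
  expect_error(cluster_tripartition(xt, k = 1), "k must be")
  expect_error(cluster_tripartition(xt, k = 1000), "k must be")
})
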