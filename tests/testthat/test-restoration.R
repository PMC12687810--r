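test_that("volcano calls detect planted depletion and skip flat features", {
  withr::local_seed(3)
  feats <- generate_lipid_names(2, 2)
  lm <- cbind(
    t = c(log(25), log(100), log(25), log(100)),
    c = c(log(100), log(100), log(100), log(100))
  )
  x <- make_group_matrix(lm, c("T", "C"), 6, feats, sdlog = log(1.1))
  tab <- volcano_call(x, "T", "C", pseudocount = 1e-6)
  expect_equal(tab$altered, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tab$log2fc[1], -2, tolerance = 0.3)
  expect_equal(tab$direction, c("down", "none", "down", "none"))
  expect_error(volcano_call(x, "T", "Z"), "Z")
})

test_that("BH adjustment follows the step-up rule", {
  withr::local_seed(8)
  feats <- generate_lipid_names(0, 6)
  vals <- matrix(rlnorm(6 * 8), 6, dimnames = list(feats, NULL))
  x <- make_lipidome(vals, rep(c("A", "B"), each = 4))
  tab <- volcano_call(x, "A", "B")
  # independent step-up computation
  m <- length(tab$pvalue)
  o <- order(tab$pvalue, decreasing = TRUE)
  expected <- numeric(m)
  running <- 1
  for (i in seq_along(o)) {
    rank <- m - i + 1
    running <- min(running, tab$pvalue[o[i]] * m / rank)
    expected[o[i]] <- running
  }
  expect_equal(tab$padj, expected, tolerance = 1e-12)
})

test_that("restoration index hits its analytic anchors", {
  expect_equal(restoration_index(10, 2, 10), 1)
  expect_equal(restoration_index(10, 2, 2), 0)
  expect_equal(restoration_index(10, 2, 6), 0.5)
  # affine invariance: index unchanged under joint a*x + b
  set.seed(4)
  for (i in 1:20) {
    m <- rnorm(3)
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    expect_equal(
      restoration_index(m[1], m[2], m[3]),
      restoration_index(a * m[1] + b, a * m[2] + b, a * m[3] + b)
    )
  }
  expect_error(restoration_index(5, 5, 7), "undefined")
})

test_that("restoration categories are exhaustive and correct on plants", {
  withr::local_seed(12)
  feats <- generate_lipid_names(3, 2)
  base <- log(1000)
  dep <- base - log(8)
  lm <- cbind(
    c = rep(base, 5),
    t = c(dep, dep, base + log(8), base, base),
    r = c(
      dep + 0.6 * (base - dep), # decreased, 60% restored
      dep + 0.2 * (base - dep), # decreased, weakly restored
      base + 0.4 * log(8), # increased, 60% restored
      base, base
    )
  )
  x <- make_group_matrix(
    lm, c("C", "1P", "CMT"), 6, feats,
    sdlog = log(1.05)
  )
  calls <- classify_restoration(x, pseudocount = 1e-9)
  expect_equal(calls$category, c(
    "decreased_restored", "decreased_not_restored", "increased_restored",
    "unchanged", "unchanged"
  ))
  expect_equal(calls$restoration_index[1], 0.6, tolerance = 0.1)
  expect_true(all(is.na(calls$restoration_index[4:5])))
  # categories partition the features
  s <- restoration_summary(calls)
  expect_equal(sum(unlist(s$counts)), nrow(calls))
  # direction invariant: decreased implies negative log2fc
  expect_true(all(calls$log2fc_t[grepl("^decreased", calls$category)] < 0))
  expect_true(all(calls$log2fc_t[grepl("^increased", calls$category)] > 0))
})

test_that("restored counts are monotone in the restore threshold", {
  sim <- simulate_perturbation_experiment(
    sim_config("perturbation", seed = 31)
  )
  xn <- normalize_to_standards(sim$matrix)
  n_restored <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(thr) {
    calls <- classify_restoration(xn, restore_threshold = thr)
    sum(grepl("_restored$", calls$category) &
      !grepl("not_restored$", calls$category))
  }, numeric(1L))
  expect_true(all(diff(n_restored) <= 0))
})

test_that("concordance reports overlap, direction and Fisher p", {
  feats <- paste0("LPG(", seq(11, 29, 2), ":0)")
  tab <- make_diff_table(
    feats,
    log2fc = c(-2, -2, 2, 0, 0, 0, 0, 0, 0, 0),
    pvalue = c(0.001, 0.001, 0.001, rep(0.9, 7))
  )
  res <- concordance(tab, tab)
  expect_equal(res$n_shared_altered, 3L)
  expect_equal(res$percent_direction_concordant, 100)
  expect_lt(res$fisher_p, 0.01)

  # direction discordance is counted
  tab2 <- tab
  tab2$log2fc[1] <- 2
  res2 <- concordance(tab, tab2)
  expect_equal(res2$n_shared_altered, 3L)
  expect_equal(res2$n_direction_concordant, 2L)

  expect_error(
    concordance(tab, make_diff_table("PG(30:0)", 0, 1)), "universe"
  )
})

test_that("Fisher p matches the exhaustive hypergeometric oracle", {
  # contingency (shared=20, a-only=8, b-only=11, neither=461)
  universe <- paste0("PC(", 30:529, ":0)")
  a_set <- universe[1:28]
  b_set <- universe[c(1:20, 29:39)]
  tab_a <- make_diff_table(universe, 1, ifelse(universe %in% a_set, 0.001, 1))
  tab_b <- make_diff_table(universe, 1, ifelse(universe %in% b_set, 0.001, 1))
  res <- concordance(tab_a, tab_b)
  expect_equal(unname(res$contingency[1, 1]), 20)
  expect_equal(
    res$fisher_p, oracle_fisher_two_sided(20, 8, 11, 461),
    tolerance = 1e-9
  )
})

test_that("null concordance Fisher p-values are calibrated", {
  # Fisher's exact test is discrete and conservative, so its null p-values
  # are stochastically >= uniform rather than exactly uniform: check
  # P(p <= alpha) <= alpha (within Monte-Carlo error) across an alpha grid.
  withr::local_seed(99)
  universe <- paste0("PC(", 30:529, ":0)")
  ps <- vapply(1:200, function(i) {
    alt_a <- runif(500) < 0.1
    alt_b <- runif(500) < 0.1
    tab_a <- make_diff_table(universe, 1, ifelse(alt_a, 0.001, 1))
    tab_b <- make_diff_table(universe, 1, ifelse(alt_b, 0.001, 1))
    concordance(tab_a, tab_b)$fisher_p
  }, numeric(1L))
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
  # and p-values do spread across the unit interval
  expect_gt(mean(ps > 0.5), 0.25)
})

test_that("venn partition does set algebra correctly", {
  perturbed <- make_diff_table(c("g1", "g2", "g3"), -1.5, 0.001)
  r1 <- make_diff_table(c("g2", "g4"), c(1.5, 1.5), c(0.001, 0.001))
  r2 <- make_diff_table("g3", 1.5, 0.001)
  part <- deg_restoration_partition(
    perturbed, list(A = r1, B = r2)
  )
  expect_setequal(part$region_I, "g1")
  expect_setequal(part$regions[["perturbed&A"]], "g2")
  expect_setequal(part$regions[["perturbed&B"]], "g3")
  expect_setequal(part$regions[["A"]], "g4")
  expect_equal(sum(part$sizes), part$n_union)
  expect_equal(part$direction_tallies$perturbed$down, 3L)

  # rescue arms with nothing altered leave the whole perturbed set in region I
  none <- make_diff_table("g9", 0, 1)
  part2 <- deg_restoration_partition(perturbed, list(A = none, B = none))
  expect_setequal(part2$region_I, c("g1", "g2", "g3"))

  dup <- make_diff_table(c("g1", "g1"), 1, 0.001)
  expect_error(deg_restoration_partition(dup, list(A = r1)), "duplicated")
})

test_that("venn regions match a brute-force enumeration on random sets", {
  withr::local_seed(55)
  ids <- paste0("g", 1:20)
  for (i in 1:100) {
    mk <- function() {
      sel <- ids[runif(20) < 0.4]
      make_diff_table(ids, sample(c(-2, 2), 20, replace = TRUE),
        ifelse(ids %in% sel, 0.001, 0.9)
      )
    }
    perturbed <- mk()
    rescued <- list(A = mk(), B = mk())
    part <- deg_restoration_partition(perturbed, rescued)
    sets <- list(
      perturbed = ids[perturbed$pvalue < 0.05],
      A = ids[rescued$A$pvalue < 0.05],
      B = ids[rescued$B$pvalue < 0.05]
    )
    expected <- oracle_venn(sets)
    expect_equal(part$regions[sort(names(part$regions))],
      expected[sort(names(expected))]
    )
    expect_equal(sum(part$sizes), part$n_union)
  }
})
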