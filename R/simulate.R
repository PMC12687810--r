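# Synthetic lipidome generator with known ground truth.
#
# Two study designs are emulated:
#   * origin  — conventional / germ-free / diet profiles with three feature
#     strata: diet-derived (high in diet, partially carried into both cecal
#     groups), host-produced (high in both cecal groups, background in
#     diet), and microbial (high only in conventional cecal contents).
#   * perturbation — control / treated / restored profiles in which treated
#     samples deplete or enrich designated features and the restored group
#     interpolates between treated and control on the log scale.
#
# Abundances are lognormal: each feature draws a baseline level, group
# effects act multiplicatively, and measurement noise is multiplicative with
# per-observation log-SD log(1 + CV).  A per-sample efficiency factor
# multiplies whole columns (including the spiked internal standards), which
# internal-standard normalization must remove.  Missingness is applied
# preferentially to low-abundance cells via a probit link on log abundance,
# mimicking left censoring.  Every dataset ships with a ground-truth table.

#' Generate grammatical shorthand lipid names with requested parity
#'
#' Draws random species names from the built-in class vocabulary with
#' odd-parity names guaranteed to contain at least one odd-carbon chain and
#' even-parity names only even chains.  All names parse round-trip and have
#' unique canonical keys; none carry isotope labels (those are reserved for
#' internal standards).
#'
#' @param n_odd,n_even Number of odd- and even-parity names.
#' @param classes Class codes to draw from (default: the multi-purpose
#'   phospholipid/sphingolipid/glycerolipid classes).
#' @param exclude Canonical keys that must not be generated (for combining
#'   several batches without collisions).
#' @param seed Optional seed.
#' @return Character vector of `n_odd + n_even` names, odd first; parities
#'   in `attr(, "parity")`.
#' @export
generate_lipid_names <- function(n_odd, n_even,
                                 classes = c(
                                   "PC", "PE", "PS", "PG", "PI", "PA",
                                   "LPC", "LPE", "LPG", "SM", "SL", "Cer",
                                   "TG", "DG", "MG"
                                 ),
                                 exclude = character(0), seed = NULL) {
  stopifnot(n_odd >= 0, n_even >= 0)
  vocab <- lipid_class_vocabulary()
  unknown_ok <- setdiff(classes, names(vocab))
  n_chains <- ifelse(classes %in% names(vocab), vocab[classes], 2L)
  if (any(n_chains == 0L) && n_odd > 0) {
    .stopf(
      "classes without acyl chains cannot yield odd-parity names: %s",
      paste(classes[n_chains == 0L], collapse = ", ")
    )
  }
  if (length(unknown_ok)) {
    # unknown classes are allowed but parsed as 'other'; keep them out of
    # the generator so parity is always chain-resolved
    .stopf(
      "unknown class code(s) for the generator: %s",
      paste(unknown_ok, collapse = ", ")
    )
  }

  odd_c <- seq(11L, 19L, by = 2L)
  even_c <- seq(12L, 22L, by = 2L)

  .with_seed(seed, {
    make_one <- function(parity) {
      cls <- sample(classes, 1L)
      k <- vocab[[cls]]
      carbons <- sample(even_c, k, replace = TRUE)
      if (parity == "odd") {
        n_odd_chains <- sample(seq_len(k), 1L)
        carbons[seq_len(n_odd_chains)] <- sample(
          odd_c, n_odd_chains,
          replace = TRUE
        )
      }
      dbl <- vapply(
        carbons,
        function(cc) sample(0:min(4L, cc %/% 4L), 1L),
        integer(1L)
      )
      paste0(
        cls, "(", paste(carbons, ":", dbl, sep = "", collapse = "_"), ")"
      )
    }
    draw <- function(n, parity, taken) {
      out <- character(0)
      attempts <- 0L
      while (length(out) < n) {
        attempts <- attempts + 1L
        if (attempts > 200L * max(n, 1L)) {
          .stopf("could not generate %d unique %s-parity names", n, parity)
        }
        nm <- make_one(parity)
        key <- canonical_key(nm)
        if (!(key %in% taken)) {
          taken <- c(taken, key)
          out <- c(out, nm)
        }
      }
      list(names = out, taken = taken)
    }
    odd <- draw(n_odd, "odd", exclude)
    even <- draw(n_even, "even", odd$taken)
    nm <- c(odd$names, even$names)
    structure(nm, parity = rep(c("odd", "even"), c(n_odd, n_even)))
  })
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic generators.  The
#' defaults are the package's reference study conditions: 6 samples per
#' group, lognormal baselines around 1e6 with between-feature log-SD 1,
#' multiplicative noise at CV 0.2, a 10-fold microbial enrichment in
#' conventional samples, 4-fold perturbation effects with restoration
#' fraction 0.7, 5% missingness biased toward low abundances, a per-sample
#' efficiency spread of CV 0.2, and spiked internal standards included.
#'
#' @param design `"origin"` or `"perturbation"`.
#' @param n_diet,n_host,n_microbial Feature counts per origin stratum
#'   (origin design).
#' @param odd_fraction Named numeric: fraction of odd-parity names per
#'   stratum (origin) or overall (perturbation).
#' @param n_decreased,n_increased,n_null Feature counts (perturbation
#'   design); `n_decreased_unrestored`, `n_increased_unrestored` carve out
#'   altered features whose restored-group mean stays at the treated level.
#' @param n_per_group Samples per group.
#' @param group_labels Character vector of 3 group labels
#'   (origin: conventional, germ-free, diet; perturbation: control,
#'   treated, restored).
#' @param baseline_log_mean,baseline_log_sd Natural-log location/spread of
#'   per-feature baseline abundances.
#' @param microbial_fd Fold enrichment of microbial features in conventional
#'   over germ-free/diet (origin design; default 10).
#' @param diet_carryover Fraction of a diet-derived feature's dietary level
#'   seen in cecal samples (default 0.3).
#' @param background_fraction Background level of an "absent" stratum as a
#'   fraction of baseline (default 0.05) — not a structural zero, so
#'   pseudocount logic is exercised.
#' @param depletion_fd,enrichment_fd Perturbation fold effects (default 4).
#' @param restoration_fraction Log-scale interpolation of the restored group
#'   from treated toward control, in `[0, 1]` (default 0.7).
#' @param cv Multiplicative noise coefficient of variation; per-observation
#'   log-SD is `log(1 + cv)`.
#' @param missing_rate Overall expected fraction of missing cells
#'   (default 0.05).
#' @param sample_scaling_cv CV of the per-sample efficiency factor
#'   (default 0.2).
#' @param include_standards Spike the internal-standard mix (default TRUE).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(design = c("origin", "perturbation"),
                       n_diet = 50, n_host = 30, n_microbial = 20,
                       odd_fraction = c(
                         diet = 0.2, host = 0.1, microbial = 0.7
                       ),
                       n_decreased = 40, n_increased = 10, n_null = 50,
                       n_decreased_unrestored = 0,
                       n_increased_unrestored = 0,
                       n_per_group = 6,
                       group_labels = NULL,
                       baseline_log_mean = log(1e6), baseline_log_sd = 1,
                       microbial_fd = 10, diet_carryover = 0.3,
                       background_fraction = 0.05,
                       depletion_fd = 4, enrichment_fd = 4,
                       restoration_fraction = 0.7,
                       cv = 0.2, missing_rate = 0.05,
                       sample_scaling_cv = 0.2,
                       include_standards = TRUE, seed = 1L) {
  design <- match.arg(design)
  if (is.null(group_labels)) {
    group_labels <- if (design == "origin") {
      c("Conv", "GF", "Diet")
    } else {
      c("C", "1P", "CMT")
    }
  }
  if (length(group_labels) != 3L || anyDuplicated(group_labels)) {
    .stopf("group_labels must be 3 distinct labels")
  }
  cfg <- list(
    design = design,
    n_diet = n_diet, n_host = n_host, n_microbial = n_microbial,
    odd_fraction = odd_fraction,
    n_decreased = n_decreased, n_increased = n_increased, n_null = n_null,
    n_decreased_unrestored = n_decreased_unrestored,
    n_increased_unrestored = n_increased_unrestored,
    n_per_group = n_per_group,
    group_labels = group_labels,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    microbial_fd = microbial_fd, diet_carryover = diet_carryover,
    background_fraction = background_fraction,
    depletion_fd = depletion_fd, enrichment_fd = enrichment_fd,
    restoration_fraction = restoration_fraction,
    cv = cv, missing_rate = missing_rate,
    sample_scaling_cv = sample_scaling_cv,
    include_standards = include_standards,
    seed = seed
  )
  with(cfg, {
    stopifnot(
      n_diet >= 0, n_host >= 0, n_microbial >= 0,
      n_decreased >= 0, n_increased >= 0, n_null >= 0,
      n_decreased_unrestored >= 0, n_increased_unrestored >= 0,
      n_decreased_unrestored <= n_decreased,
      n_increased_unrestored <= n_increased,
      n_per_group >= 2,
      microbial_fd > 0, depletion_fd > 0, enrichment_fd > 0,
      diet_carryover > 0, background_fraction > 0,
      restoration_fraction >= 0, restoration_fraction <= 1,
      cv >= 0, missing_rate >= 0, missing_rate < 1,
      sample_scaling_cv >= 0
    )
  })
  structure(cfg, class = "sim_config")
}

# draw noisy observations: expected log-mean matrix (feature x sample) ->
# values with multiplicative noise and per-sample scaling
.sim_values <- function(log_means, cv, scaling) {
  sdlog <- log(1 + cv)
  noise <- matrix(
    stats::rnorm(length(log_means), 0, sdlog),
    nrow = nrow(log_means)
  )
  exp(log_means + noise) * rep(scaling, each = nrow(log_means))
}

# left-censoring missingness: probability rises for low log abundance via a
# probit link, rescaled to hit the overall target rate
.apply_missingness <- function(vals, rate) {
  if (rate <= 0) {
    return(vals)
  }
  lv <- log(vals)
  z <- (lv - mean(lv)) / max(stats::sd(lv), 1e-12)
  w <- stats::pnorm(-z)
  p <- pmin(rate * w / mean(w), 1)
  vals[stats::runif(length(vals)) < p] <- NA_real_
  vals
}

# spike the internal-standard mix: constant amount per sample, measured with
# the same per-sample efficiency factor
.standard_block <- function(n_samples, scaling, level = 5e5) {
  names <- splash_standard_names()
  vals <- matrix(level, nrow = length(names), ncol = n_samples)
  vals <- vals * rep(scaling, each = length(names))
  rownames(vals) <- names
  vals
}

.sample_ids <- function(labels, n_per_group) {
  unlist(lapply(labels, function(g) {
    paste0(gsub("[^A-Za-z0-9]", "", g), "_", seq_len(n_per_group))
  }))
}

#' Simulate a conventional / germ-free / diet origin experiment
#'
#' Generates a raw-scale lipidome with three planted origin strata (see
#' [sim_config()]) and the matching ground truth.  Group expectations on the
#' natural-log scale: diet-derived features sit at baseline in diet samples
#' and at `diet_carryover * baseline` in both cecal groups; host features at
#' baseline in both cecal groups and `background_fraction * baseline` in
#' diet; microbial features at baseline in conventional samples and
#' `baseline / microbial_fd` in germ-free and diet.
#'
#' @param config A `sim_config` with `design = "origin"`.
#' @return List with `matrix` (raw `lipidome`, standards included when
#'   configured) and `truth` (data frame: `feature`, `origin`, `parity`,
#'   `log_mean_conv`, `log_mean_gf`, `log_mean_diet`, `is_gmpl`).
#' @export
simulate_origin_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$design == "origin")
  cfg <- config
  .with_seed(cfg$seed, {
    strata <- c(
      rep("diet_derived", cfg$n_diet),
      rep("host_produced", cfg$n_host),
      rep("microbial", cfg$n_microbial)
    )
    n_odd_by <- function(n, frac) round(n * frac)
    counts <- c(diet = cfg$n_diet, host = cfg$n_host,
      microbial = cfg$n_microbial
    )
    nm <- character(0)
    parities <- character(0)
    taken <- character(0)
    for (s in c("diet", "host", "microbial")) {
      n <- counts[[s]]
      if (n == 0L) next
      no <- n_odd_by(n, cfg$odd_fraction[[s]])
      g <- generate_lipid_names(no, n - no, exclude = taken)
      taken <- c(taken, vapply(g, canonical_key, character(1L)))
      nm <- c(nm, g)
      parities <- c(parities, attr(g, "parity"))
    }
    n_feat <- length(nm)

    base <- stats::rnorm(n_feat, cfg$baseline_log_mean, cfg$baseline_log_sd)
    lm_conv <- lm_gf <- lm_diet <- base
    is_diet <- strata == "diet_derived"
    is_host <- strata == "host_produced"
    is_micro <- strata == "microbial"
    lm_conv[is_diet] <- base[is_diet] + log(cfg$diet_carryover)
    lm_gf[is_diet] <- base[is_diet] + log(cfg$diet_carryover)
    lm_diet[is_host] <- base[is_host] + log(cfg$background_fraction)
    lm_gf[is_micro] <- base[is_micro] - log(cfg$microbial_fd)
    lm_diet[is_micro] <- base[is_micro] - log(cfg$microbial_fd)

    labels <- cfg$group_labels
    npg <- cfg$n_per_group
    log_means <- cbind(
      matrix(lm_conv, n_feat, npg),
      matrix(lm_gf, n_feat, npg),
      matrix(lm_diet, n_feat, npg)
    )
    scaling <- exp(stats::rnorm(3 * npg, 0, log(1 + cfg$sample_scaling_cv)))
    vals <- .sim_values(log_means, cfg$cv, scaling)
    vals <- .apply_missingness(vals, cfg$missing_rate)
    rownames(vals) <- nm
    colnames(vals) <- .sample_ids(labels, npg)

    if (cfg$include_standards) {
      vals <- rbind(vals, .standard_block(ncol(vals), scaling))
    }
    meta <- data.frame(
      sample_id = colnames(vals),
      group = rep(labels, each = npg),
      stringsAsFactors = FALSE
    )
    mat <- lipidome(vals, meta)
    truth <- data.frame(
      feature = vapply(nm, canonical_key, character(1L), USE.NAMES = FALSE),
      origin = strata,
      parity = parities,
      log_mean_conv = lm_conv,
      log_mean_gf = lm_gf,
      log_mean_diet = lm_diet,
      is_gmpl = is_micro,
      stringsAsFactors = FALSE
    )
    list(matrix = mat, truth = truth, config = cfg)
  })
}

#' Simulate a control / treated / restored perturbation experiment
#'
#' Treated samples multiply designated features by the configured
#' depletion/enrichment fold effects; the restored group's log mean
#' interpolates from the treated level back toward control by
#' `restoration_fraction` (1 = full return, 0 = none).  Features listed as
#' unrestored stay at the treated level in the restored group.
#'
#' @param config A `sim_config` with `design = "perturbation"`.
#' @return List with `matrix` (raw `lipidome`) and `truth` (data frame:
#'   `feature`, `parity`, `direction` (`"decreased"`/`"increased"`/
#'   `"null"`), `restored`, `expected_category`, plus the three log means).
#' @export
simulate_perturbation_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$design == "perturbation")
  cfg <- config
  .with_seed(cfg$seed, {
    n_feat <- cfg$n_decreased + cfg$n_increased + cfg$n_null
    direction <- c(
      rep("decreased", cfg$n_decreased),
      rep("increased", cfg$n_increased),
      rep("null", cfg$n_null)
    )
    restored <- rep(FALSE, n_feat)
    if (cfg$n_decreased > 0) {
      restored[seq_len(cfg$n_decreased - cfg$n_decreased_unrestored)] <- TRUE
    }
    if (cfg$n_increased > 0) {
      i0 <- cfg$n_decreased
      restored[i0 + seq_len(cfg$n_increased - cfg$n_increased_unrestored)] <-
        TRUE
    }

    frac_odd <- if (is.null(names(cfg$odd_fraction))) {
      cfg$odd_fraction[[1L]]
    } else {
      mean(cfg$odd_fraction)
    }
    no <- round(n_feat * frac_odd)
    g <- generate_lipid_names(no, n_feat - no)
    # interleave so parity is independent of planted direction
    ord <- sample.int(n_feat)
    nm <- g[ord]
    parities <- attr(g, "parity")[ord]

    base <- stats::rnorm(n_feat, cfg$baseline_log_mean, cfg$baseline_log_sd)
    lm_c <- base
    lm_t <- base
    lm_t[direction == "decreased"] <-
      base[direction == "decreased"] - log(cfg$depletion_fd)
    lm_t[direction == "increased"] <-
      base[direction == "increased"] + log(cfg$enrichment_fd)
    frac <- ifelse(direction == "null", 0,
      ifelse(restored, cfg$restoration_fraction, 0)
    )
    lm_r <- lm_t + frac * (lm_c - lm_t)

    labels <- cfg$group_labels
    npg <- cfg$n_per_group
    log_means <- cbind(
      matrix(lm_c, n_feat, npg),
      matrix(lm_t, n_feat, npg),
      matrix(lm_r, n_feat, npg)
    )
    scaling <- exp(stats::rnorm(3 * npg, 0, log(1 + cfg$sample_scaling_cv)))
    vals <- .sim_values(log_means, cfg$cv, scaling)
    vals <- .apply_missingness(vals, cfg$missing_rate)
    rownames(vals) <- nm
    colnames(vals) <- .sample_ids(labels, npg)
    if (cfg$include_standards) {
      vals <- rbind(vals, .standard_block(ncol(vals), scaling))
    }
    meta <- data.frame(
      sample_id = colnames(vals),
      group = rep(labels, each = npg),
      stringsAsFactors = FALSE
    )
    mat <- lipidome(vals, meta)

    expected_category <- ifelse(
      direction == "null", "unchanged",
      paste0(
        direction, ifelse(restored, "_restored", "_not_restored")
      )
    )
    truth <- data.frame(
      feature = vapply(nm, canonical_key, character(1L), USE.NAMES = FALSE),
      parity = parities,
      direction = direction,
      restored = restored,
      expected_category = expected_category,
      log_mean_c = lm_c,
      log_mean_t = lm_t,
      log_mean_r = lm_r,
      stringsAsFactors = FALSE
    )
    list(matrix = mat, truth = truth, config = cfg)
  })
}
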