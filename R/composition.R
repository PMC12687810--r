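# Compositional statistics: Bray-Curtis dissimilarity between samples and
# (pairwise) PERMANOVA with permutation p-values.
#
# The PERMANOVA pseudo-F follows the direct distance-based formulation:
# with N samples, a groups of sizes n_g, squared distances d_ij^2,
#   SS_total  = sum_{i<j} d_ij^2 / N
#   SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g
#   F = ((SS_total - SS_within) / (a - 1)) / (SS_within / (N - a)).
# p-values use the conservative (1 + exceedances) / (1 + permutations)
# convention, or exact enumeration when the number of distinct label
# assignments is small.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`: 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 2, 3), c(3, 2, 1)) # 1/3
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    .stopf("vectors must have equal length")
  }
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    .stopf("Bray-Curtis requires non-negative abundances")
  }
  x[is.na(x)] <- 0
  y[is.na(y)] <- 0
  tot <- sum(x + y)
  if (tot == 0) {
    .stopf("Bray-Curtis is undefined for two all-zero vectors")
  }
  sum(abs(x - y)) / tot
}

#' Bray-Curtis distance matrix over the samples of a lipidome
#'
#' Computed on raw-scale (normalized) abundances, the ecological convention;
#' missing cells are treated as zero abundance.
#'
#' @param x A `lipidome`, or a plain feature x sample matrix.
#' @return A `dist` object over samples.
#' @export
bray_curtis_matrix <- function(x) {
  vals <- if (inherits(x, "lipidome")) {
    if (x$log_scale) {
      .stopf("Bray-Curtis expects raw-scale abundances, not z-scores")
    }
    x$values
  } else {
    as.matrix(x)
  }
  if (any(vals < 0, na.rm = TRUE)) {
    .stopf("Bray-Curtis requires non-negative abundances")
  }
  vals[is.na(vals)] <- 0
  s <- colSums(vals)
  if (any(s == 0)) {
    .stopf(
      "all-zero sample(s): %s",
      paste(colnames(vals)[s == 0], collapse = ", ")
    )
  }
  man <- as.matrix(stats::dist(t(vals), method = "manhattan"))
  bc <- man / outer(s, s, "+")
  stats::as.dist(bc)
}

# squared-distance matrix and group index list -> pseudo-F
.permanova_F <- function(d2, group_idx, n, a) {
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(group_idx, function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1L)))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# enumerate all distinct assignments of group sizes to positions 1..n;
# returns a list of integer vectors (positions of each group, concatenated
# in group order) -- used for exact permutation tests on small designs
.enumerate_assignments <- function(sizes, positions = NULL) {
  n <- sum(sizes)
  if (is.null(positions)) {
    positions <- seq_len(n)
  }
  if (length(sizes) == 1L) {
    return(list(list(positions)))
  }
  first <- utils::combn(positions, sizes[1L], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- .enumerate_assignments(sizes[-1L], setdiff(positions, f))
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

# number of distinct assignments: multinomial coefficient
.n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F is
#' computed from total and within-group sums of squared distances, and its
#' null distribution by permuting group labels.  When the number of distinct
#' label assignments is at most `exhaustive_cap`, the exact permutation
#' distribution is enumerated instead of sampled; otherwise `n_permutations`
#' random permutations are drawn from `seed` and
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`, which can never
#' be zero.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param labels Group labels, one per sample (>= 2 groups, each of size
#'   >= 2).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream (recorded in the
#'   result); required for reproducible p-values.
#' @param exhaustive_cap Enumerate exactly when the distinct-assignment
#'   count is at most this (default 10000).
#' @return List of class `permanova`: `pseudo_F`, `p_value`, `method`
#'   (`"exhaustive"`/`"sampled"`), `n_permutations`, `seed`, `df_between`,
#'   `df_within`, `n_samples`, `groups`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                      exhaustive_cap = 10000) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (length(labels) != n) {
    .stopf("labels length (%d) != number of samples (%d)", length(labels), n)
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) {
    .stopf("PERMANOVA needs at least 2 groups")
  }
  if (any(sizes < 2L)) {
    .stopf(
      "every group needs >= 2 samples; too small: %s",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    )
  }
  a <- length(sizes)
  d2 <- dm^2
  groups <- split(seq_len(n), labels)
  f_obs <- .permanova_F(d2, groups, n, a)
  eps <- 1e-12

  n_distinct <- .n_assignments(as.numeric(sizes))
  if (n_distinct <= exhaustive_cap) {
    assigns <- .enumerate_assignments(as.integer(sizes))
    f_all <- vapply(assigns, function(gidx) {
      .permanova_F(d2, gidx, n, a)
    }, numeric(1L))
    p <- mean(f_all >= f_obs - eps)
    method <- "exhaustive"
    n_perm <- length(f_all)
  } else {
    f_perm <- .with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        perm <- sample.int(n)
        .permanova_F(d2, split(perm, labels), n, a)
      }, numeric(1L))
    })
    p <- (1 + sum(f_perm >= f_obs - eps)) / (1 + n_permutations)
    method <- "sampled"
    n_perm <- n_permutations
  }

  structure(
    list(
      pseudo_F = f_obs,
      p_value = p,
      method = method,
      n_permutations = n_perm,
      seed = seed,
      df_between = a - 1L,
      df_within = n - a,
      n_samples = n,
      groups = as.list(sizes)
    ),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g [%s, %d permutations]\n",
    x$pseudo_F, x$df_between, x$df_within, x$p_value, x$method,
    x$n_permutations
  ))
  invisible(x)
}

#' Pairwise PERMANOVA with BH adjustment
#'
#' Runs [permanova()] on the sub-distance-matrix of every unordered pair of
#' groups and adjusts the p-value family by Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return Data frame: `group_a`, `group_b`, `pseudo_F`, `p_value`,
#'   `p_adjusted`, `method`, `n_permutations`.
#' @export
pairwise_permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                               exhaustive_cap = 10000) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  if (length(gs) < 2L) {
    .stopf("pairwise PERMANOVA needs at least 2 groups")
  }
  pairs <- utils::combn(gs, 2L, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    idx <- which(labels %in% pr)
    res <- permanova(
      dm[idx, idx, drop = FALSE], labels[idx],
      n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else seed + i,
      exhaustive_cap = exhaustive_cap
    )
    data.frame(
      group_a = pr[1L], group_b = pr[2L],
      pseudo_F = res$pseudo_F, p_value = res$p_value,
      method = res$method, n_permutations = res$n_permutations,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c(
    "group_a", "group_b", "pseudo_F", "p_value", "p_adjusted",
    "method", "n_permutations"
  )]
}
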