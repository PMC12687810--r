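# Lipid origin deconvolution: the dual fold-difference + Welch-test caller
# for gut microbially-produced lipids (GMPLs), and the hierarchical-cluster
# tripartition of a conventional/germ-free/diet lipidome into diet-derived,
# host-produced and microbially-produced strata.
#
# The two routes are deliberately independent outputs: the cluster
# tripartition reflects global abundance signatures, the threshold caller a
# per-compound criterion (fold difference of conventional over germ-free and
# over diet both above a threshold, with Welch-test significance).  Both are
# reported, together with their intersection, by `gmpl_summary()`.

#' Pseudocounted fold difference of two group means
#'
#' `(numerator + pseudocount) / (denominator + pseudocount)`.  A positive
#' pseudocount keeps the ratio finite when a compound is absent from the
#' denominator group.
#'
#' @param numerator_mean,denominator_mean Non-negative group means
#'   (vectorized).
#' @param pseudocount Non-negative value added to both terms; must be
#'   positive if any denominator is zero.
#' @return Numeric ratio(s), strictly positive and finite.
#' @examples
#' fold_difference(10, 1) # 10
#' fold_difference(10, 0, pseudocount = 0.1) # 101
#' @export
fold_difference <- function(numerator_mean, denominator_mean,
                            pseudocount = 0) {
  if (any(numerator_mean < 0, na.rm = TRUE) ||
      any(denominator_mean < 0, na.rm = TRUE) || pseudocount < 0) {
    .stopf("fold_difference requires non-negative means and pseudocount")
  }
  fd <- (numerator_mean + pseudocount) / (denominator_mean + pseudocount)
  if (any(!is.finite(fd))) {
    .stopf("zero denominator in fold_difference; use a positive pseudocount")
  }
  fd
}

#' Two-sided Welch unequal-variance t-test
#'
#' Thin wrapper around the Welch test used throughout the pipeline, with the
#' multiplicative-noise default of testing on the log scale.  Degenerate
#' inputs (both groups constant) return p = 1 when the constants are equal,
#' p = 0 otherwise, flagged via `attr(, "degenerate")`.
#'
#' @param values_a,values_b Numeric abundance vectors (NA dropped); each
#'   group needs at least 2 present values.
#' @param on_log Test `log(value + pseudocount)` instead of raw values
#'   (default TRUE).
#' @param pseudocount Added before the log when `on_log` (default 0).
#' @return Two-sided p-value, with attribute `degenerate`.
#' @export
welch_test <- function(values_a, values_b, on_log = TRUE, pseudocount = 0) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    .stopf("welch_test needs at least 2 present values per group")
  }
  if (on_log) {
    if (any(a + pseudocount <= 0) || any(b + pseudocount <= 0)) {
      .stopf("non-positive values on log scale; increase the pseudocount")
    }
    a <- log(a + pseudocount)
    b <- log(b + pseudocount)
  }
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  p <- if (degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  structure(p, degenerate = degenerate)
}

# group means on the (imputed) raw scale, one row per feature
.group_mean_matrix <- function(x, group_cols) {
  vapply(
    group_cols,
    function(idx) rowMeans(x$values[, idx, drop = FALSE]),
    numeric(nrow(x$values))
  )
}

# vector of Welch p-values between two column sets, on log scale by default
.welch_by_row <- function(values, idx_a, idx_b, on_log, pseudocount) {
  apply(values, 1L, function(v) {
    as.numeric(welch_test(v[idx_a], v[idx_b],
      on_log = on_log, pseudocount = pseudocount
    ))
  })
}

#' Call gut microbially-produced lipids by dual fold difference + Welch test
#'
#' For every feature, computes group means in the conventional, germ-free and
#' diet groups, the pseudocounted fold differences FD(conv/GF) and
#' FD(conv/diet), and a two-sided Welch p-value for conventional vs germ-free
#' (on the log scale by default).  A feature is a significant GMPL when both
#' fold differences exceed `fd_threshold` and p < `alpha`.
#'
#' Missing cells are imputed by [impute_missing()] first; fold differences
#' use raw-scale means with a pseudocount (half the global minimum positive
#' value unless given).  No multiple-testing correction is applied by
#' default, matching the raw-p convention of the calling criterion; set
#' `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param x A normalized `lipidome` containing the three groups.
#' @param groups Named character vector with entries `conv`, `gf`, `diet`
#'   giving the group labels in the sample metadata.
#' @param fd_threshold Fold-difference threshold (default 5).
#' @param alpha Significance level (default 0.05).
#' @param on_log Welch test on log abundances (default TRUE).
#' @param adjust Apply BH adjustment to the p-values before thresholding
#'   (default FALSE).
#' @param pseudocount Pseudocount for fold differences and the log transform;
#'   default half the global minimum positive value.
#' @param cluster_labels Optional named vector from [cluster_tripartition()]
#'   to merge into the output (`cluster_label` column); otherwise
#'   `"unassigned"`.
#' @return Data frame of origin calls: `feature`, `mean_conv`, `mean_gf`,
#'   `mean_diet`, `fd_conv_gf`, `fd_conv_diet`, `p_value`, `significant_gmpl`,
#'   `parity`, `parity_stratum`, `cluster_label`.
#' @export
call_gmpl <- function(x, groups = c(conv = "Conv", gf = "GF", diet = "Diet"),
                      fd_threshold = 5, alpha = 0.05, on_log = TRUE,
                      adjust = FALSE, pseudocount = NULL,
                      cluster_labels = NULL) {
  stopifnot(inherits(x, "lipidome"))
  if (x$log_scale) {
    .stopf("call_gmpl expects raw-scale (normalized) abundances")
  }
  if (!all(c("conv", "gf", "diet") %in% names(groups))) {
    .stopf("`groups` must name 'conv', 'gf' and 'diet' labels")
  }
  cols <- .group_columns(x, groups[c("conv", "gf", "diet")])
  x <- impute_missing(x)
  if (is.null(pseudocount)) {
    pseudocount <- .min_positive(x$values) / 2
  }

  means <- .group_mean_matrix(x, cols)
  p <- .welch_by_row(x$values, cols$conv, cols$gf, on_log, pseudocount)
  if (adjust) {
    p <- stats::p.adjust(p, method = "BH")
  }
  fd_cg <- fold_difference(means[, "conv"], means[, "gf"], pseudocount)
  fd_cd <- fold_difference(means[, "conv"], means[, "diet"], pseudocount)

  key <- x$features$canonical_key
  cl <- rep("unassigned", length(key))
  if (!is.null(cluster_labels)) {
    hit <- match(key, names(cluster_labels))
    cl[!is.na(hit)] <- cluster_labels[hit[!is.na(hit)]]
  }

  data.frame(
    feature = key,
    mean_conv = means[, "conv"],
    mean_gf = means[, "gf"],
    mean_diet = means[, "diet"],
    fd_conv_gf = fd_cg,
    fd_conv_diet = fd_cd,
    p_value = p,
    significant_gmpl = fd_cg > fd_threshold & fd_cd > fd_threshold &
      p < alpha,
    parity = x$features$parity,
    parity_stratum = parity_stratum(x$features$parity),
    cluster_label = cl,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Summarize GMPL calls by parity stratum and cluster label
#'
#' @param calls Output of [call_gmpl()].
#' @return List with total features, significant GMPL counts overall and by
#'   parity stratum, cluster-label counts, and the intersection of
#'   cluster-microbial and threshold-significant features.
#' @export
gmpl_summary <- function(calls) {
  sig <- calls[calls$significant_gmpl, , drop = FALSE]
  list(
    n_features = nrow(calls),
    n_significant_gmpl = nrow(sig),
    n_significant_odd = sum(sig$parity_stratum == "odd"),
    n_significant_even = sum(sig$parity_stratum == "even"),
    cluster_counts = as.list(table(calls$cluster_label)),
    n_cluster_microbial_and_significant = sum(
      calls$cluster_label == "microbial" & calls$significant_gmpl
    )
  )
}

#' Tripartition a lipidome by unsupervised hierarchical clustering
#'
#' Features (rows of a [transform_for_clustering()] z-score matrix) are
#' clustered by Euclidean distance and agglomerative linkage, the tree is cut
#' into `k` clusters, and each cluster is labeled by its group-mean z-score
#' signature:
#' \itemize{
#'   \item `diet_derived` — the diet-group mean z is the maximum;
#'   \item `microbial` — the conventional-group mean z is the maximum and
#'     the germ-free mean z is below 0;
#'   \item `host_produced` — both conventional and germ-free means exceed
#'     the diet mean;
#'   \item `unassigned` — none of the above.
#' }
#' Rules are applied in that order.
#'
#' @param x A `lipidome` transformed via [transform_for_clustering()].
#' @param groups Named character vector with `conv`, `gf`, `diet` labels.
#' @param k Number of clusters to cut (default 3).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"ward.D2"`; `"complete"` and the other hclust methods are accepted).
#'   Ward linkage on z-scored profiles yields balanced signature blocks,
#'   whereas complete linkage can peel off small outlier sub-clusters at
#'   low `k` and merge biologically distinct blocks.
#' @return Named character vector: canonical feature key -> cluster label,
#'   with the integer cluster ids in `attr(, "cluster_id")`.
#' @export
cluster_tripartition <- function(x,
                                 groups = c(
                                   conv = "Conv", gf = "GF", diet = "Diet"
                                 ),
                                 k = 3, linkage = "ward.D2") {
  stopifnot(inherits(x, "lipidome"))
  if (!x$log_scale) {
    .stopf("cluster_tripartition expects a transform_for_clustering() matrix")
  }
  if (k < 2 || k > nrow(x$values)) {
    .stopf("k must be between 2 and the number of features")
  }
  cols <- .group_columns(x, groups[c("conv", "gf", "diet")])

  hc <- stats::hclust(stats::dist(x$values), method = linkage)
  id <- stats::cutree(hc, k = k)

  labels <- vapply(seq_len(k), function(cl) {
    rows <- which(id == cl)
    gm <- vapply(
      cols,
      function(idx) mean(x$values[rows, idx, drop = FALSE]),
      numeric(1L)
    )
    if (gm[["diet"]] == max(gm)) {
      "diet_derived"
    } else if (gm[["conv"]] == max(gm) && gm[["gf"]] < 0) {
      "microbial"
    } else if (gm[["conv"]] > gm[["diet"]] && gm[["gf"]] > gm[["diet"]]) {
      "host_produced"
    } else {
      "unassigned"
    }
  }, character(1L))

  out <- stats::setNames(labels[id], x$features$canonical_key)
  attr(out, "cluster_id") <- stats::setNames(id, x$features$canonical_key)
  out
}
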