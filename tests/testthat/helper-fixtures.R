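# shared fixture builders

# lipidome from a plain matrix: auto sample ids "g1_1, g1_2, ..." per group
make_lipidome <- function(values, groups, feature_names = rownames(values),
                          normalized = TRUE, log_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    ids <- unlist(lapply(unique(groups), function(g) {
      paste0(g, "_", seq_len(sum(groups == g)))
    }))
    colnames(values) <- ids
  }
  lipidome(
    values,
    stats::setNames(groups, colnames(values)),
    feature_names = feature_names,
    normalized = normalized,
    log_scale = log_scale
  )
}

# three-group matrix with per-group log means; rows named by `features`
make_group_matrix <- function(log_means, groups_per_col, n_per_group,
                              features, sdlog = 0) {
  stopifnot(ncol(log_means) == length(groups_per_col))
  n_feat <- nrow(log_means)
  cols <- do.call(cbind, lapply(seq_along(groups_per_col), function(j) {
    matrix(log_means[, j], n_feat, n_per_group)
  }))
  noise <- matrix(rnorm(length(cols), 0, sdlog), nrow = n_feat)
  vals <- exp(cols + noise)
  rownames(vals) <- features
  groups <- rep(groups_per_col, each = n_per_group)
  make_lipidome(vals, groups)
}

# quick diff table
make_diff_table <- function(feature, log2fc, pvalue, padj = pvalue) {
  data.frame(
    feature = feature, log2fc = log2fc, pvalue = pvalue, padj = padj,
    stringsAsFactors = FALSE
  )
}
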