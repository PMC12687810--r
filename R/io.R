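# Lipidome matrices: construction, delimited-text I/O, internal-standard
# normalization, missing-value imputation and the clustering transform.
#
# A `lipidome` is a feature x sample abundance matrix plus a per-feature
# annotation table (from the nomenclature parser) and per-sample metadata
# (sample_id -> group).  Raw abundances are non-negative; missing
# measurements are NA.  Two flags track the processing state: `normalized`
# (internal standards divided out and removed) and `log_scale` (values are
# row-wise z-scores of log abundances, for clustering only).

#' Construct a lipidome matrix
#'
#' @param values Numeric feature x sample matrix, non-negative, with `NA`
#'   marking missing measurements.  Row names are shorthand lipid names,
#'   column names sample ids (or supply `feature_names`).
#' @param sample_groups Either a named character vector (sample id -> group
#'   label) or a data frame with columns `sample_id` and `group`.
#' @param feature_names Optional character vector of feature names
#'   (defaults to `rownames(values)`).
#' @param normalized,log_scale Processing-state flags; see Details.
#' @return An object of class `lipidome`: list with `values`, `features`
#'   (annotation table, see [parse_lipid_names()]), `samples` (data frame
#'   `sample_id`, `group`), `normalized`, `log_scale`.
#' @export
lipidome <- function(values, sample_groups, feature_names = rownames(values),
                     normalized = FALSE, log_scale = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    .stopf("feature names are required (row names or `feature_names`)")
  }
  if (length(feature_names) != nrow(values)) {
    .stopf("feature_names length does not match the number of rows")
  }
  dup <- feature_names[duplicated(feature_names)]
  if (length(dup)) {
    .stopf("duplicate feature names: %s", paste(unique(dup), collapse = ", "))
  }
  if (is.null(colnames(values))) {
    .stopf("the abundance matrix must carry sample ids as column names")
  }
  if (!log_scale && any(values < 0, na.rm = TRUE)) {
    .stopf("raw-scale abundances must be non-negative")
  }

  if (is.data.frame(sample_groups)) {
    if (!all(c("sample_id", "group") %in% names(sample_groups))) {
      .stopf("sample metadata needs columns 'sample_id' and 'group'")
    }
    meta <- data.frame(
      sample_id = as.character(sample_groups$sample_id),
      group = as.character(sample_groups$group),
      stringsAsFactors = FALSE
    )
  } else {
    meta <- data.frame(
      sample_id = names(sample_groups),
      group = as.character(sample_groups),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(meta$sample_id)) {
    .stopf("duplicate sample ids in metadata")
  }
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta)) {
    .stopf(
      "samples missing from metadata: %s",
      paste(missing_meta, collapse = ", ")
    )
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  rownames(values) <- feature_names
  features <- parse_lipid_names(feature_names)

  structure(
    list(
      values = values,
      features = features,
      samples = meta,
      normalized = isTRUE(normalized),
      log_scale = isTRUE(log_scale)
    ),
    class = "lipidome"
  )
}

#' @export
print.lipidome <- function(x, ...) {
  cat(sprintf(
    "<lipidome> %d features x %d samples | groups: %s | normalized=%s log_scale=%s | %d internal standards | %d missing cells\n",
    nrow(x$values), ncol(x$values),
    paste(sort(unique(x$samples$group)), collapse = "/"),
    x$normalized, x$log_scale,
    sum(x$features$is_internal_standard),
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.lipidome <- function(x) dim(x$values)

# detect the field delimiter of a delimited text file (tab beats comma)
.detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read an abundance matrix and its sample metadata
#'
#' Reads a delimited text matrix (first column feature names, header row
#' sample ids) and a metadata table mapping every sample id to a group.
#' Feature names are parsed with [parse_lipid_name()].  Zero and empty cells
#' are recorded as missing when `zero_as_missing` is set (the default),
#' following the usual left-censoring reading of zero MS intensities.
#'
#' @param matrix_path,metadata_path Paths to delimited text files (TSV or
#'   CSV; the delimiter is auto-detected unless `delim` is given).
#' @param delim Optional explicit delimiter.
#' @param zero_as_missing Treat zeros/blanks as missing (default TRUE).
#' @return A [lipidome()] object.
#' @export
read_lipidome <- function(matrix_path, metadata_path, delim = NULL,
                          zero_as_missing = TRUE) {
  sep_m <- if (is.null(delim)) .detect_delim(matrix_path) else delim
  tab <- utils::read.table(
    matrix_path,
    header = TRUE, sep = sep_m, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  feature_names <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"

  sep_d <- if (is.null(delim)) .detect_delim(metadata_path) else delim
  meta <- utils::read.table(
    metadata_path,
    header = TRUE, sep = sep_d, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  if (!all(c("sample_id", "group") %in% names(meta))) {
    names(meta)[1:2] <- c("sample_id", "group")
  }

  if (zero_as_missing) {
    vals[!is.na(vals) & vals == 0] <- NA_real_
  }
  lipidome(vals, meta[, c("sample_id", "group")],
    feature_names = feature_names
  )
}

#' Write a lipidome to delimited text
#'
#' Writes the abundance matrix and the sample metadata as TSV, with full
#' numeric precision so a write/read round trip reproduces the object.
#'
#' @param x A `lipidome`.
#' @param matrix_path,metadata_path Output paths.
#' @return `x`, invisibly.
#' @export
write_lipidome <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "lipidome"))
  vals <- x$values
  chr <- matrix(
    ifelse(is.na(vals), "NA", sprintf("%.17g", vals)),
    nrow = nrow(vals), dimnames = dimnames(vals)
  )
  out <- data.frame(feature = rownames(vals), chr,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, matrix_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(x$samples, metadata_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(x)
}

#' Normalize abundances to class-matched internal standards
#'
#' Divides each feature's abundance in each sample by the abundance of the
#' isotope-labeled internal standard mapped to the feature's lipid class in
#' the same sample, then removes the standard features.  Classes with no
#' mapped standard fall back to the designated default standard (the
#' PC-class standard unless overridden), since the one-per-class standard
#' mix covers fewer classes than a typical lipidome spans.
#'
#' @param x A raw-scale `lipidome` containing its internal standards.
#' @param class_map Optional named character vector, lipid class ->
#'   canonical key of the standard to use.  Defaults to the standards found
#'   in the matrix, keyed by their own class.
#' @param default_standard Canonical key of the fallback standard; defaults
#'   to the PC-class standard if present, else the first standard.
#' @return Normalized `lipidome` (standards removed, `normalized = TRUE`),
#'   with the applied map stored in `attr(, "normalization")`.
#' @export
normalize_to_standards <- function(x, class_map = NULL,
                                   default_standard = NULL) {
  stopifnot(inherits(x, "lipidome"))
  if (x$normalized) {
    .stopf("matrix is already normalized")
  }
  is_std <- x$features$is_internal_standard
  if (!any(is_std)) {
    .stopf("no internal-standard features found in the matrix")
  }
  std <- x$features[is_std, , drop = FALSE]

  auto_map <- stats::setNames(std$canonical_key, std$class)
  auto_map <- auto_map[!duplicated(names(auto_map))]
  if (!is.null(class_map)) {
    auto_map[names(class_map)] <- class_map
  }
  if (is.null(default_standard)) {
    default_standard <- if ("PC" %in% names(auto_map)) {
      auto_map[["PC"]]
    } else {
      std$canonical_key[1L]
    }
  }

  std_rows <- match(unique(c(auto_map, default_standard)),
    x$features$canonical_key
  )
  if (anyNA(std_rows)) {
    .stopf(
      "mapped standard(s) absent from the matrix: %s",
      paste(setdiff(
        unique(c(auto_map, default_standard)), x$features$canonical_key
      ), collapse = ", ")
    )
  }
  std_vals <- x$values[std_rows, , drop = FALSE]
  rownames(std_vals) <- x$features$canonical_key[std_rows]
  bad <- which(is.na(std_vals) | std_vals == 0, arr.ind = TRUE)
  if (nrow(bad)) {
    .stopf(
      "standard '%s' is missing or zero in sample '%s'",
      rownames(std_vals)[bad[1L, 1L]], colnames(std_vals)[bad[1L, 2L]]
    )
  }

  keep <- which(!is_std)
  classes <- x$features$class[keep]
  std_key <- ifelse(classes %in% names(auto_map),
    auto_map[classes], default_standard
  )
  denom <- std_vals[std_key, , drop = FALSE]
  out_vals <- x$values[keep, , drop = FALSE] / denom

  out <- lipidome(out_vals, x$samples,
    feature_names = rownames(x$values)[keep], normalized = TRUE
  )
  attr(out, "normalization") <- list(
    class_map = as.list(auto_map),
    default_standard = default_standard,
    standard_map_by_feature = stats::setNames(
      std_key, x$features$canonical_key[keep]
    )
  )
  out
}

#' Impute missing abundances by half-minimum left censoring
#'
#' Missing cells get half the minimum positive value of their feature across
#' samples; features missing everywhere get half the global minimum positive
#' value.  This is the standard left-censoring treatment for below-detection
#' MS intensities.
#'
#' @param x A `lipidome`.
#' @return `x` with no missing cells; the imputation count is stored in
#'   `attr(, "imputation")`.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  vals <- x$values
  n_missing <- sum(is.na(vals))
  if (n_missing > 0L) {
    global_fill <- .min_positive(vals) / 2
    if (is.na(global_fill)) {
      .stopf("matrix has no positive values to impute from")
    }
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      fill <- .min_positive(vals[i, ])
      fill <- if (is.na(fill)) global_fill else fill / 2
      vals[i, is.na(vals[i, ])] <- fill
    }
  }
  x$values <- vals
  attr(x, "imputation") <- list(n_imputed = n_missing)
  x
}

#' Row-wise log z-score transform for clustering
#'
#' Replaces abundances by per-feature z-scores of `log(value + pseudocount)`,
#' after half-minimum imputation of missing cells.  Features with zero
#' variance get all-zero rows (no error).  This is the input expected by
#' [cluster_tripartition()], mirroring the usual heatmap preprocessing for
#' Euclidean-distance hierarchical clustering.
#'
#' @param x A normalized `lipidome`.
#' @param pseudocount Positive value added before the log; defaults to half
#'   the global minimum positive value.
#' @return Transformed `lipidome` (`log_scale = TRUE`); the pseudocount used
#'   is stored in `attr(, "transform")`.
#' @export
transform_for_clustering <- function(x, pseudocount = NULL) {
  stopifnot(inherits(x, "lipidome"))
  if (!x$normalized) {
    .stopf("transform_for_clustering expects a normalized matrix")
  }
  x <- impute_missing(x)
  if (is.null(pseudocount)) {
    pseudocount <- .min_positive(x$values) / 2
  }
  stopifnot(is.numeric(pseudocount), pseudocount > 0)
  lv <- log(x$values + pseudocount)
  mu <- rowMeans(lv)
  sdv <- apply(lv, 1L, stats::sd)
  z <- (lv - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  out <- x
  out$values <- z
  out$log_scale <- TRUE
  attr(out, "transform") <- list(pseudocount = pseudocount)
  out
}

# group -> column indices, validating presence; `groups` is a named character
# vector role -> group label (names optional)
.group_columns <- function(x, groups) {
  lapply(groups, function(g) {
    idx <- which(x$samples$group == g)
    if (length(idx) == 0L) {
      .stopf("group '%s' has no samples in the matrix", g)
    }
    idx
  })
}
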