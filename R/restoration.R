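# Three-group perturbation/restoration analyses: volcano-style differential
# calls on abundance matrices, the restoration index and its five-way
# categorization (decreased/increased x restored/not, unchanged),
# cross-dataset concordance of differential calls, and the Venn partition of
# differential features across a perturbed contrast and one or more rescue
# contrasts.

#' Volcano-style differential call between two groups
#'
#' Per feature: log2 of the pseudocounted group-mean ratio (`group_a` over
#' `group_b`), a two-sided Welch p-value on log abundances, optional
#' Benjamini-Hochberg adjustment, and the joint "altered" verdict
#' `|log2fc| >= lfc_threshold` and (adjusted) `p < alpha`.
#'
#' @param x A normalized `lipidome`.
#' @param group_a,group_b Group labels (log2 fold change is a over b).
#' @param lfc_threshold Minimum |log2 fold change| (default 1).
#' @param alpha Significance level (default 0.05).
#' @param adjust Use BH-adjusted p for the altered verdict (default FALSE).
#' @param on_log Welch test on log abundances (default TRUE).
#' @param pseudocount Pseudocount for means and logs; default half the
#'   global minimum positive value.
#' @return Data frame (`diff_table`): `feature`, `log2fc`, `pvalue`, `padj`,
#'   `altered`, `direction` (`"up"`/`"down"`/`"none"`), with the contrast in
#'   `attr(, "contrast")`.
#' @export
volcano_call <- function(x, group_a, group_b, lfc_threshold = 1,
                         alpha = 0.05, adjust = FALSE, on_log = TRUE,
                         pseudocount = NULL) {
  stopifnot(inherits(x, "lipidome"))
  if (x$log_scale) {
    .stopf("volcano_call expects raw-scale (normalized) abundances")
  }
  cols <- .group_columns(x, c(a = group_a, b = group_b))
  x <- impute_missing(x)
  if (is.null(pseudocount)) {
    pseudocount <- .min_positive(x$values) / 2
  }
  means <- .group_mean_matrix(x, cols)
  log2fc <- log2((means[, "a"] + pseudocount) / (means[, "b"] + pseudocount))
  p <- .welch_by_row(x$values, cols$a, cols$b, on_log, pseudocount)
  padj <- stats::p.adjust(p, method = "BH")
  p_use <- if (adjust) padj else p
  altered <- abs(log2fc) >= lfc_threshold & p_use < alpha
  out <- data.frame(
    feature = x$features$canonical_key,
    log2fc = log2fc,
    pvalue = p,
    padj = padj,
    altered = altered,
    direction = ifelse(!altered, "none", ifelse(log2fc > 0, "up", "down")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "contrast") <- paste(group_a, "vs", group_b)
  out
}

#' Fractional restoration of a perturbed mean toward control
#'
#' `(mean_r - mean_t) / (mean_c - mean_t)` on log-scale means: 0 means the
#' restored group sits at the perturbed level, 1 means full return to
#' control; values outside `[0, 1]` indicate over- or counter-shooting.  The
#' index is invariant under affine transforms applied jointly to the three
#' means, so any log base (or none, for already-log data) gives the same
#' value.
#'
#' @param mean_c,mean_t,mean_r Control/treated/restored group means on the
#'   log scale (vectorized).
#' @return Signed numeric index.
#' @export
restoration_index <- function(mean_c, mean_t, mean_r) {
  if (any(mean_c == mean_t)) {
    .stopf(
      "restoration_index is undefined when control and treated means are equal; filter to altered features first"
    )
  }
  (mean_r - mean_t) / (mean_c - mean_t)
}

#' Categorize features by perturbation direction and restoration
#'
#' Applies the volcano "altered" criterion to the treated-vs-control
#' contrast, then computes the [restoration_index()] (on log-scale means)
#' for altered features and assigns exactly one of five categories:
#' `decreased_restored`, `decreased_not_restored`, `increased_restored`,
#' `increased_not_restored`, `unchanged`.  A feature is restored when its
#' index reaches `restore_threshold` (default 0.5, i.e. at least half-way
#' back to control).
#'
#' @param x A normalized `lipidome` with the three groups.
#' @param groups Named character vector with entries `control`, `treated`,
#'   `restored` giving the group labels.
#' @param lfc_threshold,alpha,adjust,on_log,pseudocount Altered criterion,
#'   see [volcano_call()].
#' @param restore_threshold Minimum restoration index (default 0.5).
#' @return Data frame of restoration calls: `feature`, `mean_c`, `mean_t`,
#'   `mean_r` (raw-scale means), `log2fc_t`, `p_t`, `restoration_index`
#'   (`NA` for unchanged features), `category`.
#' @export
classify_restoration <- function(x,
                                 groups = c(
                                   control = "C", treated = "1P",
                                   restored = "CMT"
                                 ),
                                 lfc_threshold = 1, alpha = 0.05,
                                 restore_threshold = 0.5, adjust = FALSE,
                                 on_log = TRUE, pseudocount = NULL) {
  stopifnot(inherits(x, "lipidome"))
  if (!all(c("control", "treated", "restored") %in% names(groups))) {
    .stopf("`groups` must name 'control', 'treated' and 'restored' labels")
  }
  cols <- .group_columns(x, groups[c("control", "treated", "restored")])
  x <- impute_missing(x)
  if (is.null(pseudocount)) {
    pseudocount <- .min_positive(x$values) / 2
  }
  means <- .group_mean_matrix(x, cols)
  log2fc <- log2(
    (means[, "treated"] + pseudocount) / (means[, "control"] + pseudocount)
  )
  p <- .welch_by_row(
    x$values, cols$treated, cols$control, on_log, pseudocount
  )
  if (adjust) {
    p <- stats::p.adjust(p, method = "BH")
  }
  altered <- abs(log2fc) >= lfc_threshold & p < alpha

  lmeans <- log(means + pseudocount)
  idx <- rep(NA_real_, nrow(means))
  idx[altered] <- restoration_index(
    lmeans[altered, "control"], lmeans[altered, "treated"],
    lmeans[altered, "restored"]
  )
  restored <- !is.na(idx) & idx >= restore_threshold

  category <- rep("unchanged", nrow(means))
  category[altered & log2fc < 0 & restored] <- "decreased_restored"
  category[altered & log2fc < 0 & !restored] <- "decreased_not_restored"
  category[altered & log2fc > 0 & restored] <- "increased_restored"
  category[altered & log2fc > 0 & !restored] <- "increased_not_restored"

  data.frame(
    feature = x$features$canonical_key,
    mean_c = means[, "control"],
    mean_t = means[, "treated"],
    mean_r = means[, "restored"],
    log2fc_t = log2fc,
    p_t = p,
    restoration_index = idx,
    category = category,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Summarize restoration categories
#'
#' @param calls Output of [classify_restoration()].
#' @return List of per-category counts and percentages of all features.
#' @export
restoration_summary <- function(calls) {
  lev <- c(
    "decreased_restored", "increased_restored",
    "decreased_not_restored", "increased_not_restored", "unchanged"
  )
  counts <- table(factor(calls$category, levels = lev))
  list(
    n_features = nrow(calls),
    counts = as.list(counts),
    percent = as.list(round(100 * as.numeric(counts) / nrow(calls), 1) |>
      stats::setNames(lev))
  )
}

#' Read a differential-result table from delimited text
#'
#' Expects columns `feature`, `log2fc`, `pvalue` and optionally `padj`
#' (tab- or comma-delimited, auto-detected).  Used to consume result tables
#' from external differential-expression tools.
#'
#' @param path File path.
#' @param delim Optional explicit delimiter.
#' @return Data frame with those columns (`padj = NA` when absent).
#' @export
read_diff_table <- function(path, delim = NULL) {
  sep <- if (is.null(delim)) .detect_delim(path) else delim
  tab <- utils::read.table(
    path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  need <- c("feature", "log2fc", "pvalue")
  if (!all(need %in% names(tab))) {
    .stopf(
      "diff table needs columns %s; missing: %s",
      paste(need, collapse = ", "),
      paste(setdiff(need, names(tab)), collapse = ", ")
    )
  }
  if (!"padj" %in% names(tab)) {
    tab$padj <- NA_real_
  }
  ok_p <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  if (!ok_p(tab$pvalue) || !ok_p(tab$padj)) {
    .stopf("p-values outside [0, 1] in '%s'", path)
  }
  tab[, c("feature", "log2fc", "pvalue", "padj")]
}

# altered feature ids of a diff table under the joint volcano criterion
.altered_set <- function(tab, alpha, lfc_threshold, use_adjusted) {
  if ("altered" %in% names(tab) && is.logical(tab$altered)) {
    return(tab$feature[tab$altered])
  }
  p <- if (use_adjusted && !all(is.na(tab$padj))) tab$padj else tab$pvalue
  tab$feature[!is.na(p) & p < alpha & abs(tab$log2fc) >= lfc_threshold]
}

#' Concordance of differential calls between two datasets
#'
#' Over a shared feature universe, counts features altered in both tables,
#' the direction-concordant subset (matching log2 fold-change sign), a
#' per-parity-stratum breakdown (parity parsed from the canonical keys), and
#' a two-sided Fisher exact test on the 2x2 altered/not-altered contingency.
#'
#' @param calls_a,calls_b Diff tables ([volcano_call()] output or
#'   [read_diff_table()] input) keyed by canonical feature key.
#' @param universe Character vector of shared measured features; defaults to
#'   the intersection of the two tables' features.
#' @param alpha,lfc_threshold,use_adjusted Altered criterion applied to both
#'   tables when they carry no `altered` column.
#' @return List: `n_universe`, `n_altered_a`, `n_altered_b`,
#'   `n_shared_altered`, `n_direction_concordant`,
#'   `percent_direction_concordant`, `fisher_p`, `contingency`, `by_parity`.
#' @export
concordance <- function(calls_a, calls_b, universe = NULL, alpha = 0.05,
                        lfc_threshold = 1, use_adjusted = FALSE) {
  if (is.null(universe)) {
    universe <- intersect(calls_a$feature, calls_b$feature)
  }
  if (length(universe) == 0L) {
    .stopf("empty feature universe; the tables share no features")
  }
  a <- .altered_set(calls_a, alpha, lfc_threshold, use_adjusted)
  b <- .altered_set(calls_b, alpha, lfc_threshold, use_adjusted)
  a <- intersect(a, universe)
  b <- intersect(b, universe)
  shared <- intersect(a, b)

  sign_of <- function(tab, ids) {
    sign(tab$log2fc[match(ids, tab$feature)])
  }
  conc <- shared[sign_of(calls_a, shared) == sign_of(calls_b, shared)]

  n11 <- length(shared)
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- length(universe) - n11 - n10 - n01
  cont <- matrix(c(n11, n10, n01, n00), 2L, 2L,
    dimnames = list(a_altered = c("yes", "no"), b_altered = c("yes", "no"))
  )
  fisher_p <- stats::fisher.test(cont)$p.value

  strat <- parity_stratum(
    vapply(universe, function(f) chain_parity(f), character(1L))
  )
  by_parity <- lapply(c(odd = "odd", even = "even"), function(s) {
    u <- universe[strat == s]
    list(
      n_universe = length(u),
      n_altered_a = length(intersect(a, u)),
      n_altered_b = length(intersect(b, u)),
      n_shared_altered = length(intersect(shared, u))
    )
  })

  list(
    n_universe = length(universe),
    n_altered_a = length(a),
    n_altered_b = length(b),
    n_shared_altered = n11,
    n_direction_concordant = length(conc),
    percent_direction_concordant = if (n11 > 0) 100 * length(conc) / n11
      else NA_real_,
    fisher_p = fisher_p,
    contingency = cont,
    by_parity = by_parity
  )
}

#' Venn partition of differential features across perturbed and rescue arms
#'
#' Given an altered-feature criterion applied to a perturbed-vs-control diff
#' table and one or more rescue-vs-control tables, emits every region of the
#' Venn diagram over the altered sets, with up/down tallies per contrast.
#' Region I — features altered by the perturbation but by none of the rescue
#' arms — is the "restored toward baseline" set.
#'
#' @param perturbed Diff table for the perturbed-vs-control contrast.
#' @param rescued Named list of diff tables for rescue-vs-control contrasts.
#' @param alpha,lfc_threshold,use_adjusted Altered criterion (adjusted p by
#'   default, the convention for external DE tables).
#' @return List of class `venn_partition`: `regions` (named list of feature
#'   id vectors keyed by membership pattern such as `"perturbed"` or
#'   `"perturbed&rescueA"`), `sizes`, `region_I` (= `regions$perturbed`),
#'   `altered` (per-contrast altered sets), `direction_tallies`
#'   (per-contrast up/down counts), `n_union`.
#' @export
deg_restoration_partition <- function(perturbed, rescued, alpha = 0.05,
                                      lfc_threshold = 1,
                                      use_adjusted = TRUE) {
  if (is.data.frame(rescued)) {
    rescued <- list(rescue = rescued)
  }
  if (is.null(names(rescued)) || any(!nzchar(names(rescued)))) {
    names(rescued) <- paste0("rescue", seq_along(rescued))
  }
  tabs <- c(list(perturbed = perturbed), rescued)
  for (nm in names(tabs)) {
    if (anyDuplicated(tabs[[nm]]$feature)) {
      .stopf("duplicated feature ids in diff table '%s'", nm)
    }
  }
  sets <- lapply(
    tabs, .altered_set,
    alpha = alpha, lfc_threshold = lfc_threshold, use_adjusted = use_adjusted
  )
  ids <- sort(unique(unlist(sets, use.names = FALSE)))

  membership <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) {
    membership <- matrix(membership, nrow = 1L, dimnames = list(NULL, names(sets)))
  }
  pattern <- apply(membership, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  regions <- split(ids, pattern)

  tallies <- lapply(names(tabs), function(nm) {
    s <- sets[[nm]]
    lfc <- tabs[[nm]]$log2fc[match(s, tabs[[nm]]$feature)]
    list(up = sum(lfc > 0), down = sum(lfc < 0))
  })
  names(tallies) <- names(tabs)

  structure(
    list(
      regions = regions,
      sizes = vapply(regions, length, integer(1L)),
      region_I = if ("perturbed" %in% names(regions)) {
        regions[["perturbed"]]
      } else {
        character(0)
      },
      altered = sets,
      direction_tallies = tallies,
      n_union = length(ids)
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (nm in names(x$sizes)) {
    cat(sprintf("  %-40s %d\n", nm, x$sizes[[nm]]))
  }
  cat(sprintf("  union: %d | region I (perturbed only): %d\n",
    x$n_union, length(x$region_I)
  ))
  invisible(x)
}
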