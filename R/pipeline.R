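# Pipeline driver: one entry point dispatching on a run configuration, with
# a machine-readable run report (parameters, seeds, input digests, outputs)
# so every run is reproducible from its own report.

.PIPELINE_MODES <- c(
  "simulate", "origin", "perturbation", "compare-groups", "venn",
  "concordance"
)

# required config keys per mode (beyond `mode` itself)
.REQUIRED_KEYS <- list(
  "simulate" = c("design"),
  "origin" = c("matrix", "metadata", "groups"),
  "perturbation" = c("matrix", "metadata", "groups"),
  "compare-groups" = c("matrix", "metadata"),
  "venn" = c("perturbed", "rescued"),
  "concordance" = c("table_a", "table_b")
)

.validate_config <- function(cfg) {
  if (is.null(cfg$mode)) {
    .stopf("config validation failed: missing required key 'mode'")
  }
  if (!cfg$mode %in% .PIPELINE_MODES) {
    .stopf(
      "unknown mode '%s'; expected one of %s",
      cfg$mode, paste(.PIPELINE_MODES, collapse = ", ")
    )
  }
  missing <- setdiff(.REQUIRED_KEYS[[cfg$mode]], names(cfg))
  if (length(missing)) {
    .stopf(
      "config validation failed: missing required key(s) %s for mode '%s'",
      paste(sprintf("'%s'", missing), collapse = ", "), cfg$mode
    )
  }
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

.log_line <- function(msg, log_path = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(log_path)) {
    cat(line, "\n", file = log_path, append = TRUE)
  }
  invisible(line)
}

# named character vector from a config list entry like
# list(conv = "Conv", gf = "GF", diet = "Diet")
.cfg_groups <- function(x) {
  stats::setNames(as.character(unlist(x)), names(x))
}

#' Run a pipeline stage from a configuration
#'
#' Single driver for the analysis chain.  The configuration (a YAML/key-value
#' file path or an equivalent named list) names a `mode` and its inputs:
#'
#' \describe{
#'   \item{simulate}{`design` (`origin`/`perturbation`) plus any
#'     [sim_config()] field; writes `matrix.tsv`, `metadata.tsv`,
#'     `truth.tsv`.}
#'   \item{origin}{`matrix`, `metadata` paths and `groups`
#'     (`conv`/`gf`/`diet` labels); normalizes, calls GMPLs and the cluster
#'     tripartition; writes `origin_calls.tsv` and `origin_summary.json`.}
#'   \item{perturbation}{`matrix`, `metadata`, `groups`
#'     (`control`/`treated`/`restored`); writes `restoration_calls.tsv` and
#'     `restoration_summary.json`.}
#'   \item{compare-groups}{`matrix`, `metadata`; Bray-Curtis distances and
#'     (pairwise) PERMANOVA; writes `distance_matrix.tsv`,
#'     `permanova.tsv`, `compare_summary.json`.}
#'   \item{venn}{`perturbed` and `rescued` diff-table paths (columns
#'     `feature`, `log2fc`, `pvalue`, `padj`); writes `venn_partition.tsv`
#'     and `venn_summary.json`.}
#'   \item{concordance}{`table_a`, `table_b` diff-table paths; writes
#'     `concordance.json`.}
#' }
#'
#' Optional keys: thresholds (`fd_threshold`, `alpha`, `lfc_threshold`,
#' `restore_threshold`, `k`, `linkage`, `n_permutations`), `seed`, and
#' `log_file`.  A `run_report.json` capturing the echoed config, parameters,
#' seeds, input digests and output paths is always written.
#'
#' @param config Path to a YAML/key-value config file, or a named list.
#' @param out_dir Output directory (created if needed; default `"."`).
#' @param seed Overrides the config's seed when given.
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .validate_config(cfg)
  if (!is.null(seed)) {
    cfg$seed <- seed
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- if (!is.null(cfg$log_file)) file.path(out_dir, cfg$log_file)
  out <- function(name) file.path(out_dir, name)

  inputs <- character(0)
  outputs <- character(0)
  params <- list(seed = cfg$seed)
  summary <- list()

  .log_line(sprintf("mode '%s' starting", cfg$mode), log_path)

  if (cfg$mode == "simulate") {
    sim_args <- cfg[setdiff(
      intersect(names(cfg), names(formals(sim_config))), "design"
    )]
    sc <- do.call(sim_config, c(list(design = cfg$design), sim_args))
    sim <- if (cfg$design == "origin") {
      simulate_origin_experiment(sc)
    } else {
      simulate_perturbation_experiment(sc)
    }
    write_lipidome(sim$matrix, out("matrix.tsv"), out("metadata.tsv"))
    .write_tsv(sim$truth, out("truth.tsv"))
    outputs <- c(out("matrix.tsv"), out("metadata.tsv"), out("truth.tsv"))
    params <- c(params, unclass(sc)[setdiff(names(sc), "group_labels")])
    summary <- list(
      n_features = nrow(sim$truth),
      n_samples = ncol(sim$matrix$values)
    )
  } else if (cfg$mode == "origin") {
    inputs <- c(cfg$matrix, cfg$metadata)
    x <- read_lipidome(cfg$matrix, cfg$metadata)
    xn <- normalize_to_standards(x)
    groups <- .cfg_groups(cfg$groups)
    xt <- transform_for_clustering(xn)
    labels <- cluster_tripartition(
      xt, groups,
      k = cfg$k %||% 3, linkage = cfg$linkage %||% "ward.D2"
    )
    calls <- call_gmpl(
      xn, groups,
      fd_threshold = cfg$fd_threshold %||% 5,
      alpha = cfg$alpha %||% 0.05,
      adjust = isTRUE(cfg$adjust),
      cluster_labels = labels
    )
    .write_tsv(calls, out("origin_calls.tsv"))
    summary <- gmpl_summary(calls)
    summary$normalization <- attr(xn, "normalization")[c(
      "class_map", "default_standard"
    )]
    summary$pseudocount <- attr(xt, "transform")$pseudocount
    .write_json(summary, out("origin_summary.json"))
    outputs <- c(out("origin_calls.tsv"), out("origin_summary.json"))
    params <- c(params, list(
      fd_threshold = cfg$fd_threshold %||% 5, alpha = cfg$alpha %||% 0.05,
      k = cfg$k %||% 3, linkage = cfg$linkage %||% "ward.D2"
    ))
  } else if (cfg$mode == "perturbation") {
    inputs <- c(cfg$matrix, cfg$metadata)
    x <- read_lipidome(cfg$matrix, cfg$metadata)
    xn <- normalize_to_standards(x)
    calls <- classify_restoration(
      xn, .cfg_groups(cfg$groups),
      lfc_threshold = cfg$lfc_threshold %||% 1,
      alpha = cfg$alpha %||% 0.05,
      restore_threshold = cfg$restore_threshold %||% 0.5,
      adjust = isTRUE(cfg$adjust)
    )
    .write_tsv(calls, out("restoration_calls.tsv"))
    summary <- restoration_summary(calls)
    .write_json(summary, out("restoration_summary.json"))
    outputs <- c(
      out("restoration_calls.tsv"), out("restoration_summary.json")
    )
    params <- c(params, list(
      lfc_threshold = cfg$lfc_threshold %||% 1,
      alpha = cfg$alpha %||% 0.05,
      restore_threshold = cfg$restore_threshold %||% 0.5
    ))
  } else if (cfg$mode == "compare-groups") {
    inputs <- c(cfg$matrix, cfg$metadata)
    x <- read_lipidome(cfg$matrix, cfg$metadata)
    xn <- if (isFALSE(cfg$normalize)) x else normalize_to_standards(x)
    d <- bray_curtis_matrix(xn)
    dm <- as.matrix(d)
    .write_tsv(
      data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
      out("distance_matrix.tsv")
    )
    pw <- pairwise_permanova(
      d, xn$samples$group,
      n_permutations = cfg$n_permutations %||% 999,
      seed = cfg$seed %||% 1L
    )
    .write_tsv(pw, out("permanova.tsv"))
    overall <- permanova(
      d, xn$samples$group,
      n_permutations = cfg$n_permutations %||% 999,
      seed = cfg$seed %||% 1L
    )
    summary <- list(
      overall_pseudo_F = overall$pseudo_F,
      overall_p = overall$p_value,
      pairwise = lapply(seq_len(nrow(pw)), function(i) as.list(pw[i, ]))
    )
    .write_json(summary, out("compare_summary.json"))
    outputs <- c(
      out("distance_matrix.tsv"), out("permanova.tsv"),
      out("compare_summary.json")
    )
    params <- c(params, list(n_permutations = cfg$n_permutations %||% 999))
  } else if (cfg$mode == "venn") {
    rescued_paths <- unlist(cfg$rescued)
    inputs <- c(cfg$perturbed, rescued_paths)
    perturbed <- read_diff_table(cfg$perturbed)
    rescued <- lapply(rescued_paths, read_diff_table)
    names(rescued) <- names(rescued_paths) %||%
      tools::file_path_sans_ext(basename(rescued_paths))
    part <- deg_restoration_partition(
      perturbed, rescued,
      alpha = cfg$alpha %||% 0.05,
      lfc_threshold = cfg$lfc_threshold %||% 1,
      use_adjusted = !isFALSE(cfg$use_adjusted)
    )
    region_df <- data.frame(
      feature = unlist(part$regions, use.names = FALSE),
      region = rep(names(part$regions), lengths(part$regions)),
      stringsAsFactors = FALSE
    )
    .write_tsv(region_df, out("venn_partition.tsv"))
    summary <- list(
      sizes = as.list(part$sizes),
      n_union = part$n_union,
      region_I_size = length(part$region_I),
      direction_tallies = part$direction_tallies
    )
    .write_json(summary, out("venn_summary.json"))
    outputs <- c(out("venn_partition.tsv"), out("venn_summary.json"))
  } else if (cfg$mode == "concordance") {
    inputs <- c(cfg$table_a, cfg$table_b)
    res <- concordance(
      read_diff_table(cfg$table_a), read_diff_table(cfg$table_b),
      alpha = cfg$alpha %||% 0.05,
      lfc_threshold = cfg$lfc_threshold %||% 1,
      use_adjusted = isTRUE(cfg$use_adjusted)
    )
    res$contingency <- as.list(as.data.frame(res$contingency))
    summary <- res
    .write_json(summary, out("concordance.json"))
    outputs <- out("concordance.json")
  }

  report <- list(
    tool = "lipidorigin",
    version = as.character(utils::packageVersion("lipidorigin")),
    mode = cfg$mode,
    config = cfg,
    parameters = params,
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      list()
    },
    outputs = as.list(outputs),
    summary = summary
  )
  .write_json(report, out("run_report.json"))
  .log_line(sprintf("mode '%s' done", cfg$mode), log_path)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
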