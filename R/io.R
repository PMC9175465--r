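#' Write a cohort in long format
#'
#' One record per positive (individual, condition) cell with header
#' `person_id,condition`; the inverse of [read_cohort()] with
#' `format = "long"`.
#'
#' @param cohort a [cohort_matrix()].
#' @param path output CSV path.
#' @rdname cohort_io
#' @export
write_long_format <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  pos <- which(cohort$incidence == 1L, arr.ind = TRUE)
  df <- data.frame(
    person_id = sprintf("P%06d", pos[, 1]),
    condition = cohort$condition_labels[pos[, 2]],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$person_id, df$condition), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_wide_format <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  df <- data.frame(person_id = sprintf("P%06d", seq_len(nrow(cohort$incidence))),
                   cohort$incidence, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read person-level condition data into a cohort matrix
#'
#' Long format expects columns `person_id,condition`, one row per recorded
#' condition; duplicate rows collapse to a single positive cell. Wide
#' format expects a `person_id` index column followed by strictly binary
#' condition columns.
#'
#' @param path CSV path.
#' @param format `"long"` or `"wide"`.
#' @param restrict_multimorbid keep only individuals with two or more
#'   conditions (default `FALSE`).
#' @return a [cohort_matrix()].
#' @export
read_cohort <- function(path, format = c("long", "wide"),
                        restrict_multimorbid = FALSE) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    if (!all(c("person_id", "condition") %in% names(df))) {
      stop("long format requires columns person_id,condition")
    }
    if (nrow(df) == 0) stop("empty input: no (person, condition) records")
    persons <- sort(unique(df$person_id))
    conditions <- sort(unique(df$condition))
    inc <- matrix(0L, nrow = length(persons), ncol = length(conditions),
                  dimnames = list(persons, conditions))
    inc[cbind(match(df$person_id, persons), match(df$condition, conditions))] <- 1L
    rownames(inc) <- NULL
  } else {
    if (names(df)[1] != "person_id") {
      stop("wide format requires a leading person_id column")
    }
    if (nrow(df) == 0) stop("empty input: no individuals")
    inc <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!(inc %in% c(0, 1)) | is.na(inc), arr.ind = FALSE)
    if (length(bad) > 0) {
      rows <- sort(unique((bad - 1) %% nrow(inc) + 1))
      stop(sprintf("non-binary cells in wide input (rows %s)",
                   paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  cohort <- cohort_matrix(inc)
  if (restrict_multimorbid) cohort <- restrict_multimorbid(cohort)
  cohort
}

#' Write / read a community partition as CSV
#'
#' @param partition a [detect_communities()] result.
#' @param path CSV path (`node,community_id`).
#' @rdname partition_io
#' @export
write_partition_csv <- function(partition, path) {
  stopifnot(inherits(partition, "partition"))
  utils::write.csv(
    data.frame(node = names(partition$assignment),
               community_id = unname(partition$assignment),
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname partition_io
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_partition(stats::setNames(as.integer(df$community_id), df$node))
}

#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults are the
#' standard settings of the analysis: support floor 15, significance level
#' 0.01, all seven measures, the three edge strata (all associations,
#' strongest 50%, strongest 200), prevalence band cut-points at 1% and 7%,
#' and top-20 central nodes.
#'
#' @param input path to a cohort CSV, or `NULL` to simulate from
#'   `synthetic` instead.
#' @param input_format `"long"` or `"wide"`.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param min_support minimum joint frequency (default 15).
#' @param alpha significance level (default 0.01).
#' @param measures measures to run (default all seven).
#' @param strata edge strata to build; list of selection descriptors
#'   (default all three).
#' @param band_thresholds prevalence band cut-points (default 1% and 7%).
#' @param top_central_k central-node list length (default 20).
#' @param louvain_seed,louvain_resolution community detection controls.
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       input_format = "long",
                       synthetic = NULL,
                       min_support = 15,
                       alpha = 0.01,
                       measures = measure_names(),
                       strata = list(list(type = "all"),
                                     list(type = "top_fraction", f = 0.5),
                                     list(type = "top_k", k = 200)),
                       band_thresholds = c(0.01, 0.07),
                       top_central_k = 20,
                       louvain_seed = 1L,
                       louvain_resolution = 1.0,
                       output_dir = "results") {
  if (is.null(input) && is.null(synthetic)) {
    stop("either an input path or a synthetic_config is required")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be strictly inside (0, 1)")
  if (min_support < 1) stop("min_support must be at least 1")
  bad <- setdiff(measures, measure_names())
  if (length(bad) > 0) stop(sprintf("unknown measures: %s", paste(bad, collapse = ", ")))
  structure(
    list(input = input, input_format = input_format, synthetic = synthetic,
         min_support = min_support, alpha = alpha, measures = measures,
         strata = strata, band_thresholds = band_thresholds,
         top_central_k = top_central_k, louvain_seed = as.integer(louvain_seed),
         louvain_resolution = louvain_resolution, output_dir = output_dir),
    class = "run_config"
  )
}

stratum_id <- function(s) {
  switch(s$type,
         all = "all",
         top_fraction = sprintf("top%gpct", 100 * s$f),
         top_k = sprintf("top%d", s$k))
}

#' Run the full multimorbidity network pipeline
#'
#' Loads or simulates the cohort, builds the filtered association table,
#' constructs one weighted network per (measure, stratum), detects
#' communities, profiles edges by prevalence band, and compares the
#' networks of each stratum across measures. All artifacts are written
#' under `config$output_dir`; re-running with an identical configuration
#' reproduces identical artifacts.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the cohort, association table, networks,
#'   partitions, edge profiles and per-stratum comparison reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input, config$input_format)
  } else {
    generate_cohort(config$synthetic)
  }
  say("cohort: %d individuals x %d conditions",
      nrow(cohort$incidence), ncol(cohort$incidence))

  assoc <- build_association_table(cohort, min_support = config$min_support,
                                   alpha = config$alpha)
  acc <- association_accounting(assoc)
  say("Out of %d pairwise disease co-occurrences with joint frequencies >= %g, %d (%.1f%%) were excluded; %d associations remained.",
      acc$n_candidates, config$min_support, acc$n_excluded,
      if (acc$n_candidates > 0) 100 * acc$n_excluded / acc$n_candidates else 0,
      acc$n_retained)
  write_association_csv(assoc, file.path(config$output_dir, "associations.csv"))

  networks <- list()
  partitions <- list()
  profiles <- list()
  reports <- list()
  for (s in config$strata) {
    sid <- stratum_id(s)
    nets <- list()
    parts <- list()
    for (m in config$measures) {
      net <- build_network(
        assoc, measure = m, selection = s$type,
        f = if (!is.null(s$f)) s$f else 0.5,
        k = if (!is.null(s$k)) s$k else 200,
        prevalence = cohort$prevalence,
        band_thresholds = config$band_thresholds
      )
      part <- detect_communities(net, seed = config$louvain_seed,
                                 resolution = config$louvain_resolution)
      nets[[m]] <- net
      parts[[m]] <- part
      profiles[[paste(m, sid, sep = "_")]] <- edge_profile(net)
      write_graphml(net, file.path(config$output_dir,
                                   sprintf("network_%s_%s.graphml", m, sid)))
      write_gexf(net, file.path(config$output_dir,
                                sprintf("network_%s_%s.gexf", m, sid)))
      write_edgelist_csv(net, file.path(config$output_dir,
                                        sprintf("edges_%s_%s.csv", m, sid)))
      write_partition_csv(part, file.path(config$output_dir,
                                          sprintf("partition_%s_%s.csv", m, sid)))
    }
    networks[[sid]] <- nets
    partitions[[sid]] <- parts
    if (length(config$measures) >= 2) {
      rep_s <- build_comparison_report(nets, parts, k = config$top_central_k)
      reports[[sid]] <- rep_s
      write_comparison_json(rep_s, file.path(config$output_dir,
                                             sprintf("comparison_%s.json", sid)))
    }
  }

  run_log <- list(
    min_support = config$min_support, alpha = config$alpha,
    louvain_seed = config$louvain_seed,
    synthetic_seed = if (!is.null(config$synthetic)) config$synthetic$seed else NULL,
    n_individuals = nrow(cohort$incidence),
    n_conditions = ncol(cohort$incidence),
    n_candidates = acc$n_candidates,
    n_excluded = acc$n_excluded,
    n_retained = acc$n_retained
  )
  jsonlite::write_json(run_log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, association = assoc, networks = networks,
                 partitions = partitions, edge_profiles = profiles,
                 reports = reports, run_log = run_log))
}
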