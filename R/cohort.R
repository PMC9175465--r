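#' Cohort incidence matrix
#'
#' A `cohort_matrix` holds a binary person-by-condition incidence matrix
#' together with per-condition prevalence (fraction of individuals with the
#' condition) and, for synthetic cohorts, the planted block label of each
#' condition.
#'
#' @param incidence binary (0/1) matrix, individuals in rows, conditions in
#'   columns; column names are the condition labels.
#' @param planted_blocks optional integer vector of block labels, one per
#'   condition, for synthetic cohorts with planted co-occurrence structure.
#' @return An object of class `cohort_matrix` with elements `incidence`,
#'   `condition_labels`, `prevalence` and `planted_blocks`.
#' @export
cohort_matrix <- function(incidence, planted_blocks = NULL) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "integer"
  if (any(is.na(incidence)) || !all(incidence %in% c(0L, 1L))) {
    stop("incidence must be a binary 0/1 matrix with no missing values")
  }
  labels <- colnames(incidence)
  if (is.null(labels)) {
    labels <- sprintf("C%03d", seq_len(ncol(incidence)))
    colnames(incidence) <- labels
  }
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  if (!is.null(planted_blocks)) {
    if (length(planted_blocks) != ncol(incidence)) {
      stop("planted_blocks must have one label per condition")
    }
    planted_blocks <- as.integer(planted_blocks)
    names(planted_blocks) <- labels
  }
  structure(
    list(
      incidence = incidence,
      condition_labels = labels,
      prevalence = colMeans(incidence),
      planted_blocks = planted_blocks
    ),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf(
    "<cohort_matrix> %d individuals x %d conditions\n",
    nrow(x$incidence), ncol(x$incidence)
  ))
  cat(sprintf(
    "  prevalence range: %.4f - %.4f; median conditions per person: %s\n",
    min(x$prevalence), max(x$prevalence),
    stats::median(rowSums(x$incidence))
  ))
  if (!is.null(x$planted_blocks)) {
    cat(sprintf("  planted blocks: %d\n", length(unique(x$planted_blocks))))
  }
  invisible(x)
}

#' Restrict a cohort to multimorbid individuals
#'
#' Keeps only individuals with two or more recorded conditions, mirroring the
#' usual multimorbidity analysis-cohort definition, and recomputes prevalence
#' on the restricted cohort.
#'
#' @param cohort a [cohort_matrix()].
#' @return A `cohort_matrix` in which every row sum is at least 2.
#' @export
restrict_multimorbid <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  keep <- rowSums(cohort$incidence) >= 2L
  cohort_matrix(cohort$incidence[keep, , drop = FALSE],
                planted_blocks = cohort$planted_blocks)
}

#' Prevalence band of a condition
#'
#' Categorizes prevalence as low (< 1%), moderate (1 to < 7%) or high
#' (>= 7%); the band boundaries are closed on the left of each upper band.
#'
#' @param p numeric vector of prevalences in \[0, 1\].
#' @param thresholds the two band cut-points, defaults `c(0.01, 0.07)`.
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
prevalence_band <- function(p, thresholds = c(0.01, 0.07)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  cut(p, breaks = c(-Inf, thresholds, Inf),
      labels = c("low", "moderate", "high"), right = FALSE)
}
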