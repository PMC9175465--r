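#' Two-way contingency table for a condition pair
#'
#' The cells of the 2x2 table underlying every co-occurrence measure:
#' `a` individuals with both conditions, `b` with the first only, `c` with
#' the second only, `d` with neither, and `n = a + b + c + d`.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d))
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  # stored as doubles so products such as a*d cannot overflow integer range
  structure(as.list(c(cells, n = sum(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (n=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Count the contingency table of two conditions in a cohort
#'
#' @param cohort a [cohort_matrix()].
#' @param condition_x,condition_y distinct condition labels present in the
#'   cohort.
#' @return a [contingency_table()].
#' @export
count_contingency <- function(cohort, condition_x, condition_y) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (identical(condition_x, condition_y)) {
    stop("condition_x and condition_y must differ")
  }
  for (lab in c(condition_x, condition_y)) {
    if (!lab %in% cohort$condition_labels) {
      stop(sprintf("unknown condition label: %s", lab))
    }
  }
  x <- cohort$incidence[, condition_x]
  y <- cohort$incidence[, condition_y]
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  c_ <- sum(x == 0L & y == 1L)
  contingency_table(a, b, c_, length(x) - a - b - c_)
}

# Vectorized measure kernels over parallel cell-count vectors. All seven
# user-facing measure functions delegate here, as does the bulk association
# path. Preconditions are checked by the scalar wrappers.
measure_lift <- function(a, b, c, d, n) n * a / ((a + b) * (a + c))

measure_relative_risk <- function(a, b, c, d, n) {
  rr_xy <- ifelse(c > 0, a * (c + d) / (c * (a + b)), Inf)
  rr_yx <- ifelse(b > 0, a * (b + d) / (b * (a + c)), Inf)
  pmax(rr_xy, rr_yx)
}

measure_phi <- function(a, b, c, d, n) {
  (a * d - b * c) / sqrt((a + b) * (a + c) * (b + d) * (c + d))
}

measure_jaccard <- function(a, b, c, d, n) a / (a + b + c)

measure_cosine <- function(a, b, c, d, n) a / sqrt((a + b) * (a + c))

measure_kulczynski <- function(a, b, c, d, n) (a / (a + b) + a / (a + c)) / 2

measure_joint_prevalence <- function(a, b, c, d, n) a / n

#' @rdname co_occurrence_measures
#' @export
lift <- function(t) {
  check_table(t)
  if ((t$a + t$b) == 0 || (t$a + t$c) == 0) {
    stop("lift undefined: a condition has an empty marginal")
  }
  measure_lift(t$a, t$b, t$c, t$d, t$n)
}

#' @rdname co_occurrence_measures
#' @export
relative_risk <- function(t) {
  check_table(t)
  if ((t$a + t$b) == 0 || (t$a + t$c) == 0) {
    stop("relative risk undefined: a condition has an empty marginal")
  }
  rr <- measure_relative_risk(t$a, t$b, t$c, t$d, t$n)
  if (is.infinite(rr)) {
    warning("relative risk is infinite (a zero denominator direction)")
  }
  rr
}

#' @rdname co_occurrence_measures
#' @export
phi_coefficient <- function(t) {
  check_table(t)
  if (any(c(t$a + t$b, t$a + t$c, t$b + t$d, t$c + t$d) == 0)) {
    stop("phi undefined: a marginal total is zero")
  }
  measure_phi(t$a, t$b, t$c, t$d, t$n)
}

#' @rdname co_occurrence_measures
#' @export
jaccard <- function(t) {
  check_table(t)
  if ((t$a + t$b + t$c) == 0) {
    stop("Jaccard undefined: no individual has either condition")
  }
  measure_jaccard(t$a, t$b, t$c, t$d, t$n)
}

#' @rdname co_occurrence_measures
#' @export
cosine_coefficient <- function(t) {
  check_table(t)
  if ((t$a + t$b) == 0 || (t$a + t$c) == 0) {
    stop("cosine undefined: a condition has an empty marginal")
  }
  measure_cosine(t$a, t$b, t$c, t$d, t$n)
}

#' @rdname co_occurrence_measures
#' @export
kulczynski <- function(t) {
  check_table(t)
  if ((t$a + t$b) == 0 || (t$a + t$c) == 0) {
    stop("Kulczynski undefined: a condition has an empty marginal")
  }
  measure_kulczynski(t$a, t$b, t$c, t$d, t$n)
}

#' Disease co-occurrence measures on a 2x2 table
#'
#' The seven association measures used to weight multimorbidity network
#' edges, each a function of the contingency cells `a, b, c, d, n`:
#'
#' * `lift(t)` = `n a / ((a+b)(a+c))`; 1 under exact independence.
#' * `relative_risk(t)` = the maximum of the two directional relative risks
#'   `a(c+d)/(c(a+b))` and `a(b+d)/(b(a+c))` (RR is asymmetric; the maximum
#'   symmetrizes it). A zero denominator direction yields `Inf` with a
#'   warning.
#' * `phi_coefficient(t)` = `(ad - bc) / sqrt((a+b)(a+c)(b+d)(c+d))`, in
#'   \[-1, 1\]; inversion-invariant but not null-invariant.
#' * `jaccard(t)` = `a / (a+b+c)`; null-invariant.
#' * `cosine_coefficient(t)` = `a / sqrt((a+b)(a+c))`; null-invariant, the
#'   geometric mean of the two confidences.
#' * `kulczynski(t)` = `(a/(a+b) + a/(a+c)) / 2`; null-invariant, the
#'   arithmetic mean of the two confidences (hence always >= cosine >=
#'   Jaccard on the same table).
#' * `joint_prevalence(t)` = `a / n`.
#'
#' @param t a [contingency_table()].
#' @return a single numeric value.
#' @name co_occurrence_measures
NULL

#' @rdname co_occurrence_measures
#' @export
joint_prevalence <- function(t) {
  check_table(t)
  if (t$n == 0) stop("joint prevalence undefined: empty table")
  measure_joint_prevalence(t$a, t$b, t$c, t$d, t$n)
}

check_table <- function(t) {
  if (!inherits(t, "contingency_table")) {
    stop("expected a contingency_table")
  }
  invisible(t)
}

#' All seven measures of a contingency table
#'
#' @param t a [contingency_table()].
#' @return named numeric vector with elements `lift`, `relative_risk`,
#'   `phi`, `jaccard`, `cosine`, `kulczynski`, `joint_prevalence`.
#' @export
all_measures <- function(t) {
  check_table(t)
  c(lift = lift(t),
    relative_risk = suppressWarnings(relative_risk(t)),
    phi = phi_coefficient(t),
    jaccard = jaccard(t),
    cosine = cosine_coefficient(t),
    kulczynski = kulczynski(t),
    joint_prevalence = joint_prevalence(t))
}

#' Canonical measure names
#'
#' @return character vector of the seven measure names in canonical order.
#' @export
measure_names <- function() {
  c("lift", "relative_risk", "phi", "jaccard", "cosine", "kulczynski",
    "joint_prevalence")
}

#' Significance test for a 2x2 contingency table
#'
#' Uses the Pearson chi-square test (1 df) when all four expected cell
#' frequencies exceed five, and the two-sided Fisher exact test otherwise —
#' the standard Cochran rule. A degenerate table (a zero row or column
#' total) returns p = 1 under the Fisher branch. No continuity correction
#' is applied by default; `correct = TRUE` switches the chi-square branch
#' to the Yates-corrected statistic.
#'
#' @param t a [contingency_table()].
#' @param correct apply the Yates continuity correction on the chi-square
#'   branch.
#' @return list with elements `p_value` and `test_used` (`"chi_square"` or
#'   `"fisher_exact"`).
#' @export
significance_test <- function(t, correct = FALSE) {
  check_table(t)
  row1 <- t$a + t$b
  row2 <- t$c + t$d
  col1 <- t$a + t$c
  col2 <- t$b + t$d
  if (t$n == 0 || row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    return(list(p_value = 1.0, test_used = "fisher_exact"))
  }
  expected <- outer(c(row1, row2), c(col1, col2)) / t$n
  if (all(expected > 5)) {
    stat <- chi_square_stat(t$a, t$b, t$c, t$d, t$n, correct = correct)
    list(p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         test_used = "chi_square")
  } else {
    m <- matrix(c(t$a, t$c, t$b, t$d), nrow = 2)
    list(p_value = stats::fisher.test(m)$p.value,
         test_used = "fisher_exact")
  }
}

# Pearson chi-square statistic of a 2x2 table in closed form,
# n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)), i.e. n * phi^2; vectorized.
chi_square_stat <- function(a, b, c, d, n, correct = FALSE) {
  num <- if (correct) pmax(abs(a * d - b * c) - n / 2, 0) else a * d - b * c
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
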