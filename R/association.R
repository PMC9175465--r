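#' Build the filtered association table of all condition dyads
#'
#' Enumerates every unordered condition pair, builds its 2x2 contingency
#' table, and applies the standard filters of a multimorbidity association
#' analysis: a candidate dyad must have joint frequency (support)
#' `a >= min_support`; a candidate is retained only when it is statistically
#' significant at level `alpha` (chi-square when all expected cell counts
#' exceed five, Fisher exact otherwise) and positively associated
#' (`phi > 0`). All seven co-occurrence measures are computed for retained
#' dyads.
#'
#' @param cohort a [cohort_matrix()].
#' @param min_support minimum joint frequency for a dyad to be a candidate
#'   (default 15).
#' @param alpha significance level; dyads with `p_value >= alpha` are
#'   excluded (default 0.01).
#' @param correct apply Yates continuity correction on the chi-square
#'   branch (default `FALSE`).
#' @return a data frame of class `association_table` with one row per
#'   retained dyad, ordered by pair label, and columns `pair_x`, `pair_y`,
#'   `a`, `b`, `c`, `d`, `n`, `test_used`, `p_value` and the seven measures.
#'   Attributes `n_candidates`, `n_excluded` and `filter_params` record the
#'   filter accounting.
#' @export
build_association_table <- function(cohort, min_support = 15, alpha = 0.01,
                                    correct = FALSE) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (min_support < 1) stop("min_support must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be strictly inside (0, 1)")
  x <- cohort$incidence
  if (nrow(x) == 0 || ncol(x) < 2) stop("cohort must be nonempty with >= 2 conditions")
  n <- nrow(x)
  k <- ncol(x)
  labels <- cohort$condition_labels

  joint <- crossprod(x)                       # a for every pair
  margin <- diag(joint)
  idx <- which(upper.tri(joint), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  a <- as.numeric(joint[idx])
  b <- as.numeric(margin[i]) - a
  cc <- as.numeric(margin[j]) - a
  d <- n - a - b - cc

  cand <- a >= min_support
  n_candidates <- sum(cand)
  i <- i[cand]; j <- j[cand]
  a <- a[cand]; b <- b[cand]; cc <- cc[cand]; d <- d[cand]

  # significance: closed-form chi-square where Cochran's rule holds,
  # Fisher exact elsewhere
  row1 <- a + b; row2 <- cc + d; col1 <- a + cc; col2 <- b + d
  min_margin_prod <- pmin(row1, row2) * pmin(col1, col2)
  use_chi <- min_margin_prod / n > 5 & row1 > 0 & row2 > 0 & col1 > 0 & col2 > 0
  p <- rep(1.0, length(a))
  test_used <- rep("fisher_exact", length(a))
  if (any(use_chi)) {
    stat <- chi_square_stat(a[use_chi], b[use_chi], cc[use_chi], d[use_chi],
                            n, correct = correct)
    p[use_chi] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    test_used[use_chi] <- "chi_square"
  }
  need_fisher <- which(!use_chi & row1 > 0 & row2 > 0 & col1 > 0 & col2 > 0)
  for (r in need_fisher) {
    m <- matrix(c(a[r], cc[r], b[r], d[r]), nrow = 2)
    p[r] <- stats::fisher.test(m)$p.value
  }

  phi <- measure_phi(a, b, cc, d, n)
  keep <- p < alpha & !is.na(phi) & phi > 0
  n_excluded <- n_candidates - sum(keep)

  i <- i[keep]; j <- j[keep]
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]; d <- d[keep]
  out <- data.frame(
    pair_x = labels[i],
    pair_y = labels[j],
    a = a, b = b, c = cc, d = d, n = rep(n, length(a)),
    test_used = test_used[keep],
    p_value = p[keep],
    lift = measure_lift(a, b, cc, d, n),
    relative_risk = measure_relative_risk(a, b, cc, d, n),
    phi = phi[keep],
    jaccard = measure_jaccard(a, b, cc, d, n),
    cosine = measure_cosine(a, b, cc, d, n),
    kulczynski = measure_kulczynski(a, b, cc, d, n),
    joint_prevalence = measure_joint_prevalence(a, b, cc, d, n),
    stringsAsFactors = FALSE
  )
  # canonical unordered pair orientation: pair_x < pair_y lexicographically
  flip <- out$pair_x > out$pair_y
  if (any(flip)) {
    tmp <- out$pair_x[flip]
    out$pair_x[flip] <- out$pair_y[flip]
    out$pair_y[flip] <- tmp
    tmp <- out$b[flip]
    out$b[flip] <- out$c[flip]
    out$c[flip] <- tmp
  }
  out <- out[order(out$pair_x, out$pair_y), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("association_table", "data.frame"),
            n_candidates = n_candidates,
            n_excluded = n_excluded,
            filter_params = list(min_support = min_support, alpha = alpha))
}

#' @export
print.association_table <- function(x, ...) {
  acc <- association_accounting(x)
  cat(sprintf(
    "<association_table> Out of %d candidate dyads (support >= %g), %d (%.1f%%) were excluded; %d associations remained.\n",
    acc$n_candidates, attr(x, "filter_params")$min_support, acc$n_excluded,
    if (acc$n_candidates > 0) 100 * acc$n_excluded / acc$n_candidates else 0,
    acc$n_retained
  ))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Filter accounting of an association table
#'
#' @param assoc an [build_association_table()] result.
#' @return list with `n_candidates`, `n_excluded`, `n_retained`.
#' @export
association_accounting <- function(assoc) {
  stopifnot(inherits(assoc, "association_table"))
  list(n_candidates = as.integer(attr(assoc, "n_candidates")),
       n_excluded = as.integer(attr(assoc, "n_excluded")),
       n_retained = nrow(assoc))
}

#' Write / read an association table as CSV
#'
#' The CSV mirrors the in-memory columns; the filter accounting travels in
#' a `# n_candidates,n_excluded,min_support,alpha` comment-style first line.
#'
#' @param assoc an association table.
#' @param path file path.
#' @rdname association_io
#' @export
write_association_csv <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_table"))
  acc <- association_accounting(assoc)
  fp <- attr(assoc, "filter_params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_candidates=%d n_excluded=%d min_support=%g alpha=%g",
                     acc$n_candidates, acc$n_excluded,
                     fp$min_support, fp$alpha), con)
  utils::write.csv(as.data.frame(assoc), con, row.names = FALSE)
}

#' @rdname association_io
#' @export
read_association_csv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- as.numeric(regmatches(header, gregexpr("[0-9.]+", header))[[1]])
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(out,
            class = c("association_table", "data.frame"),
            n_candidates = as.integer(meta[1]),
            n_excluded = as.integer(meta[2]),
            filter_params = list(min_support = meta[3], alpha = meta[4]))
}
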