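worked_table <- contingency_table(15, 5, 10, 70)

test_that("measures reproduce hand-computed values on the worked table", {
  expect_equal(lift(worked_table), 3.0)
  expect_equal(relative_risk(worked_table), 9.0)
  expect_equal(phi_coefficient(worked_table), 1000 / sqrt(3e6))
  expect_equal(phi_coefficient(worked_table), 0.57735, tolerance = 1e-5)
  expect_equal(jaccard(worked_table), 0.5)
  expect_equal(cosine_coefficient(worked_table), 15 / sqrt(500))
  expect_equal(kulczynski(worked_table), 0.675)
  expect_equal(joint_prevalence(worked_table), 0.15)
})

test_that("independence point: ad = bc gives lift 1, RR 1, phi 0", {
  t <- contingency_table(10, 10, 40, 40)
  expect_equal(lift(t), 1.0)
  expect_equal(relative_risk(t), 1.0)
  expect_equal(phi_coefficient(t), 0.0)
})

test_that("perfect association saturates the bounded measures", {
  t <- contingency_table(20, 0, 0, 80)
  expect_equal(lift(t), 5.0)
  expect_equal(phi_coefficient(t), 1.0)
  expect_equal(jaccard(t), 1.0)
  expect_equal(cosine_coefficient(t), 1.0)
  expect_equal(kulczynski(t), 1.0)
  expect_warning(rr <- relative_risk(t), "infinite")
  expect_identical(rr, Inf)
})

test_that("count_contingency counts cells directly", {
  coh <- cohort_matrix(matrix(c(1, 1, 0, 1, 0, 0), nrow = 3,
                              dimnames = list(NULL, c("x", "y"))))
  t <- count_contingency(coh, "x", "y")
  expect_equal(unlist(t[c("a", "b", "c", "d", "n")]),
               c(a = 1, b = 1, c = 0, d = 1, n = 3))
  expect_error(count_contingency(coh, "x", "x"), "differ")
  expect_error(count_contingency(coh, "x", "z"), "unknown")
})

test_that("contingency tables match the per-person loop oracle on random cohorts", {
  coh <- random_cohort(500, 8, p = 0.25, seed = 31)
  for (pair in combn(8, 2, simplify = FALSE)) {
    lx <- coh$condition_labels[pair[1]]
    ly <- coh$condition_labels[pair[2]]
    t <- count_contingency(coh, lx, ly)
    z <- oracle_cells(coh$incidence[, lx], coh$incidence[, ly])
    expect_equal(unlist(t[c("a", "b", "c", "d", "n")]), as.numeric(z),
                 ignore_attr = TRUE)
    expect_equal(t$a + t$b + t$c + t$d, t$n)
  }
})

test_that("all seven measures agree with the indicator-vector oracle", {
  coh <- random_cohort(400, 6, p = 0.35, seed = 77)
  for (pair in combn(6, 2, simplify = FALSE)) {
    lx <- coh$condition_labels[pair[1]]
    ly <- coh$condition_labels[pair[2]]
    got <- suppressWarnings(all_measures(count_contingency(coh, lx, ly)))
    want <- oracle_measures(coh$incidence[, lx], coh$incidence[, ly])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("null-invariance holds for Jaccard/cosine/Kulczynski and fails elsewhere", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      a <- sample(1:50, 1); b <- sample(0:30, 1); cc <- sample(0:30, 1)
      d1 <- sample(1:100, 1); d2 <- d1 + sample(1:500, 1)
      t1 <- contingency_table(a, b, cc, d1)
      t2 <- contingency_table(a, b, cc, d2)
      expect_identical(jaccard(t1), jaccard(t2))
      expect_identical(cosine_coefficient(t1), cosine_coefficient(t2))
      expect_identical(kulczynski(t1), kulczynski(t2))
      expect_false(isTRUE(all.equal(lift(t1), lift(t2))))
      expect_false(isTRUE(all.equal(joint_prevalence(t1), joint_prevalence(t2))))
      if (b > 0 && cc > 0) {
        expect_false(isTRUE(all.equal(phi_coefficient(t1), phi_coefficient(t2))))
        expect_false(isTRUE(all.equal(relative_risk(t1), relative_risk(t2))))
      }
    }
  })
})

test_that("phi is inversion-invariant; Jaccard is not", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      a <- sample(1:40, 1); b <- sample(1:40, 1)
      cc <- sample(1:40, 1); d <- sample(41:200, 1)
      t <- contingency_table(a, b, cc, d)
      t_inv <- contingency_table(d, cc, b, a)
      expect_identical(phi_coefficient(t), phi_coefficient(t_inv))
      if (a != d) {
        expect_false(isTRUE(all.equal(jaccard(t), jaccard(t_inv))))
      }
    }
  })
})

test_that("measure inequalities and identities hold on random tables", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      a <- sample(1:60, 1); b <- sample(0:40, 1)
      cc <- sample(0:40, 1); d <- sample(1:300, 1)
      t <- contingency_table(a, b, cc, d)
      # kulczynski >= cosine >= jaccard (arithmetic >= geometric mean)
      expect_gte(kulczynski(t), cosine_coefficient(t) - 1e-12)
      expect_gte(cosine_coefficient(t), jaccard(t) - 1e-12)
      # cosine^2 = lift * joint_prevalence
      expect_equal(cosine_coefficient(t)^2, lift(t) * joint_prevalence(t),
                   tolerance = 1e-12)
      # chi-square statistic = n * phi^2
      expect_equal(comorbnet:::chi_square_stat(t$a, t$b, t$c, t$d, t$n),
                   t$n * phi_coefficient(t)^2, tolerance = 1e-12)
      # symmetry in the two conditions (b <-> c swap)
      t_sw <- contingency_table(a, cc, b, d)
      expect_equal(suppressWarnings(all_measures(t)),
                   suppressWarnings(all_measures(t_sw)), tolerance = 1e-12)
    }
  })
})

test_that("significance test follows the Cochran branch rule", {
  # all expected counts > 5: chi-square, statistic n * phi^2 = 4
  res <- significance_test(contingency_table(30, 20, 20, 30))
  expect_equal(res$test_used, "chi_square")
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE))
  # chi-square branch agrees with stats::chisq.test without correction
  t <- contingency_table(40, 25, 18, 60)
  res <- significance_test(t)
  ref <- chisq.test(matrix(c(40, 18, 25, 60), 2), correct = FALSE)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  # small expected count: Fisher
  res <- significance_test(contingency_table(3, 2, 2, 93))
  expect_equal(res$test_used, "fisher_exact")
  # boundary: expected exactly 5 is NOT > 5, so Fisher
  res <- significance_test(contingency_table(15, 5, 10, 70))
  expect_equal(res$test_used, "fisher_exact")
  expect_equal(res$p_value,
               fisher.test(matrix(c(15, 10, 5, 70), 2))$p.value,
               tolerance = 1e-12)
  # degenerate table
  res <- significance_test(contingency_table(0, 0, 5, 95))
  expect_equal(res$p_value, 1.0)
  expect_equal(res$test_used, "fisher_exact")
})

test_that("association table filters and accounting are consistent", {
  # identical columns: pair retained with jaccard 1
  withr::with_seed(8, {
    x <- rbinom(400, 1, 0.3)
    inc <- cbind(A = x, B = x, C = rbinom(400, 1, 0.3))
  })
  assoc <- build_association_table(cohort_matrix(inc), min_support = 15)
  acc <- association_accounting(assoc)
  expect_equal(acc$n_candidates - acc$n_excluded, acc$n_retained)
  ab <- assoc[assoc$pair_x == "A" & assoc$pair_y == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$jaccard, 1.0)
  expect_true(all(assoc$a >= 15))
  expect_true(all(assoc$p_value < 0.01))
  expect_true(all(assoc$phi > 0))
  # stable, lexicographic pair ordering
  expect_true(all(assoc$pair_x < assoc$pair_y))
  expect_false(is.unsorted(paste(assoc$pair_x, assoc$pair_y)))
  expect_error(build_association_table(cohort_matrix(inc), min_support = 0),
               "min_support")
  expect_error(build_association_table(cohort_matrix(inc), alpha = 1.1),
               "alpha")
})

test_that("bulk association path matches the per-pair operations", {
  coh <- random_cohort(300, 6, p = 0.4, seed = 404)
  assoc <- build_association_table(coh, min_support = 5, alpha = 0.5)
  for (r in seq_len(nrow(assoc))) {
    t <- count_contingency(coh, assoc$pair_x[r], assoc$pair_y[r])
    expect_equal(assoc$a[r], t$a)
    ref <- suppressWarnings(all_measures(t))
    got <- unlist(assoc[r, names(ref)])
    expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
    st <- significance_test(t)
    expect_equal(assoc$p_value[r], st$p_value, tolerance = 1e-12)
    expect_equal(assoc$test_used[r], st$test_used)
  }
})

test_that("association tables round-trip through CSV", {
  coh <- random_cohort(300, 5, p = 0.4, seed = 12)
  assoc <- build_association_table(coh, min_support = 5, alpha = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_association_csv(assoc, path)
  back <- read_association_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(assoc), tolerance = 1e-12)
  expect_equal(association_accounting(back), association_accounting(assoc))
})
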