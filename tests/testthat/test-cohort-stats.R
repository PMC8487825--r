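# Group summaries, one-way ANOVA, chi-square and incidence tables, against
# textbook-formula oracles.

test_that("group summaries report mean and sample SD per group", {
  s <- group_summary(c(1, 1, 1, 2, 4, 6), rep(c("A", "B"), each = 3))
  expect_equal(s$mean, c(1, 4))
  expect_equal(s$sd, c(0, 2))
  expect_equal(s$n, c(3L, 3L))
  expect_equal(s$label[2], "4.00 ± 2.00")
  expect_error(group_summary(1:3, c("A", "A", NA)), "empty group|length")
})

test_that("one-way ANOVA matches the explicit sums-of-squares oracle", {
  # textbook-style 3x3 dataset
  vals <- c(6, 8, 4, 5, 4, 3, 8, 9, 7)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  got <- anova_oneway(vals, grp, "toy")
  want <- oracle_anova_F(vals, grp)
  expect_equal(got$statistic, want$F, tolerance = 1e-10)
  expect_equal(got$df, c(want$df1, want$df2))
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  # random data oracle check
  withr::with_seed(41, {
    v <- rnorm(60); g <- sample(c("A", "B", "C"), 60, replace = TRUE)
  })
  got2 <- anova_oneway(v, g)
  want2 <- oracle_anova_F(v, g)
  expect_equal(got2$statistic, want2$F, tolerance = 1e-10)
  expect_equal(got2$p_value, want2$p, tolerance = 1e-10)
})

test_that("with two groups F equals the squared pooled t statistic", {
  withr::with_seed(42, { x <- rnorm(12, 0, 1); y <- rnorm(15, 0.8, 1) })
  got <- anova_oneway(c(x, y), rep(c("x", "y"), c(12, 15)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA near-null and degenerate cases behave", {
  withr::with_seed(43, v <- rnorm(30))
  base <- rep(c("A", "B", "C"), each = 10)
  got <- anova_oneway(v - stats::ave(v, base), base)  # identical group means
  expect_equal(got$statistic, 0, tolerance = 1e-10)
  expect_equal(got$p_value, 1, tolerance = 1e-10)
  expect_error(anova_oneway(rep(1, 9), rep(c("A", "B", "C"), 3)), "identical")
  expect_error(anova_oneway(1:5, rep("A", 5)), "2 groups")
})

test_that("chi-square matches the hand (O-E)^2/E computation", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  got <- chi_square(tab)
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(got$df, 1)
  want <- oracle_chisq(tab)
  expect_equal(got$statistic, want$X2, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  # observed equal to expected, and proportional rows: X2 = 0, p = 1
  expect_equal(chi_square(matrix(25, 2, 2))$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square(matrix(25, 2, 2))$p_value, 1)
  prop <- rbind(c(10, 30), c(20, 60))
  expect_equal(chi_square(prop)$statistic, 0, tolerance = 1e-12)
  # 3x2 random table against the oracle
  t2 <- matrix(c(12, 7, 21, 9, 14, 18), 3, 2)
  expect_equal(chi_square(t2)$statistic, oracle_chisq(t2)$X2, tolerance = 1e-10)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("incidence tables count exact rational proportions", {
  coh <- generate_cohort(n_per_group = 2, seed = 6)
  # toy check by direct counting on the annotated table
  ann <- annotate_cohort(coh)
  it <- incidence_table(coh, "grade_ge_I")
  for (g in c("A", "B", "C")) {
    all_row <- it$table[it$table$group == g & it$table$segment == "all", ]
    expect_equal(all_row$total, sum(ann$group == g))
    expect_equal(all_row$affected,
                 sum(ann$grade_derived[ann$group == g] >= "I"))
    expect_equal(all_row$proportion, all_row$affected / all_row$total)
  }
  seg_tot <- it$table[it$table$segment != "all", ]
  expect_equal(sum(seg_tot$total), nrow(coh))
  expect_error(incidence_table(coh, "nope"), "unknown predicate")
  expect_error(incidence_table(coh[0, ], "plaque"), "empty")
})

test_that("incidence predicates cover plaque and IMT thickening", {
  coh <- generate_cohort(n_per_group = 10, seed = 7)
  ann <- annotate_cohort(coh)
  itp <- incidence_table(coh, "plaque")
  expect_equal(itp$table$affected[itp$table$segment == "all"],
               as.vector(tapply(ann$plaque_call, ann$group, sum)))
  iti <- incidence_table(coh, "imt_thickened")
  expect_equal(iti$table$affected[iti$table$segment == "all"],
               as.vector(tapply(ann$imt_class == "thickened", ann$group, sum)))
})

test_that("full comparison report is deterministic and detects the calibrated contrasts", {
  coh <- generate_cohort(n_per_group = 30, seed = 8)
  rep1 <- run_full_comparison(coh)
  rep2 <- run_full_comparison(coh)
  expect_identical(rep1, rep2)
  # IMT separates the groups at this effect size
  expect_true(all(vapply(rep1$imt, function(x) x$p_value < 0.05, TRUE)))
  # demographics generated from identical contrasts should rarely separate;
  # check structure rather than significance
  expect_named(rep1$demographic_tests, c("age", "tc", "tg", "sex", "smoker"))
  expect_equal(rep1$stenosis_ge_I$predicate, "grade_ge_I")
  expect_error(run_full_comparison(coh[coh$group != "C", ]), "A, B and C")
})

test_that("report files are written and byte-stable", {
  coh <- generate_cohort(n_per_group = 6, seed = 12)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  run_full_comparison(coh, td1)
  run_full_comparison(coh, td2)
  for (f in list.files(td1)) {
    expect_true(file.exists(file.path(td2, f)))
    expect_identical(readLines(file.path(td1, f), warn = FALSE),
                     readLines(file.path(td2, f), warn = FALSE))
  }
  expect_true(file.exists(file.path(td1, "report.txt")))
})

test_that("type-I error of ANOVA and chi-square wrappers is near 0.05 under the null", {
  nrep <- 400
  withr::with_seed(55, {
    rej_a <- mean(replicate(nrep, {
      anova_oneway(rnorm(90), rep(c("A", "B", "C"), each = 30))$p_value < 0.05
    }))
    rej_c <- mean(replicate(nrep, {
      tab <- cbind(rbinom(3, 100, 0.3))
      tab <- cbind(tab, 100 - tab)
      chi_square(tab)$p_value < 0.05
    }))
  })
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej_a - 0.05), 3 * se + 1e-9)
  expect_lt(abs(rej_c - 0.05), 3 * se + 0.01)  # small-sample discreteness slack
})
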