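# Wilcoxon signed-rank implementation, summaries, counts, subgroups, report.

test_that("exact Wilcoxon agrees with the reference implementation when tie-free", {
  set.seed(51)
  for (i in 1:10) {
    d <- round(rnorm(10, 0.3, 1), 3)
    d <- d[d != 0]
    ours <- wilcoxon_signed_rank(d, method = "exact")
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$W, unname(ref$statistic))
  }
})

test_that("asymptotic Wilcoxon matches the tie-corrected normal approximation", {
  set.seed(52)
  for (i in 1:10) {
    d <- round(rnorm(15, 0.2, 1), 2)
    d <- d[d != 0]
    ours <- wilcoxon_signed_rank(d, method = "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("twelve same-sign tie-free differences give exact p = 2/4096", {
  d <- -(1:12) - 0.5
  res <- wilcoxon_signed_rank(d, method = "exact")
  expect_equal(res$W, 0)
  expect_equal(res$p, 2 / 4096, tolerance = 1e-12)
})

test_that("positive and negative rank sums always partition n(n+1)/2", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    d <- round(rnorm(n, 0, 1), 1)
    d <- d[d != 0]
    if (length(d) < 1) next
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$W + res$W_neg, res$n * (res$n + 1) / 2)
  }
})

test_that("exact and asymptotic p-values agree within 0.01 for n >= 20", {
  set.seed(54)
  for (i in 1:10) {
    d <- round(rnorm(22, 0.25, 1), 2)
    d <- d[d != 0]
    p_exact <- wilcoxon_signed_rank(d, method = "exact")$p
    p_norm <- wilcoxon_signed_rank(d, method = "normal", continuity = TRUE)$p
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("degenerate difference vectors are rejected", {
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "no nonzero pairs")
  expect_error(wilcoxon_signed_rank(c(1, NA)), "finite")
  expect_error(wilcoxon_signed_rank(rnorm(30), method = "exact"), "n <= 25")
})

test_that("summaries expose the SD divisor explicitly", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  s_pop <- summarize_values(x, sd_divisor = "n")
  s_smp <- summarize_values(x, sd_divisor = "n-1")
  expect_equal(s_pop$sd, 2)
  n <- length(x)
  expect_equal(s_smp$sd, s_pop$sd * sqrt(n / (n - 1)))
  expect_equal(summarize_values(rep(3, 5), "n")$sd, 0)
  expect_true(is.na(summarize_values(7)$sd))
  s <- summarize_values(c(-1, -2, 3, 0))
  expect_equal(s$n_negative, 2)
  expect_equal(s$n_positive, 1)
  expect_equal(s$n_zero, 1)
})

test_that("event counts and percentages", {
  r <- count_events(c(-1, 2, -3), "negative")
  expect_equal(r$count, 2)
  expect_equal(round(r$percent, 1), 66.7)
  expect_equal(count_events(numeric(0), "positive"),
               list(count = 0L, n = 0L, percent = 0))
  r2 <- count_events(c(-7, -8, 1), function(x) x < -6)
  expect_equal(r2$count, 2)
})

test_that("subgroup means validate group labels", {
  v <- c(10, 20, 30, 40)
  g <- c("M", "F", "M", "F")
  m <- subgroup_means(v, g, expected = c("M", "F"))
  expect_equal(unname(m[c("M", "F")]), c(20, 30))
  expect_error(subgroup_means(v, c("M", "F", "X", "F"),
                              expected = c("M", "F")), "unknown group")
  expect_equal(unname(subgroup_means(v, rep("a", 4))["a"]), mean(v))
})

test_that("the cohort report is deterministic and flags incomplete rows", {
  cohort <- load_reference_cohort()
  meas <- reference_measurements(cohort)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rep1 <- build_cohort_report(meas, out_dir = d1)
  rep2 <- build_cohort_report(meas, out_dir = d2)
  expect_identical(readBin(file.path(d1, "tests.csv"), raw(), 1e6),
                   readBin(file.path(d2, "tests.csv"), raw(), 1e6))
  expect_identical(readBin(file.path(d1, "summary.csv"), raw(), 1e6),
                   readBin(file.path(d2, "summary.csv"), raw(), 1e6))
  # a missing delta is excluded with a message, tests still run
  meas_bad <- meas
  meas_bad$delta[3] <- NA
  expect_message(rep3 <- build_cohort_report(meas_bad), "excluded")
  expect_true(all(is.finite(rep3$tests$p)))
  # identical pre/post: not computable, reported as such
  same <- data.frame(patient = 1:5, side = "right", variable = "height_mm",
                     delta = 0)
  rep4 <- build_cohort_report(same)
  expect_identical(rep4$tests$method, "not-computable")
  expect_true(is.na(rep4$tests$p))
})

test_that("the bundled reference fixture is structurally sound and flags known cell inconsistencies", {
  cohort <- load_reference_cohort()
  expect_identical(nrow(cohort$demographics), 12L)
  expect_identical(nrow(cohort$changes), 12L)
  expect_identical(sum(cohort$demographics$sex == "F"), 4L)
  expect_identical(sum(cohort$demographics$dysmorphism == "II"), 2L)
  flags <- validate_reference_changes(cohort)
  # two published cells disagree with their own pre/post values:
  # patient 1 left prints -36.1% (cells give -38.1%) and patient 7 left
  # prints -38.9% (cells give -39.9%); both ship as printed
  expect_true(any(flags$patient == 1 & flags$cell == "density_left_pct"))
  expect_true(any(flags$patient == 7 & flags$cell == "density_left_pct"))
  expect_identical(nrow(flags), 2L)
})
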