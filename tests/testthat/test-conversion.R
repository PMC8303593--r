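# Conversion factors, summaries, side averaging, signed-rank inference.

diam_row <- function(subject, side, site, structure, modality, plane, mm)
  data.frame(subject = subject, side = side, site = site,
             structure = structure, modality = modality, plane = plane,
             diameter_mm = mm, stringsAsFactors = FALSE)

test_that("observations are the stated per-plane ratios", {
  d <- rbind(
    diam_row("S1", "left", "M3", "IAC", "CBCT", "axial", 4.0),
    diam_row("S1", "left", "M3", "IAC", "MRI", "axial", 3.0),
    diam_row("S1", "left", "M3", "IAN", "MRI", "axial", 2.0))
  obs <- compute_observations(d)
  expect_equal(obs$value[obs$factor_type == "CBCT_IAC_over_MRI_IAN"], 2.0)
  expect_equal(obs$value[obs$factor_type == "MRI_IAC_over_MRI_IAN"], 1.5)
  # identical masks: all factors 1
  d2 <- rbind(diam_row("S1", "left", "M3", "IAC", "MRI", "coronal", 3.3),
              diam_row("S1", "left", "M3", "IAN", "MRI", "coronal", 3.3))
  expect_equal(compute_observations(d2)$value, 1.0)
  # non-positive nerve diameter is a data error
  d3 <- rbind(diam_row("S1", "left", "M3", "IAC", "MRI", "axial", 3),
              diam_row("S1", "left", "M3", "IAN", "MRI", "axial", 0))
  expect_error(compute_observations(d3), class = "data_error")
})

test_that("summaries are the mean of ratios, not the ratio of means", {
  d <- rbind(
    diam_row("S1", "left", "M3", "IAC", "MRI", "axial", 4),
    diam_row("S1", "left", "M3", "IAN", "MRI", "axial", 1),
    diam_row("S2", "left", "M3", "IAC", "MRI", "axial", 2),
    diam_row("S2", "left", "M3", "IAN", "MRI", "axial", 2))
  s <- summarize_factors(compute_observations(d))
  expect_equal(s$mean, 2.5)            # (4/1 + 2/2) / 2
  expect_false(isTRUE(all.equal(s$mean, (4 + 2) / (1 + 2))))  # != 1.5
  expect_equal(s$sd, stats::sd(c(4, 1)))
  # hand-computed pair: {1, 3} -> mean 2, sd sqrt(2)
  d2 <- rbind(
    diam_row("S1", "left", "M3", "IAC", "MRI", "axial", 1),
    diam_row("S1", "left", "M3", "IAN", "MRI", "axial", 1),
    diam_row("S1", "right", "M3", "IAC", "MRI", "axial", 3),
    diam_row("S1", "right", "M3", "IAN", "MRI", "axial", 1))
  s2 <- summarize_factors(compute_observations(d2))
  expect_equal(s2$n, 2L)
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2))
  # n = 1 reports an undefined SD
  s3 <- summarize_factors(compute_observations(
    rbind(diam_row("S1", "left", "M3", "IAC", "MRI", "axial", 4),
          diam_row("S1", "left", "M3", "IAN", "MRI", "axial", 2))))
  expect_true(is.na(s3$sd))
})

test_that("side averaging leaves one value per subject", {
  obs <- data.frame(subject = c("S1", "S1", "S2"),
                    side = c("left", "right", "left"),
                    site = "M3", plane = "axial",
                    factor_type = "MRI_IAC_over_MRI_IAN",
                    value = c(1.8, 2.2, 2.4))
  av <- side_average(obs)
  expect_equal(nrow(av), 2L)
  expect_equal(av$value[av$subject == "S1"], 2.0)
  expect_equal(av$value[av$subject == "S2"], 2.4)
})

test_that("scale invariance: common rescaling leaves factors unchanged", {
  set.seed(21)
  d <- NULL
  for (i in 1:6) for (side in c("left", "right")) {
    ian <- stats::runif(1, 2, 3)
    d <- rbind(d,
      diam_row(sprintf("S%d", i), side, "M3", "IAN", "MRI", "axial", ian),
      diam_row(sprintf("S%d", i), side, "M3", "IAC", "MRI", "axial",
               ian * stats::runif(1, 1.2, 2)),
      diam_row(sprintf("S%d", i), side, "M3", "IAC", "CBCT", "axial",
               ian * stats::runif(1, 1.2, 2)))
  }
  o1 <- compute_observations(d)
  d2 <- d; d2$diameter_mm <- d2$diameter_mm * 3.7
  o2 <- compute_observations(d2)
  expect_equal(o1$value, o2$value)
})

test_that("exact signed-rank p-values match full enumeration up to n = 12", {
  set.seed(31)
  for (n in 3:12) {
    for (rep_i in 1:3) {
      d <- round(stats::rnorm(n, mean = 0.3), 4)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      res <- signed_rank_test(d)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, enumerate_signed_rank_p(d),
                   tolerance = 1e-12)
      # and agreement with the standard implementation
      ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
      expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(res$statistic, unname(ref$statistic))
    }
  }
})

test_that("all-positive differences give the textbook exact p", {
  res <- signed_rank_test(c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 2 / 2^5)
})

test_that("ties fall back to the corrected normal approximation", {
  d <- c(1, 1, -1, 2, 3, 3, -2, 4)
  res <- signed_rank_test(d)
  expect_match(res$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("zero handling: drop matches R default, Pratt keeps zero ranks", {
  d <- c(0, 0, 1, -2, 3, 4, -1.5, 2.5)
  drop <- signed_rank_test(d, "drop")
  ref <- suppressWarnings(stats::wilcox.test(d[d != 0], exact = TRUE))
  expect_equal(drop$p_value, unname(ref$p.value), tolerance = 1e-12)
  pratt <- signed_rank_test(d, "pratt")
  expect_equal(pratt$n_zero, 2L)
  expect_gt(pratt$statistic, drop$statistic)  # zeros shift the ranks up
  expect_true(pratt$p_value >= 0 && pratt$p_value <= 1)
})

test_that("degenerate all-zero differences report p = 1 without rejection", {
  res <- signed_rank_test(rep(0, 8))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_false(res$reject)
})

test_that("generator ratios are recovered by the summary within 2 SE", {
  for (r in c(1.3, 1.8, 2.4)) {
    set.seed(round(1000 * r))
    n <- 36
    ian <- stats::rnorm(n, 2.5, 0.3)
    d <- NULL
    for (i in seq_len(n)) {
      subj <- sprintf("S%02d", ceiling(i / 2))
      side <- if (i %% 2 == 0) "left" else "right"
      d <- rbind(d,
        diam_row(subj, side, "M3", "IAN", "MRI", "axial",
                 ian[i] * (1 + stats::rnorm(1, 0, 0.05))),
        diam_row(subj, side, "M3", "IAC", "MRI", "axial",
                 r * ian[i] * (1 + stats::rnorm(1, 0, 0.05))))
    }
    s <- summarize_factors(compute_observations(d))
    se <- s$sd / sqrt(s$n)
    expect_lt(abs(s$mean - r), 2 * se)
  }
})

test_that("paired comparison runs end to end and respects alpha", {
  set.seed(8)
  obs <- NULL
  for (i in 1:10) {
    v <- stats::runif(1, 1.5, 2.5)
    obs <- rbind(obs,
      data.frame(subject = sprintf("S%d", i), side = "left", site = "M3",
                 plane = "axial", factor_type = "CBCT_IAC_over_MRI_IAN",
                 value = v + 0.4 + stats::rnorm(1, 0, 0.05)),
      data.frame(subject = sprintf("S%d", i), side = "left", site = "M3",
                 plane = "axial", factor_type = "MRI_IAC_over_MRI_IAN",
                 value = v))
  }
  res <- compare_factors(obs, "M3", "axial")
  expect_s3_class(res, "wilcoxon_result")
  expect_equal(res$n_subjects, 10L)
  expect_true(res$reject)   # systematic +0.4 shift
  expect_warning(compare_factors(obs[obs$subject %in%
                                       c("S1", "S2", "S3"), ],
                                 "M3", "axial"),
                 "little power")
})
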