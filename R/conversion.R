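# Cross-modality conversion factors and the paired Wilcoxon design.
#
# A conversion factor is the per-observation ratio of a canal diameter
# (CBCT or MRI) to the nerve diameter (MRI) in one plane. Summaries are
# the mean and sample SD of the ratios over all subjects and sides
# (mean-of-ratios, not ratio-of-means). For inference the two factor types
# are first averaged over a subject's left and right sides, leaving one
# paired observation per participant, and their difference is tested
# against zero with a one-sample Wilcoxon signed-rank test at alpha 0.05.

FACTOR_TYPES <- c("CBCT_IAC_over_MRI_IAN", "MRI_IAC_over_MRI_IAN")

#' Compute per-observation conversion factors
#'
#' Joins canal and nerve diameters by subject/side/site/plane and forms
#' the two ratios IAC(CBCT)/IAN(MRI) and IAC(MRI)/IAN(MRI). Incomplete
#' pairs are skipped (and counted in the `n_skipped` attribute).
#'
#' @param diameters data frame with columns `subject`, `side`, `site`,
#'   `structure` (IAC/IAN), `modality` (CBCT/MRI), `plane`, `diameter_mm`.
#' @return Data frame of observations: `subject`, `side`, `site`, `plane`,
#'   `factor_type`, `value`.
#' @export
compute_observations <- function(diameters) {
  req <- c("subject", "side", "site", "structure", "modality", "plane",
           "diameter_mm")
  if (!all(req %in% names(diameters)))
    stop_input(paste("diameters must have columns:",
                     paste(req, collapse = ", ")))
  key <- c("subject", "side", "site", "plane")
  pick <- function(st, mo) {
    d <- diameters[diameters$structure == st & diameters$modality == mo, ]
    stats::setNames(d[, c(key, "diameter_mm")],
                    c(key, paste(st, mo, sep = "_")))
  }
  wide <- merge(pick("IAN", "MRI"), pick("IAC", "MRI"),
                by = key, all.x = TRUE)
  wide <- merge(wide, pick("IAC", "CBCT"), by = key, all.x = TRUE)
  if (any(!is.na(wide$IAN_MRI) & wide$IAN_MRI <= 0))
    stop_data("non-positive nerve diameter in the input")
  out <- list()
  n_skipped <- 0L
  specs <- list(c("CBCT_IAC_over_MRI_IAN", "IAC_CBCT"),
                c("MRI_IAC_over_MRI_IAN", "IAC_MRI"))
  for (sp in specs) {
    num <- wide[[sp[2]]]
    ok <- !is.na(num) & !is.na(wide$IAN_MRI)
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok))
      out[[sp[1]]] <- data.frame(
        wide[ok, key], factor_type = sp[1],
        value = num[ok] / wide$IAN_MRI[ok],
        stringsAsFactors = FALSE, row.names = NULL)
  }
  obs <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(obs, "n_skipped") <- n_skipped
  obs
}

#' Summarize conversion factors
#'
#' Arithmetic mean and sample SD (denominator n - 1) of the
#' per-observation ratios over all subjects and sides, by site, plane and
#' factor type. This is the mean of ratios, never the ratio of mean
#' diameters.
#'
#' @param observations data frame from [compute_observations()].
#' @return Data frame of class `conversion_summary` with columns `site`,
#'   `plane`, `factor_type`, `n`, `mean`, `sd` (`NA` when n = 1).
#' @export
summarize_factors <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0)
    stop_input("no observations to summarize")
  agg <- function(f) stats::aggregate(
    observations$value,
    by = observations[c("site", "plane", "factor_type")], FUN = f)
  out <- agg(length)
  names(out)[4] <- "n"
  out$mean <- agg(mean)$x
  out$sd <- agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)$x
  class(out) <- c("conversion_summary", "data.frame")
  out
}

#' @export
print.conversion_summary <- function(x, ...) {
  cat("<conversion_summary> mean +/- SD of per-observation ratios\n")
  y <- as.data.frame(x)
  y$mean <- round(y$mean, 3); y$sd <- round(y$sd, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Average observations over a subject's sides
#'
#' Collapses the multiple observations per subject to one value per
#' subject, site, plane and factor type (the mean over the available
#' sides; a single side passes through unchanged).
#'
#' @param observations data frame from [compute_observations()].
#' @return Data frame with columns `subject`, `site`, `plane`,
#'   `factor_type`, `value`.
#' @export
side_average <- function(observations) {
  stats::aggregate(
    value ~ subject + site + plane + factor_type,
    data = observations, FUN = mean)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether a set of differences is centered at zero. Zeros are
#' dropped before ranking by default (the classic procedure and the
#' default of standard statistical software); the Pratt variant keeps them
#' in the ranking. Without ties (and with `zero_handling = "drop"`) and at
#' most `exact_max_n` differences the exact null distribution of the
#' positive-rank sum is used; otherwise a normal approximation with
#' mid-ranks, tie correction and continuity correction.
#'
#' @param d numeric vector of differences.
#' @param zero_handling `"drop"` or `"pratt"`.
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @param alpha decision level (default 0.05; rejection when p <= alpha).
#' @return An object of class `wilcoxon_result`: `statistic` (positive
#'   rank sum V), `p_value`, `n` (differences used), `n_zero`, `method`,
#'   `zero_handling`, `reject`, `degenerate`.
#' @export
signed_rank_test <- function(d, zero_handling = c("drop", "pratt"),
                             exact_max_n = 25, alpha = 0.05) {
  zero_handling <- match.arg(zero_handling)
  d <- d[is.finite(d)]
  if (length(d) == 0) stop_input("no finite differences")
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    res <- list(statistic = 0, p_value = 1, n = 0L, n_zero = n_zero,
                method = "degenerate (all differences zero)",
                zero_handling = zero_handling, alpha = alpha,
                reject = FALSE, degenerate = TRUE)
    class(res) <- "wilcoxon_result"
    return(res)
  }
  if (zero_handling == "drop") {
    x <- d[d != 0]
    n <- length(x)
    r <- rank(abs(x))
    W <- sum(r[x > 0])
    ties <- anyDuplicated(abs(x)) > 0
    if (!ties && n <= exact_max_n) {
      p <- min(1, 2 * min(stats::psignrank(W, n),
                          1 - stats::psignrank(W - 1, n)))
      method <- "exact"
    } else {
      mu <- n * (n + 1) / 4
      tie_tab <- table(r)
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal approximation with tie correction"
    }
  } else {
    n <- length(d)
    m <- n - n_zero
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- (n * (n + 1) - n_zero * (n_zero + 1)) / 4
    tie_tab <- table(r[d != 0])
    sig2 <- (n * (n + 1) * (2 * n + 1) -
               n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Pratt (zeros ranked), normal approximation"
    n <- m
  }
  res <- list(statistic = W, p_value = p, n = as.integer(n),
              n_zero = n_zero, method = method,
              zero_handling = zero_handling, alpha = alpha,
              reject = p <= alpha, degenerate = FALSE)
  class(res) <- "wilcoxon_result"
  res
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> V = %.1f, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  cat(sprintf("  H0 'difference is zero' %s at alpha = %.2f\n",
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Compare the two conversion factors at one site and plane
#'
#' Side-averages both factor types to one observation per participant,
#' forms the per-subject difference CBCT-factor minus MRI-factor and runs
#' the one-sample Wilcoxon signed-rank test against zero.
#'
#' @param observations data frame from [compute_observations()].
#' @param site,plane the stratum to test.
#' @param zero_handling,exact_max_n,alpha passed to [signed_rank_test()].
#' @return A `wilcoxon_result` with `site`, `plane` and `n_subjects` added.
#' @export
compare_factors <- function(observations, site, plane,
                            zero_handling = "drop", exact_max_n = 25,
                            alpha = 0.05) {
  per <- side_average(observations[observations$site == site &
                                     observations$plane == plane, ])
  a <- per[per$factor_type == FACTOR_TYPES[1], c("subject", "value")]
  b <- per[per$factor_type == FACTOR_TYPES[2], c("subject", "value")]
  paired <- merge(a, b, by = "subject", suffixes = c("_cbct", "_mri"))
  if (nrow(paired) == 0)
    stop_input(sprintf("no paired subjects at %s/%s", site, plane))
  if (nrow(paired) < 6)
    warning(sprintf("only %d paired subjects at %s/%s: the test has ",
                    nrow(paired), site, plane),
            "little power and no attainable p < 0.05 below n = 6")
  res <- signed_rank_test(paired$value_cbct - paired$value_mri,
                          zero_handling = zero_handling,
                          exact_max_n = exact_max_n, alpha = alpha)
  res$site <- site
  res$plane <- plane
  res$n_subjects <- nrow(paired)
  res
}
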