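#' Subsampled Wilcoxon rank-sum comparison
#'
#' Compares two samples with repeated two-sided Wilcoxon rank-sum tests on
#' equal-size subsamples, so that unequal and large group sizes do not bias
#' the test: each iteration draws `n` values from each group without
#' replacement (independently across iterations) and runs the rank-sum test
#' with tie correction under the normal approximation. The arithmetic mean
#' of the iteration p-values is the reported summary; the full p-value
#' distribution is kept because a mean p is an unconventional statistic and
#' quantiles are often more informative.
#'
#' @param x,y Numeric samples.
#' @param n Subsample size per group (default 300). If a group is smaller,
#'   `n` is lowered to the smaller group size with a warning.
#' @param iterations Number of subsample iterations (default 10000).
#' @param seed Integer seed; the run is exactly reproducible for a fixed
#'   seed and unaffected by the caller's RNG state.
#' @param replace Draw subsamples with replacement (bootstrap mode).
#' @param labels Length-2 character vector naming the groups.
#' @return A `trab_comparison` object: list with `p_values`, `mean_p`,
#'   `n`, `iterations`, `seed`, `labels`.
#' @examples
#' r <- subsampled_wilcoxon(rnorm(400), rnorm(400), n = 100,
#'                          iterations = 50, seed = 1)
#' r$mean_p
#' @export
subsampled_wilcoxon <- function(x, y, n = 300, iterations = 10000,
                                seed = NULL, replace = FALSE,
                                labels = c("x", "y")) {
  # sorting makes subsample draws independent of the caller's data order
  # (permutation invariance) without affecting the test statistic
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  if (length(x) == 0 || length(y) == 0) abort("empty group")
  if (iterations < 1) abort("`iterations` must be >= 1")
  n_min <- min(length(x), length(y))
  if (!replace && n > n_min) {
    warn(sprintf("subsample size lowered from %d to %d (smallest group)",
                 n, n_min))
    n <- n_min
  }
  run <- function() {
    vapply(seq_len(iterations), function(i) {
      xi <- if (replace) sample(x, n, replace = TRUE) else
        x[sample.int(length(x), n)]
      yi <- if (replace) sample(y, n, replace = TRUE) else
        y[sample.int(length(y), n)]
      suppressWarnings(
        stats::wilcox.test(xi, yi, alternative = "two.sided",
                           exact = FALSE, correct = FALSE)$p.value
      )
    }, 0)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(
      p_values = p, mean_p = mean(p), n = n, iterations = iterations,
      seed = seed, replace = replace, labels = labels,
      method = "subsampled Wilcoxon rank-sum (two-sided, normal approx.)"
    ),
    class = "trab_comparison"
  )
}

#' @export
print.trab_comparison <- function(x, ...) {
  cat(sprintf(
    "<trab_comparison> %s vs %s: mean p = %.4g (n = %d per group, %d iterations)\n",
    x$labels[1], x$labels[2], x$mean_p, x$n, x$iterations
  ))
  invisible(x)
}

#' Tidy a subsampled comparison
#'
#' `tidy()` returns one row per summary statistic of the p-value
#' distribution; `glance()` returns a one-row overview.
#'
#' @param x A `trab_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trab_comparison <- function(x, ...) {
  tibble(
    group1 = x$labels[1], group2 = x$labels[2],
    mean_p = x$mean_p,
    median_p = median(x$p_values),
    p05 = unname(quantile(x$p_values, 0.05)),
    p95 = unname(quantile(x$p_values, 0.95)),
    frac_below_05 = mean(x$p_values < 0.05)
  )
}

#' @rdname tidy.trab_comparison
#' @export
glance.trab_comparison <- function(x, ...) {
  tibble(
    mean_p = x$mean_p, n = x$n, iterations = x$iterations,
    seed = x$seed %||% NA_integer_, method = x$method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

new_disttest <- function(test, statistic, df, p_value, n) {
  tibble(test = test, statistic = statistic, df = df,
         p_value = p_value, n = n)
}

#' Shapiro-Wilk normality test
#'
#' Wraps the standard Shapiro-Wilk test. The algorithm is limited to 5000
#' values; larger samples are subsampled (seeded) down to `max_n` and the
#' subsampling is recorded in the `subsampled` column.
#'
#' @param x Numeric sample of at least 3 distinct values.
#' @param max_n Algorithmic sample-size limit (<= 5000).
#' @param seed Seed for the subsampling of large samples.
#' @return A one-row tibble: `test`, `statistic` (W), `df` (NA), `p_value`,
#'   `n`, `subsampled`.
#' @export
shapiro_wilk <- function(x, max_n = 5000, seed = 1) {
  x <- x[!is.na(x)]
  n0 <- length(x)
  if (n0 < 3) abort("Shapiro-Wilk requires at least 3 values")
  if (diff(range(x)) == 0) abort("degenerate (constant) sample")
  sub <- FALSE
  if (n0 > max_n) {
    x <- withr::with_seed(seed, sample(x, max_n))
    sub <- TRUE
  }
  sw <- stats::shapiro.test(x)
  out <- new_disttest("shapiro-wilk", unname(sw$statistic), NA_real_,
                      sw$p.value, length(x))
  out$subsampled <- sub
  out
}

#' Moment skewness and kurtosis
#'
#' Plain moment estimators: skewness `m3 / m2^1.5` and kurtosis
#' `m4 / m2^2` (non-excess: a Gaussian has kurtosis 3, values below 3 are
#' platykurtic/"flattened").
#'
#' @param x Numeric sample.
#' @return A single numeric value.
#' @export
moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' @rdname moment_skewness
#' @export
moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

#' Chi-squared uniformity test for azimuthal angles
#'
#' Bins angles into equal-width sectors over [0, 360) and tests the counts
#' against equal expectation. Degrees of freedom are `bins - 1` (the
#' standard convention for a fully specified uniform null).
#'
#' @param angles Angles in degrees, all in `[0, 360)`.
#' @param bins Number of sectors (>= 2; default 36, i.e. 10-degree bins).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_uniformity <- function(angles, bins = 36) {
  counts <- rose_bins(angles, bins)$count
  n <- sum(counts)
  if (n / bins < 1) {
    abort("expected count below 1 per sector; use fewer bins")
  }
  ct <- suppressWarnings(stats::chisq.test(counts))
  new_disttest("chi-squared uniformity", unname(ct$statistic),
               unname(ct$parameter), ct$p.value, n)
}

#' Rose-diagram sector counts
#'
#' Counts angles in `bins` equal half-open sectors `[lo, hi)` over
#' [0, 360). The counts sum to the number of angles; plotting (see
#' [plot_rose()]) is a thin layer over these counts.
#'
#' @param angles Angles in degrees, all in `[0, 360)`. `NA` values are
#'   dropped.
#' @param bins Number of sectors (>= 2).
#' @return A tibble with `sector`, `start_deg`, `end_deg`, `count`.
#' @export
rose_bins <- function(angles, bins = 36) {
  if (bins < 2) abort("`bins` must be >= 2")
  angles <- angles[!is.na(angles)]
  if (length(angles) && (min(angles) < 0 || max(angles) >= 360)) {
    abort("angles must lie in [0, 360)")
  }
  w <- 360 / bins
  idx <- floor(angles / w) + 1L
  count <- tabulate(idx, nbins = bins)
  tibble(
    sector = seq_len(bins),
    start_deg = (seq_len(bins) - 1) * w,
    end_deg = seq_len(bins) * w,
    count = count
  )
}
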