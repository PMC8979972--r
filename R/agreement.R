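## Method-comparison statistics: Bland-Altman limits of agreement,
## two-way mixed intraclass correlation, coefficient of variation.

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b` per pair; bias is their mean, SD uses the n-1
#' denominator, and the 95% limits of agreement are `bias +/- 1.96 SD`.
#'
#' @param a,b paired measurements in the same units.
#' @param ids optional subject identifiers.
#' @return An object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, and the per-pair table.
#' @export
bland_altman <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop("insufficient pairs: unequal lengths")
  if (length(a) < 2) stop("insufficient pairs: need n >= 2")
  if (anyNA(a) || anyNA(b)) stop("insufficient pairs: missing values")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(a),
                 pairs = data.frame(id = if (is.null(ids)) seq_along(a) else ids,
                                    a = a, b = b, mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3g +/- %.3g (SD)\n",
              x$n, x$bias, x$sd))
  cat(sprintf("  95%% limits of agreement: [%.3g, %.3g]\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$diff,
                 xlab = "mean of methods", ylab = "difference (A - B)", ...)
  graphics::abline(h = x$bias, lty = 3)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Two-way mixed, single-measure intraclass correlation
#'
#' Computed from the two-way ANOVA mean squares of a complete subjects x
#' conditions matrix. `definition = "consistency"` gives ICC(3,1) =
#' `(MSR - MSE) / (MSR + (k-1) MSE)`; `"absolute"` (default, the variant
#' usually reported as "two-way mixed, absolute agreement, single
#' measures") adds the condition variance term,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`. 95% confidence
#' intervals follow the F-distribution method (Satterthwaite degrees of
#' freedom for the absolute variant).
#'
#' @param ratings numeric matrix, subjects in rows, conditions in columns
#'   (>= 2 x 2, complete).
#' @param definition `"absolute"` or `"consistency"`.
#' @param conf confidence level (default 0.95).
#' @return An object of class `icc`: `icc`, `ci_low`, `ci_high`,
#'   `definition`, mean squares.
#' @export
icc_two_way_mixed <- function(ratings, definition = c("absolute", "consistency"),
                              conf = 0.95) {
  definition <- match.arg(definition)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least a 2 x 2 ratings matrix")
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  gm <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  sst <- sum((ratings - gm)^2)
  if (sst <= .Machine$double.eps * max(1, gm^2) * n * k)
    stop("degenerate ratings: zero total variance")
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (definition == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse == 0 && msc == 0) {
      ci <- c(1, 1)
    } else {
      r <- icc
      a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
      if (!is.finite(a) || !is.finite(b)) {
        ci <- c(1, 1)
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        f1 <- stats::qf(1 - alpha / 2, n - 1, v)
        f2 <- stats::qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - f1 * mse) /
          (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (f2 * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * f2 * msr)
        ci <- c(lo, hi)
      }
    }
  }
  ## perfect reproduction: both mean squares vanish
  if (mse == 0 && (definition == "consistency" || msc == 0)) {
    icc <- 1; ci <- c(1, 1)
  }
  structure(list(icc = icc, ci_low = min(ci), ci_high = max(ci),
                 definition = definition, conf = conf,
                 n = n, k = k, msr = msr, msc = msc, mse = mse),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC (two-way mixed, single measures, %s): %.3f\n",
              x$definition, x$icc))
  cat(sprintf("  %d%% CI [%.3f, %.3f]  (n = %d subjects, k = %d conditions)\n",
              round(100 * x$conf), x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Coefficient of variation for paired measurements
#'
#' Default is the within-subject SD method:
#' `CoV% = (SD(a - b) / sqrt(2)) / grand mean x 100`. The simple
#' alternative `SD(a - b) / grand mean x 100` is exposed by `method`.
#'
#' @param a,b paired measurements.
#' @param method `"within-subject"` (default) or `"simple"`.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(a, b,
                                     method = c("within-subject", "simple")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 2)
    stop("insufficient pairs: need n >= 2 equal-length vectors")
  gm <- mean(c(a, b))
  if (gm <= 0) stop("invalid scale: grand mean must be > 0")
  s <- stats::sd(a - b)
  if (method == "within-subject") s <- s / sqrt(2)
  100 * s / gm
}
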