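# Agreement statistics comparing MTV (the segmented metabolic tumor
# volume) to the reference GTV (gross tumor volume): per-case ratio,
# Spearman rank correlation, intra-class correlation ICC(A,1) with its
# F-based 95% CI, and Bland-Altman bias / limits of agreement.

#' MTV/GTV ratio summary
#'
#' Per-case ratio `r_j = mtv_j / gtv_j`, summarized as mean and sample SD
#' (n - 1 denominator). A ratio of 1 means the segmentation reproduces the
#' reference volume.
#'
#' @param mtv,gtv Paired volumes in cm^3, equal length >= 2; `gtv` must be
#'   strictly positive.
#' @return List: `ratio_mean`, `ratio_sd`, `n`.
#' @export
ratio_stats <- function(mtv, gtv) {
  if (length(mtv) != length(gtv)) stop("mtv and gtv lengths differ")
  if (length(mtv) < 2) stop("need at least 2 pairs")
  if (any(gtv <= 0)) stop("zero or negative GTV: ratio undefined")
  r <- mtv / gtv
  list(ratio_mean = mean(r), ratio_sd = stats::sd(r), n = length(r))
}

#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for n >= 10 and the exact permutation
#' distribution of rho for n < 10 (all n! permutations enumerated).
#'
#' @param x,y Numeric vectors, equal length >= 3, neither constant.
#' @return List: `rho`, `p_value`, `n`, `method` (`"t-approx"` or
#'   `"exact-permutation"`).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3) stop("need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approx"
  } else {
    perms <- .permutations(n)
    # Pearson-on-ranks rho for every permutation of y: only the cross
    # term varies, so vectorize over the n! column matrix
    ry_perm <- matrix(ry[t(perms)], nrow = n)
    cross <- drop(crossprod(rx, ry_perm))
    rhos <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Intra-class correlation ICC(A,1)
#'
#' Two-way random effects, absolute agreement, single measures: the ICC
#' variant whose null of interest is "the two measurements agree in value",
#' not merely "they co-vary". Computed from the two-way ANOVA mean squares
#' (rows = cases, columns = the two methods):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2.
#' The 95% CI follows the McGraw & Wong F-distribution method with
#' Satterthwaite degrees of freedom.
#'
#' @param x,y Paired measurements, equal length n >= 4.
#' @param conf Confidence level (default 0.95).
#' @return List: `icc`, `ci95` (length-2), `variant = "ICC(A,1)"`, `n`,
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4) stop("need at least 4 pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  if (sum((dat - grand)^2) <= 0)
    stop("zero total variance: ICC undefined")
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # between cases
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # between methods
  sse <- sum((sweep(sweep(dat, 1, row_m), 2, col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  list(icc = icc, ci95 = c(lower, upper), variant = "ICC(A,1)", n = n,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman analysis
#'
#' Differences `d_j = mtv_j - gtv_j`; bias = mean(d), sd = sample SD(d),
#' 95% limits of agreement = bias +/- 1.96 sd. Reported inline as
#' "bias +/- SD" (the SD of the differences, not the limits themselves).
#'
#' @param mtv,gtv Paired volumes (cm^3), equal length >= 2.
#' @return List: `bias`, `sd`, `loa95` (length-2 lower/upper), `n`.
#' @export
bland_altman <- function(mtv, gtv) {
  if (length(mtv) != length(gtv)) stop("mtv and gtv lengths differ")
  if (length(mtv) < 2) stop("need at least 2 pairs")
  d <- mtv - gtv
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s, loa95 = c(bias - 1.96 * s, bias + 1.96 * s),
       n = length(d))
}

#' Per-method agreement report against a reference volume
#'
#' One row per segmentation method with the full agreement panel: MTV/GTV
#' ratio mean and SD, Spearman rho and p, ICC(A,1) with 95% CI, and
#' Bland-Altman bias, SD and limits of agreement (cm^3).
#'
#' @param mtv Named list (or data.frame) of per-case MTV vectors, one
#'   entry per method.
#' @param gtv Reference GTV vector (cm^3), matching each MTV in length.
#' @return `data.frame` of class `agreement_report`.
#' @examples
#' gtv <- c(100, 250, 80, 500, 120, 60, 300, 90)
#' mtv <- list("mo-pet" = gtv * 1.1, "suv-2.0" = gtv * 0.9 + 30)
#' agreement_report(mtv, gtv)
#' @export
agreement_report <- function(mtv, gtv) {
  mtv <- as.list(mtv)
  if (is.null(names(mtv)) || any(names(mtv) == ""))
    stop("each MTV entry must be named with its method label")
  rows <- lapply(names(mtv), function(meth) {
    m <- mtv[[meth]]
    rs <- ratio_stats(m, gtv)
    sc <- spearman_cor(m, gtv)
    ic <- icc_agreement(m, gtv)
    ba <- bland_altman(m, gtv)
    data.frame(method = meth, n = rs$n,
               ratio_mean = rs$ratio_mean, ratio_sd = rs$ratio_sd,
               spearman_rho = sc$rho, spearman_p = sc$p_value,
               icc = ic$icc, icc_lo = ic$ci95[1], icc_hi = ic$ci95[2],
               ba_bias = ba$bias, ba_sd = ba$sd,
               ba_loa_lo = ba$loa95[1], ba_loa_hi = ba$loa95[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", class(out))
  out
}

#' Write an agreement report
#'
#' @param report An [agreement_report()] table.
#' @param path Output path; format from the extension (`.csv` or `.json`).
#' @export
write_agreement <- function(report, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA)
  else
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
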