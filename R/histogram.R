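#' Build an SUV intensity histogram
#'
#' Discretizes a set of SUV values into `n_bins` equal-width bins spanning
#' `[min(values), max(values)]`. Bins are left-closed, right-open, except
#' the last bin whose right edge is inclusive so the maximum value is
#' counted. The normalized bin occupancies `P_i` are the probability of
#' occurrence of each SUV level and feed the Otsu objective.
#'
#' @param values Numeric vector of SUV values; finite, >= 0, non-empty.
#' @param n_bins Number of bins, >= 2. 128 is the package default used by
#'   [segment_mo_pet()]; it balances intensity resolution against the cost
#'   of the threshold search.
#' @return Object of class `suv_histogram` with fields `bin_edges`
#'   (length `n_bins + 1`), `p` (probabilities, sum 1), `counts`,
#'   `n_samples`, `value_min`, `value_max` and `mids` (bin centers, the
#'   representative SUV level of each bin).
#' @examples
#' h <- build_histogram(c(0, 1, 2, 3), n_bins = 4)
#' h$p  # 0.25 each
#' @export
build_histogram <- function(values, n_bins) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input: no SUV values to histogram")
  if (any(!is.finite(values)) || any(values < 0))
    stop("SUV values must be finite and >= 0")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2) stop("`n_bins` must be >= 2")
  lo <- min(values); hi <- max(values)
  if (hi <= lo)
    stop("degenerate (constant) distribution: all values equal ",
         format(lo), "; no threshold exists")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  # left-closed bins; clamp the maximum into the last bin
  bin <- pmin(findInterval(values, edges, left.open = FALSE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, p = counts / length(values),
                 counts = counts, n_samples = length(values),
                 value_min = lo, value_max = hi,
                 mids = (edges[-1] + edges[-(n_bins + 1)]) / 2),
            class = "suv_histogram")
}

#' @export
print.suv_histogram <- function(x, ...) {
  cat(sprintf("<suv_histogram> %d bins over SUV [%.4g, %.4g], n = %d\n",
              length(x$p), x$value_min, x$value_max, x$n_samples))
  invisible(x)
}

# map SUV-valued thresholds to the last bin index of the lower class:
# a threshold strictly inside bin j assigns bin j to the lower class;
# a threshold at a bin edge leaves that edge's upper bin in the upper class.
threshold_to_cut <- function(hist, thresholds) {
  left <- hist$bin_edges[-length(hist$bin_edges)]
  vapply(thresholds, function(t) sum(left < t), integer(1))
}

#' Per-class statistics of a thresholded histogram
#'
#' Partitions the histogram bins at the given SUV thresholds into
#' `K = length(thresholds) + 1` classes and returns, per class, the
#' probability mass `P_k = sum(P_i)`, the mean SUV level
#' `mu_k = sum(i * P_i) / P_k` and the variance
#' `var_k = sum((i - mu_k)^2 * P_i) / P_k`, with the bin center as the
#' representative level `i` of each bin. A threshold falling strictly
#' inside a bin assigns that whole bin to the lower class. Empty classes
#' report mass, mean and variance 0 and are flagged.
#'
#' @param hist A `suv_histogram`.
#' @param thresholds Strictly increasing SUV thresholds inside
#'   `(value_min, value_max)`; may be empty (one class = whole histogram).
#' @return `data.frame` with columns `class`, `p`, `mu`, `var`, `empty`.
#' @export
class_statistics <- function(hist, thresholds = numeric(0)) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  if (length(thresholds) &&
      (min(thresholds) <= hist$value_min || max(thresholds) >= hist$value_max))
    stop("threshold outside histogram range (",
         format(hist$value_min), ", ", format(hist$value_max), ")")
  cuts <- threshold_to_cut(hist, thresholds)
  if (length(cuts) > 1 && any(diff(cuts) == 0))
    warning("two thresholds fall in the same bin; a class is empty")
  bounds <- c(0L, cuts, length(hist$p))
  out <- lapply(seq_len(length(bounds) - 1), function(k) {
    sel <- seq.int(bounds[k] + 1L, length.out = bounds[k + 1L] - bounds[k])
    pk <- sum(hist$p[sel])
    if (pk <= 0)
      return(data.frame(class = k, p = 0, mu = 0, var = 0, empty = TRUE))
    mu <- sum(hist$mids[sel] * hist$p[sel]) / pk
    # a class whose mass sits in a single bin is a point mass: variance 0
    v <- if (sum(hist$p[sel] > 0) <= 1) 0 else
      sum((hist$mids[sel] - mu)^2 * hist$p[sel]) / pk
    data.frame(class = k, p = pk, mu = mu, var = v, empty = FALSE)
  })
  do.call(rbind, out)
}

# Cumulative moments for the Otsu search. Segment cost of bins a..b
# (1-based, a <= b) is P * var of that slice; costs for all segments are
# derived from prefix sums of p, p*x and p*x^2.
.otsu_prefix <- function(hist) {
  x <- hist$mids; p <- hist$p
  list(P = c(0, cumsum(p)), S = c(0, cumsum(p * x)),
       Q = c(0, cumsum(p * x * x)), NZ = c(0, cumsum(p > 0)))
}

# cost (P_k * sigma_k^2) of segments; a, b vectors of equal length.
# Segments holding mass in at most one bin are point masses: cost exactly 0
# (also guards the prefix-sum cancellation noise there).
.segment_cost <- function(pre, a, b) {
  P <- pre$P[b + 1] - pre$P[a]
  S <- pre$S[b + 1] - pre$S[a]
  Q <- pre$Q[b + 1] - pre$Q[a]
  cost <- ifelse(P > 0, Q - S * S / P, 0)
  cost[pre$NZ[b + 1] - pre$NZ[a] <= 1] <- 0
  pmax(cost, 0)  # guard tiny negative rounding
}

#' Multi-level Otsu thresholds
#'
#' Chooses the `K - 1` strictly increasing thresholds (at histogram bin
#' edges) that minimize the probability-weighted within-class variance
#' `sum_k P_k * var_k` — equivalently maximize the between-class variance —
#' over all ordered cut combinations. With `solver = "dp"` (default) an
#' exact dynamic program over prefix sums finds the same global minimizer
#' as full enumeration in `O(K * B^2)`; `solver = "exhaustive"` enumerates
#' every cut combination and is provided for verification. Ties on the
#' objective are broken toward the lexicographically smallest threshold
#' vector, so the result is deterministic.
#'
#' @param hist A `suv_histogram`.
#' @param K Number of classes, >= 2 (so `K - 1` thresholds). The histogram
#'   must contain at least `K` non-empty bins.
#' @param solver `"dp"` or `"exhaustive"`.
#' @return Object of class `threshold_set`: `K`, `thresholds` (SUV values
#'   at bin edges), `cut_bins` (index of the last bin of each lower class),
#'   `objective` (the minimized within-class variance, SUV^2), and
#'   `per_class` (the [class_statistics()] table at the optimum).
#' @examples
#' set.seed(1)
#' h <- build_histogram(c(rnorm(200, 1, 0.1), rnorm(200, 5, 0.2)), 64)
#' multilevel_otsu(h, K = 2)
#' @export
multilevel_otsu <- function(hist, K = 3, solver = c("dp", "exhaustive")) {
  solver <- match.arg(solver)
  K <- as.integer(K)
  if (is.na(K) || K < 2) stop("`K` must be >= 2")
  B <- length(hist$p)
  if (sum(hist$p > 0) < K)
    stop("insufficient distinct levels: ", sum(hist$p > 0),
         " non-empty bins for K = ", K)
  pre <- .otsu_prefix(hist)
  cuts <- if (solver == "dp") .otsu_dp(pre, B, K) else .otsu_exhaustive(pre, B, K)
  thresholds <- hist$bin_edges[cuts + 1L]
  per_class <- class_statistics(hist, thresholds)
  structure(list(K = K, thresholds = thresholds, cut_bins = cuts,
                 objective = sum(per_class$p * per_class$var),
                 per_class = per_class,
                 bin_edges = hist$bin_edges),
            class = "threshold_set")
}

# exact DP. suffix[k, i] = min cost of splitting bins i..B into k classes.
# Reconstruction walks forward taking the smallest cut achieving the
# optimum at each step => lexicographically smallest threshold vector.
.otsu_dp <- function(pre, B, K) {
  suffix <- matrix(Inf, K, B + 1)         # [classes remaining, start bin]
  suffix[1, 1:B] <- .segment_cost(pre, 1:B, rep(B, B))
  for (k in 2:K) {
    # suffix[k, i] = min over c in i..B-k+1 of cost(i..c) + suffix[k-1, c+1]
    for (i in 1:(B - k + 1)) {
      cc <- i:(B - k + 1)
      tot <- .segment_cost(pre, rep(i, length(cc)), cc) + suffix[k - 1, cc + 1]
      suffix[k, i] <- min(tot)
    }
  }
  cuts <- integer(K - 1)
  start <- 1L
  target <- suffix[K, 1]
  for (j in seq_len(K - 1)) {
    k_rem <- K - j
    cc <- start:(B - k_rem)
    tot <- .segment_cost(pre, rep(start, length(cc)), cc) +
           suffix[k_rem, cc + 1]
    # smallest cut attaining the optimum (tolerate float noise at 0 scale)
    best <- min(tot)
    pick <- cc[which(tot <= best + 1e-12 * max(1, abs(best)))[1]]
    cuts[j] <- pick
    target <- target - .segment_cost(pre, start, pick)
    start <- pick + 1L
  }
  cuts
}

# full enumeration of all strictly increasing cut vectors; vectorized over
# combinations via the segment-cost prefix sums. Lexicographically smallest
# argmin (combn emits combinations in lexicographic order).
.otsu_exhaustive <- function(pre, B, K) {
  combs <- utils::combn(B - 1L, K - 1L)   # cut bins in 1..B-1
  n <- ncol(combs)
  total <- numeric(n)
  a <- rep(1L, n)
  for (j in seq_len(K - 1)) {
    b <- combs[j, ]
    total <- total + .segment_cost(pre, a, b)
    a <- b + 1L
  }
  total <- total + .segment_cost(pre, a, rep(B, n))
  combs[, which.min(total)]
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> K = %d, thresholds (SUV): %s\n", x$K,
              paste(signif(x$thresholds, 5), collapse = ", ")))
  cat(sprintf("  within-class objective: %.6g SUV^2\n", x$objective))
  invisible(x)
}

#' Serialize a threshold set to JSON
#'
#' Keys: `K`, `thresholds`, `objective`, `per_class`.
#'
#' @param x A `threshold_set`.
#' @param path Output path.
#' @export
write_threshold_json <- function(x, path) {
  jsonlite::write_json(list(K = x$K, thresholds = x$thresholds,
                            objective = x$objective,
                            per_class = x$per_class),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
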