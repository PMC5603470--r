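# Independent oracles used across the suite. These deliberately avoid the
# package's own prefix-sum machinery: per-bin loops, naive scans, direct
# enumeration.

# brute-force per-bin counting (left-closed bins, last bin right-inclusive)
oracle_hist_counts <- function(values, edges) {
  B <- length(edges) - 1
  counts <- integer(B)
  for (v in values) {
    b <- B
    for (i in seq_len(B - 1)) if (v >= edges[i] && v < edges[i + 1]) {
      b <- i
      break
    }
    counts[b] <- counts[b] + 1L
  }
  counts
}

# naive weighted moments of bins a..b of a histogram
oracle_class_moments <- function(mids, p, a, b) {
  sel <- a:b
  pk <- sum(p[sel])
  if (pk <= 0) return(c(p = 0, mu = 0, var = 0))
  mu <- 0
  for (i in sel) mu <- mu + mids[i] * p[i]
  mu <- mu / pk
  v <- 0
  for (i in sel) v <- v + (mids[i] - mu)^2 * p[i]
  c(p = pk, mu = mu, var = v / pk)
}

# P_k * var_k cost of bins a..b, by the naive loop
oracle_segment_cost <- function(mids, p, a, b) {
  m <- oracle_class_moments(mids, p, a, b)
  unname(m["p"] * m["var"])
}

# classical two-class Otsu: scan every single cut position
oracle_otsu2 <- function(hist) {
  B <- length(hist$p)
  best <- Inf
  best_c <- NA_integer_
  for (cc in 1:(B - 1)) {
    tot <- oracle_segment_cost(hist$mids, hist$p, 1, cc) +
      oracle_segment_cost(hist$mids, hist$p, cc + 1, B)
    if (tot < best) {
      best <- tot
      best_c <- cc
    }
  }
  best_c
}

# exhaustive enumeration of all ordered cut vectors for K classes
oracle_otsu_k <- function(hist, K) {
  B <- length(hist$p)
  combs <- utils::combn(B - 1, K - 1)
  # precompute naive cost of every segment once (still package-independent)
  cost <- matrix(NA_real_, B, B)
  for (a in 1:B) for (b in a:B)
    cost[a, b] <- oracle_segment_cost(hist$mids, hist$p, a, b)
  best <- Inf
  best_cuts <- NULL
  for (q in seq_len(ncol(combs))) {
    cuts <- combs[, q]
    bounds <- c(0, cuts, B)
    tot <- 0
    for (k in seq_len(K)) tot <- tot + cost[bounds[k] + 1, bounds[k + 1]]
    if (tot < best - 1e-15) {
      best <- tot
      best_cuts <- cuts
    }
  }
  best_cuts
}

random_histogram <- function(n_bins = 64, n = 2000) {
  # mixture of 2-4 lognormal-ish clusters, occasionally with empty bins
  kcl <- sample(2:4, 1)
  v <- unlist(lapply(seq_len(kcl), function(i)
    pmax(rnorm(ceiling(n / kcl), mean = runif(1, 1, 12),
               sd = runif(1, 0.2, 1.5)), 0)))
  build_histogram(v, n_bins)
}

# single-sphere phantom helper
sphere_phantom <- function(diameter = 22, lbr = 8, psf_fwhm = 0,
                           noise_coef = 0, seed = 1, shape = c(40, 40, 40),
                           spacing = c(2, 2, 2)) {
  center <- spacing * (shape - 1) / 2
  generate_phantom(phantom_spec(
    shape = shape, spacing = spacing, background_suv = 1,
    spheres = data.frame(x = center[1], y = center[2], z = center[3],
                         diameter = diameter, lbr = lbr),
    psf_fwhm = psf_fwhm, noise_coef = noise_coef, seed = seed))
}

phantom_center <- function(ph) {
  ph$spec$spacing * (ph$spec$shape - 1) / 2
}

# run a Python oracle script, returning its JSON output (Python and its
# scientific stack are part of the pinned environment)
run_python_oracle <- function(code, input) {
  td <- tempfile("pyoracle")
  dir.create(td)
  in_json <- file.path(td, "in.json")
  out_json <- file.path(td, "out.json")
  jsonlite::write_json(input, in_json, digits = NA, auto_unbox = TRUE)
  script <- file.path(td, "oracle.py")
  writeLines(sprintf(code, in_json, out_json), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_json))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(out_json, simplifyVector = TRUE)
}
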