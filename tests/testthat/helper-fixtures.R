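# shared fixture builders; everything is generated in code at test time

toy_axis <- function(n = 5L, from = 1000, by = 10) {
  seq(from, by = by, length.out = n)
}

# small dataset with deterministic pseudo-random rows
toy_dataset <- function(n_spectra = 3L, axis = toy_axis(), seed = 11L) {
  set.seed(seed)
  m <- matrix(round(stats::runif(n_spectra * length(axis)), 6),
              nrow = n_spectra)
  ir_dataset(axis, m, ids = sprintf("s%d", seq_len(n_spectra)))
}

# independent 2x2 normal-equations solve for z = a + b*r, written as the
# explicit closed form of the normal equations (no shared code path)
oracle_msc <- function(z, r) {
  n <- length(z)
  sx <- sum(r); sy <- sum(z); sxx <- sum(r * r); sxy <- sum(r * z)
  det <- n * sxx - sx * sx
  b <- (n * sxy - sx * sy) / det
  a <- (sy * sxx - sx * sxy) / det
  res <- z - a - b * r
  list(a = a, b = b, rmse = sqrt(sum(res^2) / n))
}

# fixed broadband axis used by the synthetic checks
fp_axis <- function() default_axis()
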