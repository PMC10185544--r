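#' Derive a per-unit random seed from a master seed
#'
#' Each virtual patient (and each side within a patient) gets its own RNG
#' stream keyed on the master seed and a unit index, so adding patients to a
#' cohort does not perturb the draws of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer unit index (patient number, side, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus of the Lehmer generator
  s <- (abs(as.numeric(master_seed)) %% m)
  # two multiplicative mixing rounds keep nearby (seed, index) pairs apart
  s <- (s * 48271 + as.numeric(index) + 1) %% m
  s <- (s * 69621 + 11) %% m
  as.integer(if (s == 0) 1 else s)
}

#' FNV-1a hash of an R object (hex string)
#'
#' Stable content hash used to stamp pipeline artifacts with their
#' configuration, so a report is traceable to the exact settings that
#' produced it.
#'
#' @param x Any serialisable R object.
#' @return A character scalar, 8 hex digits.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  # drop the serialization header (R version stamp) so the hash depends on
  # content only
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# quantile convention used for all reported medians/quartiles: linear
# interpolation (type 7), recorded in output metadata
quartiles <- function(x) {
  qs <- quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = qs[1], median = qs[2], q3 = qs[3])
}

# draw from a log-normal with a given *median* (not mean), truncated to
# (lower, upper) on the natural scale; exact inverse-CDF truncation
rlnorm_med <- function(n, median, log_sd, lower = 0, upper = Inf) {
  mu <- log(median)
  if (log_sd == 0) {
    return(rep(pmin(pmax(median, lower), upper), n))
  }
  plo <- plnorm(lower, mu, log_sd)
  phi <- plnorm(upper, mu, log_sd)
  if (phi <= plo) {
    abort("truncation interval has zero probability mass")
  }
  qlnorm(plo + runif(n) * (phi - plo), mu, log_sd)
}

# normal draw truncated to [lower, upper]
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
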