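# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and dhyper), relying on factorial identities,
# explicit pair loops and full enumeration.

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, probabilities via products of binomial coefficients
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(1)
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  probs <- exp(vapply(support, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) all-pairs Kendall tau-b
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tie_x <- 0; tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[j] - x[i]; sy <- y[j] - y[i]
      if (sx == 0 && sy == 0) {
        # tied in both: counts in neither correction term's pair total
      } else if (sx == 0) {
        tie_x <- tie_x + 1
      } else if (sy == 0) {
        tie_y <- tie_y + 1
      } else if (sign(sx) == sign(sy)) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  # pairs tied in both x and y reduce both denominators
  both <- n0 - conc - disc - tie_x - tie_y
  (conc - disc) / sqrt((n0 - tie_x - both) * (n0 - tie_y - both))
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# random 2x2 table with total n
random_table <- function(total) {
  cuts <- sort(sample(0:total, 3, replace = TRUE))
  matrix(c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], total - cuts[3]),
         nrow = 2, byrow = TRUE)
}

# small acquisition protocol used when epoch content, not scale, is under test
tiny_protocol <- function(n_trials = 8) {
  stimulation_protocol(n_trials = n_trials)
}

# one-row truth for hand-built patients
truth_row <- function(amplitude = 2, latency = 40, power = 8, id = "P001") {
  tibble::tibble(
    patient_id = id,
    amplitude_right = amplitude, amplitude_left = amplitude,
    latency_right = latency, latency_left = latency,
    tfa_power_right = power, tfa_power_left = power
  )
}

# abnormality calls with specified category counts for one grade
engineered_calls <- function(grade, n_a, n_b, n_c, n_d, id_offset = 0) {
  cats <- rep(c("A", "B", "C", "D"), times = c(n_a, n_b, n_c, n_d))
  tibble::tibble(
    patient_id = sprintf("G%dP%03d", grade, id_offset + seq_along(cats)),
    side = "right",
    amplitude_abnormal = cats %in% c("B", "C"),
    power_abnormal = cats %in% c("C", "D"),
    category = cats,
    grade = grade
  )
}
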