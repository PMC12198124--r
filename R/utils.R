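# internal helpers shared across modules

# per-stage RNG streams derived from one root seed; kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

check_prob <- function(x, name, allow_one = TRUE) {
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > hi) {
    stop(name, " must be a probability in [0, ", if (allow_one) "1]" else "1)", call. = FALSE)
  }
  invisible(x)
}

# Hardy-Weinberg genotype probabilities for alt-allele dosage 0/1/2,
# given alt allele frequency p. Vectorised over p -> length(p) x 3 matrix.
hwe_probs <- function(p) {
  q <- 1 - p
  cbind(q * q, 2 * p * q, p * p, deparse.level = 0)
}

# Mendelian transmission with one known parent (dosage tc) and the other
# parent drawn from the population (alt frequency p): 3x3 matrix
# T[to + 1, tc + 1] = P(offspring dosage to | parent dosage tc).
trans_single <- function(p) {
  out <- matrix(0, 3, 3)
  for (tc in 0:2) {
    a <- tc / 2 # P(parent transmits alt)
    out[, tc + 1] <- c((1 - a) * (1 - p), a * (1 - p) + (1 - a) * p, a * p)
  }
  out
}

# Mendelian transmission from a known parent pair: 3x3x3 array
# T[to + 1, tm + 1, tf + 1]; no dependence on allele frequency.
trans_pair_array <- function() {
  out <- array(0, c(3, 3, 3))
  for (tm in 0:2) {
    for (tf in 0:2) {
      a <- tm / 2
      b <- tf / 2
      out[, tm + 1, tf + 1] <- c(
        (1 - a) * (1 - b),
        a * (1 - b) + (1 - a) * b,
        a * b
      )
    }
  }
  out
}

TRANS_PAIR <- trans_pair_array()
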