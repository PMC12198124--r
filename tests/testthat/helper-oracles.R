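# Independent brute-force oracles, written from first principles (scalar
# probability functions and explicit loops) so they share no code path with
# the package implementations they check.

hw_prob <- function(g, p) stats::dbinom(g, 2, p)

# P(child dosage | parent dosages), from the two transmitted alleles
mendel_prob <- function(to, tm, tf) {
  pa <- tm / 2
  pb <- tf / 2
  c((1 - pa) * (1 - pb), pa * (1 - pb) + (1 - pa) * pb, pa * pb)[to + 1]
}

# P(child dosage | one parent dosage, other parent from the population)
mendel_prob_single <- function(to, tc, p) {
  sum(vapply(0:2, function(tp) hw_prob(tp, p) * mendel_prob(to, tc, tp), numeric(1)))
}

# observation probability under the mistyping model
emit_prob <- function(obs, tru, p, e) {
  (obs == tru) * (1 - e) + e * hw_prob(obs, p)
}

oracle_lod_single <- function(go, gc, p, e) {
  num <- 0
  den_c <- 0
  den_o <- 0
  for (tc in 0:2) {
    wc <- hw_prob(tc, p) * emit_prob(gc, tc, p, e)
    den_c <- den_c + wc
    for (to in 0:2) {
      num <- num + wc * mendel_prob_single(to, tc, p) * emit_prob(go, to, p, e)
    }
  }
  for (to in 0:2) den_o <- den_o + hw_prob(to, p) * emit_prob(go, to, p, e)
  log(num) - log(den_c * den_o)
}

oracle_lod_pair <- function(go, gm, gf, p, e) {
  num <- 0
  den_m <- 0
  den_f <- 0
  den_o <- 0
  for (tm in 0:2) {
    wm <- hw_prob(tm, p) * emit_prob(gm, tm, p, e)
    den_m <- den_m + wm
    for (tf in 0:2) {
      wf <- hw_prob(tf, p) * emit_prob(gf, tf, p, e)
      for (to in 0:2) {
        num <- num + wm * wf * mendel_prob(to, tm, tf) * emit_prob(go, to, p, e)
      }
    }
  }
  for (tf in 0:2) den_f <- den_f + hw_prob(tf, p) * emit_prob(gf, tf, p, e)
  for (to in 0:2) den_o <- den_o + hw_prob(to, p) * emit_prob(go, to, p, e)
  log(num) - log(den_m * den_f * den_o)
}

# non-exclusion probabilities by exhaustive enumeration over genotype
# configurations; a candidate is excluded only by Mendelian impossibility
oracle_ne <- function(p, mode) {
  g <- 0:2
  compatible_pair <- function(o, m, f) mendel_prob(o, m, f) > 0
  if (mode == "first_parent") {
    tot <- 0
    for (o in g) {
      for (cand in g) {
        if (mendel_prob_single(o, cand, p) > 0) {
          tot <- tot + hw_prob(o, p) * hw_prob(cand, p)
        }
      }
    }
    return(tot)
  }
  if (mode == "second_parent") {
    tot <- 0
    for (m in g) {
      for (f in g) {
        for (o in g) {
          w <- hw_prob(m, p) * hw_prob(f, p) * mendel_prob(o, m, f)
          if (w == 0) next
          for (cand in g) {
            if (compatible_pair(o, m, cand)) tot <- tot + w * hw_prob(cand, p)
          }
        }
      }
    }
    return(tot)
  }
  tot <- 0
  for (o in g) {
    for (c1 in g) {
      for (c2 in g) {
        if (compatible_pair(o, c1, c2)) {
          tot <- tot + hw_prob(o, p) * hw_prob(c1, p) * hw_prob(c2, p)
        }
      }
    }
  }
  tot
}

# exact HWE test by full enumeration of heterozygote configurations,
# via genotype-arrangement counting with plain factorials (small n only)
oracle_hwe <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  na <- 2 * nAA + nAB
  nminor <- min(na, 2 * n - na)
  if (nminor == 0) return(1)
  hets <- seq(nminor %% 2, nminor, by = 2)
  ways <- vapply(hets, function(h) {
    choose(n, h) * choose(n - h, (nminor - h) / 2) * 2^h
  }, numeric(1))
  prob <- ways / sum(ways)
  obs <- prob[hets == nAB]
  sum(prob[prob <= obs + 1e-12])
}

# quick geno_matrix constructor for hand-built fixtures
toy_gm <- function(calls, colony = NULL, loci_extra = NULL, depth = NULL) {
  n <- nrow(calls)
  L <- ncol(calls)
  samples <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)))
  if (!is.null(colony)) samples$colony <- colony
  loci <- tibble::tibble(
    locus_id = sprintf("L%02d", seq_len(L)),
    chrom = "chr1",
    pos = seq_len(L) * 100L,
    rad_locus = sprintf("rl%02d", seq_len(L)),
    pos_in_locus = 50L,
    ref = "A", alt = "C"
  )
  if (!is.null(loci_extra)) for (nm in names(loci_extra)) loci[[nm]] <- loci_extra[[nm]]
  geno_matrix(calls, samples, loci, depth = depth)
}
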