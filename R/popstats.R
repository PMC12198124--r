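#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`; for a biallelic locus
#' with allele frequency `p` this is `1 - p^2 - q^2 - 2 p^2 q^2`.
#'
#' @param p Allele frequency (either allele; the statistic is symmetric).
#'   Vectorised.
#' @return PIC values in `[0, 0.375]` for biallelic loci.
#' @export
pic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-locus population statistics
#'
#' Expected heterozygosity under Hardy-Weinberg from sample allele
#' frequencies, observed heterozygosity, their deviation, nucleotide
#' diversity (expected heterozygosity with the small-sample correction
#' `2n/(2n - 1)` on allele count `2n`), the within-population inbreeding
#' coefficient `Fis = 1 - Ho/He` (0 by convention at monomorphic loci) and
#' PIC.
#'
#' @param gm A [geno_matrix()].
#' @param by Optional name of a column of `gm$samples` to group by
#'   (e.g. `"colony"`); statistics are then computed per group.
#' @return A tibble with one row per locus (per group when `by` is given):
#'   `locus_id`, (`group`), `n_called`, `maf`, `ho`, `he`, `delta_het`,
#'   `pi`, `fis`, `pic`.
#' @export
locus_stats <- function(gm, by = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  one <- function(g, label) {
    ms <- marker_stats(g)
    p <- ms$p_alt
    he <- 2 * p * (1 - p)
    n2 <- 2 * ms$n_called
    out <- tibble::tibble(
      locus_id = ms$locus_id,
      n_called = ms$n_called,
      maf = ms$maf,
      ho = ms$obs_het,
      he = he,
      delta_het = he - ms$obs_het,
      pi = ifelse(n2 > 1, n2 / (n2 - 1) * he, NA_real_),
      fis = ifelse(!is.na(he) & he > 0, 1 - ms$obs_het / he, 0),
      pic = pic(p)
    )
    if (!is.null(label)) out <- dplyr::mutate(out, group = label, .after = "locus_id")
    out
  }
  if (is.null(by)) {
    return(one(gm, NULL))
  }
  stopifnot(by %in% names(gm$samples))
  groups <- split(gm$samples$sample_id, gm$samples[[by]])
  dplyr::bind_rows(lapply(names(groups), function(gname) {
    one(subset_geno(gm, samples = groups[[gname]]), gname)
  }))
}

#' Per-locus non-exclusion probability
#'
#' The probability, under Hardy-Weinberg equilibrium and error-free
#' genotypes, that a random unrelated candidate (or candidate pair) is
#' genotypically compatible with a random offspring, i.e. cannot be
#' excluded as its parent. Modes: `"first_parent"` (no known co-parent),
#' `"second_parent"` (one parent known), `"parent_pair"` (both candidates
#' jointly). The default route evaluates the closed-form biallelic
#' exclusion formulas (Jamieson & Taylor); `method = "enumeration"`
#' exhaustively enumerates all genotype configurations and is kept as an
#' equivalent, independently derived route.
#'
#' @param p Allele frequency (vectorised; symmetric in `p` and `1 - p`).
#' @param mode One of `"first_parent"`, `"second_parent"`, `"parent_pair"`.
#' @param method `"closed_form"` (default) or `"enumeration"`.
#' @return Non-exclusion probabilities in (0, 1]; monomorphic loci give 1.
#' @export
nonexclusion <- function(p, mode = c("first_parent", "second_parent", "parent_pair"),
                         method = c("closed_form", "enumeration")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (method == "closed_form") {
    q <- 1 - p
    s2 <- p^2 + q^2
    s3 <- p^3 + q^3
    s4 <- p^4 + q^4
    s5 <- p^5 + q^5
    s6 <- p^6 + q^6
    excl <- switch(mode,
      first_parent = 1 - 4 * s2 + 2 * s2^2 + 4 * s3 - 3 * s4,
      second_parent = 1 - 2 * s2 + s3 + 2 * s4 - 3 * s5 - 2 * s2^2 + 3 * s2 * s3,
      parent_pair = 1 + 4 * s4 - 4 * s5 - 3 * s6 - 8 * s2^2 + 8 * s2 * s3 + 2 * s3^2
    )
    return(1 - excl)
  }
  vapply(p, ne_enumerate, numeric(1), mode = mode)
}

# exhaustive enumeration over genotype configurations (dosages 0/1/2);
# compatibility means positive Mendelian transmission probability
ne_enumerate <- function(p, mode) {
  hw <- drop(hwe_probs(p))
  t1 <- trans_single(p)
  g <- 0:2
  switch(mode,
    first_parent = {
      # offspring ~ HWE, candidate ~ HWE; compatible as a lone parent
      sum(outer(hw, hw) * (t1 > 0))
    },
    second_parent = {
      # (known parent m, offspring o) drawn as a true parent-offspring
      # pair; candidate c compatible as the co-parent of o given m
      total <- 0
      for (m in g) {
        for (o in g) {
          w <- hw[m + 1] * t1[o + 1, m + 1]
          if (w == 0) next
          compat <- vapply(g, function(cc) TRANS_PAIR[o + 1, m + 1, cc + 1] > 0, logical(1))
          total <- total + w * sum(hw[compat])
        }
      }
      total
    },
    parent_pair = {
      total <- 0
      for (o in g) {
        ok <- 0
        for (c1 in g) {
          for (c2 in g) {
            if (TRANS_PAIR[o + 1, c1 + 1, c2 + 1] > 0) {
              ok <- ok + hw[c1 + 1] * hw[c2 + 1]
            }
          }
        }
        total <- total + hw[o + 1] * ok
      }
      total
    }
  )
}

#' Panel informativeness summary
#'
#' Unweighted per-locus means of expected/observed heterozygosity and PIC,
#' plus the multilocus non-exclusion probabilities (per-locus values
#' multiplied across loci, treating loci as independent).
#'
#' @param gm Optional [geno_matrix()]; supplies observed heterozygosity,
#'   typing rate, sample count and (when `freqs` is `NULL`) allele
#'   frequencies.
#' @param freqs Optional tibble with `p_alt` per locus; defaults to
#'   frequencies estimated from `gm`.
#' @return A one-row tibble: `n_individuals`, `n_loci`, `mean_prop_typed`,
#'   `mean_he`, `mean_ho`, `mean_pic`, `ne_1p`, `ne_2p`, `ne_pp`.
#' @export
panel_summary <- function(gm = NULL, freqs = NULL) {
  if (is.null(gm) && is.null(freqs)) stop("need a genotype matrix or allele frequencies", call. = FALSE)
  if (is.null(freqs)) {
    ms <- marker_stats(gm)
    freqs <- ms[!is.na(ms$p_alt), c("locus_id", "p_alt")]
  }
  p <- freqs$p_alt
  if (!length(p)) stop("empty panel", call. = FALSE)
  mean_ho <- mean_typed <- n_ind <- NA_real_
  if (!is.null(gm)) {
    ms <- marker_stats(gm)
    mean_ho <- mean(ms$obs_het, na.rm = TRUE)
    mean_typed <- mean(ms$call_rate)
    n_ind <- nrow(gm$calls)
  }
  tibble::tibble(
    n_individuals = n_ind,
    n_loci = length(p),
    mean_prop_typed = mean_typed,
    mean_he = mean(2 * p * (1 - p)),
    mean_ho = mean_ho,
    mean_pic = mean(pic(p)),
    ne_1p = prod(nonexclusion(p, "first_parent")),
    ne_2p = prod(nonexclusion(p, "second_parent")),
    ne_pp = prod(nonexclusion(p, "parent_pair"))
  )
}

#' Weir-Cockerham F_ST between two populations
#'
#' Per-locus Weir & Cockerham (1984) theta for a pair of populations, with
#' the unweighted mean across evaluable loci. Loci monomorphic across both
#' populations, or with an undefined denominator, are skipped.
#'
#' @param gm A [geno_matrix()].
#' @param by Name of the `gm$samples` column holding the two population
#'   labels (default `"colony"`).
#' @return A list with `per_locus` (tibble `locus_id`, `a`, `b`, `c`,
#'   `fst`) and `mean_fst`.
#' @export
fst_wc <- function(gm, by = "colony") {
  stopifnot(inherits(gm, "geno_matrix"), by %in% names(gm$samples))
  labs <- gm$samples[[by]]
  pops <- sort(unique(labs))
  if (length(pops) != 2) stop("exactly two populations are required", call. = FALSE)
  stat_for <- function(pop) {
    marker_stats(subset_geno(gm, samples = gm$samples$sample_id[labs == pop]))
  }
  s1 <- stat_for(pops[1])
  s2 <- stat_for(pops[2])
  n1 <- s1$n_called
  n2 <- s2$n_called
  p1 <- s1$p_alt
  p2 <- s2$p_alt
  h1 <- s1$obs_het
  h2 <- s2$obs_het
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2v - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(is.finite(denom) & denom > 0, a / denom, NA_real_)
  fst[pbar %in% c(0, 1)] <- NA_real_ # monomorphic in both populations
  per_locus <- tibble::tibble(locus_id = s1$locus_id, a = a, b = b, c = cc, fst = fst)
  list(per_locus = per_locus, mean_fst = mean(fst, na.rm = TRUE))
}
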