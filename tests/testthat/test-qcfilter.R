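test_that("marker statistics count alleles, calls and heterozygotes", {
  gm <- toy_gm(rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, NA, 1L), c(2L, NA, NA)))
  ms <- marker_stats(gm)
  # {hom-ref, het, het, hom-alt}: MAF 0.5, obs het 0.5
  expect_equal(ms$maf[1], 0.5)
  expect_equal(ms$obs_het[1], 0.5)
  # {hom-ref, het, missing, missing}: call rate 2/4
  expect_equal(ms$call_rate[2], 0.5)
  # {hom-ref, hom-ref, het}: minor allele count 1 of 6
  expect_equal(ms$maf[3], 1 / 6)
  expect_equal(ms$mac[3], 1L)
})

test_that("the HWE exact test matches full enumeration for all n <= 20", {
  for (n in c(2, 5, 11, 20)) {
    for (nAA in 0:n) {
      for (nAB in 0:(n - nAA)) {
        nBB <- n - nAA - nAB
        expect_equal(
          hwe_exact_pvalue(nAA, nAB, nBB), oracle_hwe(nAA, nAB, nBB),
          tolerance = 1e-10,
          label = sprintf("hwe(%d,%d,%d)", nAA, nAB, nBB)
        )
      }
    }
  }
  # pinned examples: two-configuration case, extreme het excess, monomorphic
  expect_equal(hwe_exact_pvalue(1, 0, 1), 1 / 3)
  expect_lt(hwe_exact_pvalue(0, 50, 0), 1e-10)
  expect_equal(hwe_exact_pvalue(12, 0, 0), 1)
  expect_error(hwe_exact_pvalue(0, 0, 0), "total")
})

test_that("Mendelian error rates flag impossible trios only", {
  # samples: o1 = errored child of s1 x d1 at locus 1; o2 consistent
  calls <- rbind(
    s1 = c(0L, 1L, 0L),
    d1 = c(0L, 1L, 2L),
    o1 = c(1L, 2L, 1L),
    o2 = c(0L, 0L, NA)
  )
  gm <- toy_gm(calls)
  gm$samples$sample_id <- rownames(calls)
  rownames(gm$calls) <- rownames(calls)
  trios <- tibble::tibble(offspring = c("o1", "o2"), sire = "s1", dam = "d1")
  me <- mendel_error_rate(gm, trios)
  # locus 1: hom-ref x hom-ref -> het is an error (1 of 2 trios)
  expect_equal(me$rate[1], 0.5)
  # locus 2: het x het is consistent with anything
  expect_equal(me$rate[2], 0)
  # locus 3: only one evaluable trio (o2 missing), opposing-hom rule ok
  expect_equal(me$n_evaluable[3], 1L)
  expect_equal(me$rate[3], 0)
  # arithmetic: 1 errored trio of 25 evaluable -> 0.04
  expect_equal(1 / 25, 0.04)
})

test_that("dosage r-squared matches hand Pearson computations", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  # hand calculation: cov = 1/3, both variances 2/3 -> r = 1/2, r^2 = 1/4
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 1, 2)), 0.25)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(ld_r2(c(0, NA, 2), c(NA, 1, 2))))
})

test_that("greedy LD pruning removes the later member of correlated pairs", {
  x1 <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 2L, 1L, 0L)
  x3 <- c(2L, 0L, 1L, 0L, 1L, 2L, 2L, 0L, 1L, 1L) # near-independent of x1
  # duplicated locus: exactly one copy retained
  gm <- toy_gm(cbind(x1, x1, x3))
  expect_setequal(prune_ld(gm), c("L01", "L03"))
  # mutually independent loci: all retained
  set.seed(1)
  indep <- matrix(sample(0:2, 60, replace = TRUE), nrow = 10)
  expect_equal(length(prune_ld(toy_gm(indep))), 6)
  # 3-locus chain: r2(1,2) and r2(2,3) high, r2(1,3) low -> manual greedy
  # walk removes locus 2 (later member of the worst pair), keeps 1 and 3
  x2 <- x1
  x2[1] <- 1L # still r2(1,2) > 0.5
  gm <- toy_gm(cbind(x1, x2, x3))
  r12 <- ld_r2(x1, x2)
  r23 <- ld_r2(x2, x3)
  r13 <- ld_r2(x1, x3)
  expect_true(r12 > 0.5 && r13 < 0.5)
  kept <- prune_ld(gm)
  expect_equal(length(kept), 2)
  expect_true("L01" %in% kept)
})

make_sim <- function(n_loci = 300, seed = 11, e = 0.01, m = 0.01, depth = 20) {
  ped <- build_design(design_config(n_loci = n_loci))
  fr <- sample_founder_frequencies(n_loci, 0.05, 0.5, seed = seed)
  truth <- drop_genotypes(ped, fr, seed = seed)
  obs <- corrupt(truth, error_model(e, m, depth_mean = depth), seed = seed)
  gm <- subset_geno(obs, samples = ped$id[ped$sequenced])
  list(gm = gm, ped = ped, trios = trios_from_pedigree(ped, rownames(gm$calls)))
}

test_that("a disabled cascade passes everything through unchanged", {
  sim <- make_sim(80)
  off <- filter_config(
    sample_max_missing = NULL, sample_median_depth_range = NULL,
    sample_het_range = NULL, marker_min_maf = NULL, marker_min_mac = NULL,
    marker_mean_depth_range = NULL, marker_max_missing = NULL,
    locus_position_window = NULL, one_snp_per_locus = FALSE,
    hwe_alpha = NULL, mendel_max_rate = NULL, ld_r2_max = NULL
  )
  res <- run_cascade(sim$gm, sim$trios, off)
  expect_identical(res$matrix$calls, sim$gm$calls)
  expect_true(all(res$report$removed == 0))
})

test_that("each cascade step removes exactly its planted failure", {
  # 10 clean high-MAF loci as a base, plus one planted failure per filter
  set.seed(42)
  n <- 40
  base <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  colony <- rep(c("ES", "UL"), each = n / 2)
  mono <- rep(0L, n) # monomorphic
  unshared <- c(rbinom(n / 2, 2, 0.5), rep(NA, n / 2)) # absent from UL
  low_maf <- rbinom(n, 2, 0.02) # MAF below 0.3
  low_maf[1:2] <- 1L # but MAC of 4 so only the MAF step catches it
  gappy <- rbinom(n, 2, 0.5)
  gappy[1:4] <- NA # 10% missing
  calls <- cbind(base, mono, unshared, low_maf, gappy)
  storage.mode(calls) <- "integer"
  L <- ncol(calls)
  depth <- matrix(20, n, L)
  depth[, 5] <- 90 # marker mean depth out of range
  pos_in_locus <- rep(50L, L)
  pos_in_locus[6] <- 80L # outside the 40-70 bp window
  rad <- sprintf("rl%02d", seq_len(L))
  rad[8] <- rad[7] # two SNPs on one RAD locus -> later one dropped
  gm <- toy_gm(calls,
    colony = colony,
    loci_extra = list(pos_in_locus = pos_in_locus, rad_locus = rad),
    depth = depth
  )
  # sample failures: one sample mostly missing, one depth outlier
  gm$calls[1, ] <- NA
  gm$depth[2, ] <- 60
  cfg <- filter_config(sample_het_range = NULL, hwe_alpha = NULL, ld_r2_max = NULL)
  res <- run_cascade(gm, NULL, cfg)
  rep <- res$report
  got <- stats::setNames(rep$removed, rep$step)
  expect_equal(got[["monomorphic"]], 1L)
  expect_equal(got[["shared_across_colonies"]], 1L)
  expect_equal(got[["sample_missingness"]], 1L)
  expect_equal(got[["sample_median_depth"]], 1L)
  expect_equal(got[["marker_maf"]], 1L)
  expect_equal(got[["marker_mean_depth"]], 1L)
  expect_equal(got[["marker_missingness"]], 1L)
  expect_equal(got[["locus_position"]], 1L)
  expect_equal(got[["one_snp_per_locus"]], 1L)
  # conservation: the report telescopes to the final dimensions
  expect_equal(
    rep$markers_remaining[nrow(rep)], ncol(res$matrix$calls)
  )
  expect_equal(
    rep$samples_remaining[nrow(rep)], nrow(res$matrix$calls)
  )
  n_mark_removed <- sum(rep$removed[rep$scope == "marker"])
  expect_equal(ncol(gm$calls) - n_mark_removed, ncol(res$matrix$calls))
})

test_that("the cascade is idempotent on its own output", {
  # enough input markers that the surviving panel keeps per-sample
  # statistics stable, as in the study's ~500-marker final panel
  sim <- make_sim(8000)
  cfg <- filter_config()
  first <- run_cascade(sim$gm, sim$trios, cfg)
  expect_gt(ncol(first$matrix$calls), 200)
  again <- run_cascade(first$matrix, sim$trios, cfg)
  expect_true(all(again$report$removed == 0))
  expect_identical(again$matrix$calls, first$matrix$calls)
})

test_that("tightening any single threshold never increases survivors", {
  sim <- make_sim(500)
  base <- run_cascade(sim$gm, sim$trios, filter_config())
  # tightening a marker threshold never increases surviving markers
  for (cfg in list(
    filter_config(marker_min_maf = 0.42),
    filter_config(marker_max_missing = 0.03),
    filter_config(mendel_max_rate = 0.01)
  )) {
    tight <- run_cascade(sim$gm, sim$trios, cfg)
    expect_lte(ncol(tight$matrix$calls), ncol(base$matrix$calls))
    expect_equal(nrow(tight$matrix$calls), nrow(base$matrix$calls))
  }
  # tightening a sample threshold never increases surviving samples
  tight <- run_cascade(sim$gm, sim$trios, filter_config(sample_het_range = c(0.2, 0.5)))
  expect_lte(nrow(tight$matrix$calls), nrow(base$matrix$calls))
})

test_that("error-free simulated data passes the Mendel filter untouched", {
  ped <- build_design(design_config(n_loci = 120))
  fr <- sample_founder_frequencies(120, 0.1, 0.5, seed = 13)
  truth <- drop_genotypes(ped, fr, seed = 13)
  gm <- subset_geno(truth, samples = ped$id[ped$sequenced])
  trios <- trios_from_pedigree(ped, rownames(gm$calls))
  cfg <- filter_config(
    sample_het_range = NULL, marker_min_maf = NULL, marker_min_mac = NULL,
    locus_position_window = NULL, one_snp_per_locus = FALSE,
    hwe_alpha = NULL, ld_r2_max = NULL
  )
  res <- run_cascade(gm, trios, cfg)
  expect_equal(res$report$removed[res$report$step == "mendel"], 0L)
})

test_that("MAF tiers build nested panels with strict thresholds", {
  # a locus at exactly MAF 0.45 is excluded from the 0.45 tier
  exact45 <- c(rep(1L, 9), 0L) # 9 alt alleles of 20
  set.seed(3)
  high <- matrix(rbinom(40, 2, 0.5), 10, 4)
  gm <- toy_gm(cbind(exact45, high))
  stopifnot(marker_stats(gm)$maf[1] == 0.45)
  panels <- build_subsets(gm, tiers = c(0.40, 0.45))
  expect_false("L01" %in% panels[["maf_gt_0.45"]]$loci$locus_id)
  expect_true("L01" %in% panels[["maf_gt_0.4"]]$loci$locus_id)
  # nesting and decreasing size on simulated data
  sim <- make_sim(400, seed = 15)
  panels <- build_subsets(sim$gm, tiers = c(0.30, 0.40, 0.45, 0.48))
  sizes <- vapply(panels, function(p) ncol(p$calls), numeric(1))
  expect_true(all(diff(sizes) < 0))
  for (k in 2:length(panels)) {
    expect_true(all(panels[[k]]$loci$locus_id %in% panels[[k - 1]]$loci$locus_id))
  }
})
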