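test_that("single-parent LOD matches hand computations and flags exclusions", {
  # hom-ref offspring and candidate at p = 0.5, no error:
  # P(o | c parent) = 0.5 vs P(o) = 0.25 -> ln 2
  expect_equal(lod_single(0L, 0L, 0.5, e = 0), log(2))
  # opposing homozygotes are a Mendelian impossibility without error
  expect_identical(lod_single(0L, 2L, 0.5, e = 0), -Inf)
  # with error the same configuration is finite and negative
  v <- lod_single(0L, 2L, 0.5, e = 0.05)
  expect_true(is.finite(v) && v < 0)
  # missing genotypes skip the locus
  expect_true(is.na(lod_single(NA, 1L, 0.5, e = 0.05)))
})

test_that("parent-pair LOD matches hand computations", {
  # all three hom-ref at p = 0.5, no error: P(o|m,f) = 1 vs 0.25 -> ln 4
  expect_equal(lod_pair(0L, 0L, 0L, 0.5, e = 0), log(4))
  expect_identical(lod_pair(0L, 0L, 2L, 0.5, e = 0), -Inf)
})

test_that("LOD scores equal the brute-force enumeration oracle on a full grid", {
  for (p in c(0.1, 0.37, 0.5, 0.82)) {
    for (e in c(0.01, 0.05, 0.2)) {
      for (go in 0:2) {
        for (gc in 0:2) {
          expect_equal(
            lod_single(go, gc, p, e), oracle_lod_single(go, gc, p, e),
            tolerance = 1e-10,
            label = sprintf("single(go=%d,gc=%d,p=%.2f,e=%.2f)", go, gc, p, e)
          )
          for (gf in 0:2) {
            expect_equal(
              lod_pair(go, gc, gf, p, e), oracle_lod_pair(go, gc, gf, p, e),
              tolerance = 1e-10,
              label = sprintf("pair(%d,%d,%d,p=%.2f,e=%.2f)", go, gc, gf, p, e)
            )
          }
        }
      }
    }
  }
})

test_that("true trios score higher as pairs than as single parents on average", {
  set.seed(5)
  p <- runif(40, 0.2, 0.5)
  n <- 400
  gm_m <- rbinom(n * 40, 2, rep(p, each = n))
  gm_f <- rbinom(n * 40, 2, rep(p, each = n))
  a1 <- rbinom(n * 40, 1, gm_m / 2)
  a2 <- rbinom(n * 40, 1, gm_f / 2)
  go <- a1 + a2
  pv <- rep(p, each = n)
  single <- lod_single(go, gm_m, pv, e = 0.05)
  pair <- lod_pair(go, gm_m, gm_f, pv, e = 0.05)
  expect_gt(mean(pair), mean(single))
  expect_gt(mean(single), 0) # true-parent LOD has positive expectation
})

test_that("with no error and full typing the true parent is never excluded", {
  ped <- build_design(design_config(n_loci = 150))
  fr <- sample_founder_frequencies(150, 0.1, 0.5, seed = 17)
  truth <- drop_genotypes(ped, fr, seed = 17)
  trios <- trios_from_pedigree(ped)[1:40, ]
  for (i in seq_len(nrow(trios))) {
    v <- lod_single(
      truth$calls[trios$offspring[i], ], truth$calls[trios$sire[i], ],
      fr$p_alt,
      e = 0
    )
    expect_true(all(is.finite(v)))
  }
})

test_that("allele frequency estimates converge on the simulating values", {
  n <- 10000
  ped <- tibble::tibble(
    id = sprintf("i%05d", 1:n), colony = "ES", generation = 0L,
    family = "F01", role = "sire", sire = NA_character_, dam = NA_character_,
    retained = FALSE, sequenced = TRUE
  )
  fr <- tibble::tibble(locus_id = sprintf("l%02d", 1:30), p_alt = seq(0.05, 0.95, length.out = 30))
  gm <- drop_genotypes(ped, fr, seed = 19)
  est <- estimate_allele_freqs(gm)
  se <- sqrt(fr$p_alt * (1 - fr$p_alt) / (2 * n))
  expect_true(mean(abs(est$p_alt - fr$p_alt) <= 3 * se) > 0.95)
})

test_that("calibration thresholds match an independent search on the same draws", {
  fr <- sample_founder_frequencies(2, 0.45, 0.5, seed = 23)
  prm <- sim_params(n_offspring = 3000, n_candidates = 47)
  cal <- calibrate(fr, prm, mode = "male", seed = 4, keep_draws = TRUE)
  draws <- cal$draws[cal$draws$valid, ]
  # brute-force reference: evaluate every observed A-LOD as a threshold
  ref <- function(gamma) {
    a <- draws$a_lod
    tr <- draws$is_true
    if (mean(tr) >= gamma) return(-999)
    cand <- sort(unique(a))
    ok <- cand[vapply(cand, function(t) mean(tr[a >= t]) >= gamma, logical(1))]
    if (!length(ok)) return(999) else min(ok)
  }
  expect_equal(cal$c_lod_relaxed, ref(0.80))
  expect_equal(cal$c_lod_strict, ref(0.95))
  # a 2-locus panel cannot separate 47 candidates: finite positive thresholds
  expect_true(cal$c_lod_strict >= cal$c_lod_relaxed)
  # reproducibility: same seed gives bit-identical thresholds
  again <- calibrate(fr, prm, mode = "male", seed = 4)
  expect_identical(
    c(again$c_lod_relaxed, again$c_lod_strict),
    c(cal$c_lod_relaxed, cal$c_lod_strict)
  )
})

test_that("confidence classes follow the threshold semantics including sentinels", {
  expect_equal(
    bsfparentage:::classify_assignment(c(20, 10, 3, -2), 5, 15),
    c("strict", "relaxed", "unassigned_most_likely", "unassigned_not_most_likely")
  )
  # complete-separation sentinel assigns everything strictly
  expect_equal(bsfparentage:::classify_assignment(-5, -999, -999), "strict")
  # no-power sentinel never assigns
  expect_equal(bsfparentage:::classify_assignment(50, 999, 999), "unassigned_most_likely")
})

make_study <- function(n_loci = 96, seed = 2, maf_low = 0.4) {
  ped <- build_design(design_config(n_loci = n_loci))
  fr <- sample_founder_frequencies(n_loci, maf_low, 0.5, seed = seed)
  truth <- drop_genotypes(ped, fr, seed = seed)
  obs <- corrupt(truth, error_model(0.05, 0.05), seed = seed)
  study <- subsample_to_study(ped, seed = seed)
  list(obs = obs, study = study, fr = fr, ped = ped)
}

test_that("assignment is invariant to locus and sample ordering", {
  s <- make_study(60)
  panels <- list(panel = s$fr$locus_id)
  base <- batch_assign(s$obs, s$study$couples, s$study$larvae, panels)
  # shuffle loci and samples
  set.seed(99)
  gm2 <- subset_geno(s$obs,
    samples = sample(rownames(s$obs$calls)),
    loci = sample(colnames(s$obs$calls))
  )
  shuf <- batch_assign(gm2, s$study$couples[sample(47), ], s$study$larvae, panels)
  key <- function(df) df[order(df$offspring, df$mode), c("offspring", "mode", "candidate", "a_lod")]
  expect_equal(key(base), key(shuf), tolerance = 1e-12)
})

test_that("candidates never cross colonies and modes multiply out", {
  s <- make_study(48)
  asn <- batch_assign(s$obs, s$study$couples, s$study$larvae, list(p = s$fr$locus_id))
  colony_of <- function(id) sub("_.*", "", id)
  expect_true(all(colony_of(asn$candidate) == colony_of(asn$offspring)))
  expect_equal(nrow(asn), 75 * 3)
})

test_that("confidence summaries cover the four classes and sum to 100", {
  s <- make_study(60)
  thresholds <- tibble::tibble(
    panel = "p", mode = c("male", "female", "parent_pair"),
    c_lod_relaxed = 5, c_lod_strict = 15
  )
  asn <- batch_assign(s$obs, s$study$couples, s$study$larvae,
    list(p = s$fr$locus_id),
    thresholds = thresholds
  )
  conf <- summarize_confidence(asn)
  sums <- tapply(conf$pct, conf$mode, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_setequal(as.character(unique(conf$class)), bsfparentage:::confidence_classes)
})

test_that("calibration tidiers expose thresholds and accuracy", {
  fr <- sample_founder_frequencies(4, 0.4, 0.5, seed = 29)
  cal <- calibrate(fr, sim_params(n_offspring = 500, n_candidates = 10), mode = "female", seed = 6)
  td <- tidy(cal)
  expect_equal(td$confidence, c("relaxed", "strict"))
  expect_equal(td$c_lod, c(cal$c_lod_relaxed, cal$c_lod_strict))
  gl <- glance(cal)
  expect_equal(gl$n_loci, 4)
  expect_true(gl$accuracy >= 0 && gl$accuracy <= 1)
})
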