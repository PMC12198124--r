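#' Filter cascade configuration
#'
#' Thresholds for the sample- and marker-filter cascade applied before
#' parentage analysis. Defaults mirror the study pipeline: sample
#' missingness <= 30%, sample median depth in 1-27x, sample heterozygosity
#' in 0.14-0.61; marker MAF >= 0.3, minor allele count >= 4, mean depth in
#' 15-75x, missingness <= 5%, SNP position within the 40th-70th bp of its
#' RAD locus (inclusive), one SNP per RAD locus, Hardy-Weinberg exact test
#' P >= 0.05, Mendelian error rate <= 3%, and LD pruning at r^2 > 0.5 in a
#' 50-variant window sliding by 5. Set any element to `NULL` to disable
#' that step. `marker_max_obs_het` (0.5 in the population-statistics
#' export) is available but disabled by default because the assignment
#' pipeline deliberately skips heterozygosity-based marker exclusion.
#'
#' @param sample_max_missing Max fraction of missing markers per sample.
#' @param sample_median_depth_range Length-2 numeric, allowed sample median depth.
#' @param sample_het_range Length-2 numeric, allowed sample heterozygosity.
#' @param marker_min_maf Minimum minor allele frequency.
#' @param marker_min_mac Minimum minor allele count.
#' @param marker_max_obs_het Maximum observed heterozygosity (disabled by default).
#' @param marker_mean_depth_range Length-2 numeric, allowed marker mean depth.
#' @param marker_max_missing Max fraction of missing calls per marker.
#' @param locus_position_window Length-2 integer, allowed SNP position within
#'   its RAD locus (bp, inclusive).
#' @param one_snp_per_locus Keep only the first SNP (by position) per RAD locus.
#' @param hwe_alpha Hardy-Weinberg exact-test significance threshold.
#' @param mendel_max_rate Maximum per-marker Mendelian error rate across trios.
#' @param ld_window,ld_step,ld_r2_max Windowed LD pruning parameters
#'   (window and step in variant counts).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(sample_max_missing = 0.30,
                          sample_median_depth_range = c(1, 27),
                          sample_het_range = c(0.14, 0.61),
                          marker_min_maf = 0.3,
                          marker_min_mac = 4,
                          marker_max_obs_het = NULL,
                          marker_mean_depth_range = c(15, 75),
                          marker_max_missing = 0.05,
                          locus_position_window = c(40, 70),
                          one_snp_per_locus = TRUE,
                          hwe_alpha = 0.05,
                          mendel_max_rate = 0.03,
                          ld_window = 50, ld_step = 5, ld_r2_max = 0.5) {
  for (r in list(sample_median_depth_range, sample_het_range,
                 marker_mean_depth_range, locus_position_window)) {
    if (!is.null(r) && (length(r) != 2 || r[1] > r[2])) {
      stop("range thresholds must be length-2 and ordered", call. = FALSE)
    }
  }
  structure(
    list(
      sample_max_missing = sample_max_missing,
      sample_median_depth_range = sample_median_depth_range,
      sample_het_range = sample_het_range,
      marker_min_maf = marker_min_maf,
      marker_min_mac = marker_min_mac,
      marker_max_obs_het = marker_max_obs_het,
      marker_mean_depth_range = marker_mean_depth_range,
      marker_max_missing = marker_max_missing,
      locus_position_window = locus_position_window,
      one_snp_per_locus = isTRUE(one_snp_per_locus),
      hwe_alpha = hwe_alpha,
      mendel_max_rate = mendel_max_rate,
      ld_window = ld_window, ld_step = ld_step, ld_r2_max = ld_r2_max
    ),
    class = "filter_config"
  )
}

#' Per-marker summary statistics
#'
#' Statistics are computed over non-missing calls only; MAF is folded to
#' be at most 0.5. A marker with zero calls gets `call_rate` 0 and `NA`
#' for the undefined statistics.
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per locus: `locus_id`, `n_called`,
#'   `call_rate`, `p_alt`, `maf`, `mac`, `obs_het`, `mean_depth`,
#'   `monomorphic`.
#' @export
marker_stats <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  G <- gm$calls
  if (ncol(G) == 0) stop("empty genotype matrix", call. = FALSE)
  n_called <- colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  tot <- 2 * n_called
  p_alt <- ifelse(n_called > 0, alt / tot, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  mac <- pmin(alt, tot - alt)
  obs_het <- ifelse(n_called > 0, colSums(G == 1L, na.rm = TRUE) / n_called, NA_real_)
  mean_depth <- if (is.null(gm$depth)) {
    rep(NA_real_, ncol(G))
  } else {
    colMeans(gm$depth, na.rm = TRUE)
  }
  tibble::tibble(
    locus_id = colnames(G) %||% character(0),
    n_called = as.integer(unname(n_called)),
    call_rate = unname(n_called) / nrow(G),
    p_alt = unname(p_alt),
    maf = unname(maf),
    mac = as.integer(unname(mac)),
    obs_het = unname(obs_het),
    mean_depth = unname(mean_depth),
    monomorphic = unname(n_called > 0 & mac == 0L)
  )
}

#' Per-sample summary statistics
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with `sample_id`, `missing_frac`, `het` (heterozygous
#'   fraction among non-missing calls) and `median_depth` (`NA` when no
#'   depth matrix is present).
#' @export
sample_stats <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  G <- gm$calls
  n_called <- rowSums(!is.na(G))
  tibble::tibble(
    sample_id = rownames(G) %||% character(0),
    missing_frac = unname(1 - n_called / ncol(G)),
    het = unname(ifelse(n_called > 0, rowSums(G == 1L, na.rm = TRUE) / n_called, NA_real_)),
    median_depth = if (is.null(gm$depth)) NA_real_ else unname(apply(gm$depth, 1, stats::median, na.rm = TRUE))
  )
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the total sample size and minor allele
#' count, the p-value is the summed probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' configuration (two-sided by probability mass).
#'
#' @param nAA,nAB,nBB Genotype counts (vectorised).
#' @return P-values in (0, 1]; monomorphic loci give exactly 1.
#' @export
hwe_exact_pvalue <- function(nAA, nAB, nBB) {
  mapply(function(aa, ab, bb) {
    if (any(c(aa, ab, bb) < 0) || aa + ab + bb < 1) {
      stop("genotype counts must be non-negative with total >= 1", call. = FALSE)
    }
    n <- aa + ab + bb
    n_a <- 2L * aa + ab
    n_minor <- min(n_a, 2L * n - n_a)
    if (n_minor == 0L) return(1)
    hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
    # conditional probability of each heterozygote count given n and n_minor
    logp <- lfactorial(n) -
      lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
      lfactorial(n - (n_minor + hets) / 2) +
      hets * log(2) +
      lfactorial(n_minor) + lfactorial(2L * n - n_minor) - lfactorial(2L * n)
    prob <- exp(logp)
    prob <- prob / sum(prob)
    obs <- prob[match(ab, hets)]
    sum(prob[prob <= obs * (1 + 1e-7)])
  }, nAA, nAB, nBB)
}

#' Build parent-offspring trios from a pedigree
#'
#' @param pedigree Pedigree tibble (columns `id`, `sire`, `dam`).
#' @param sample_ids Optional character vector; trios are restricted to
#'   individuals in this set.
#' @return A tibble with columns `offspring`, `sire`, `dam`.
#' @export
trios_from_pedigree <- function(pedigree, sample_ids = NULL) {
  tr <- dplyr::filter(pedigree, !is.na(.data$sire), !is.na(.data$dam))
  tr <- tibble::tibble(offspring = tr$id, sire = tr$sire, dam = tr$dam)
  if (!is.null(sample_ids)) {
    tr <- dplyr::filter(
      tr,
      .data$offspring %in% sample_ids, .data$sire %in% sample_ids, .data$dam %in% sample_ids
    )
  }
  tr
}

#' Per-marker Mendelian error rate over known trios
#'
#' A trio is evaluable at a locus when offspring, sire and dam are all
#' called; it is an error when the offspring genotype is impossible under
#' Mendelian transmission from the two parental genotypes.
#'
#' @param gm A [geno_matrix()].
#' @param trios Tibble from [trios_from_pedigree()].
#' @return A tibble with `locus_id`, `n_evaluable`, `n_errors`, `rate`
#'   (`NA` when no trio is evaluable; such loci pass the filter by
#'   convention).
#' @export
mendel_error_rate <- function(gm, trios) {
  stopifnot(inherits(gm, "geno_matrix"))
  ids <- rownames(gm$calls)
  miss <- setdiff(unlist(trios[c("offspring", "sire", "dam")]), ids)
  if (length(miss)) stop("trio ids absent from matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  GO <- gm$calls[trios$offspring, , drop = FALSE]
  GS <- gm$calls[trios$sire, , drop = FALSE]
  GD <- gm$calls[trios$dam, , drop = FALSE]
  evaluable <- !is.na(GO) & !is.na(GS) & !is.na(GD)
  impossible <- array(FALSE, dim(GO))
  idx <- which(evaluable)
  flat <- (GO[idx] + 1L) + 3L * GS[idx] + 9L * GD[idx]
  impossible[idx] <- TRANS_PAIR[flat] == 0
  n_eval <- colSums(evaluable)
  n_err <- colSums(impossible)
  tibble::tibble(
    locus_id = colnames(gm$calls),
    n_evaluable = as.integer(unname(n_eval)),
    n_errors = as.integer(unname(n_err)),
    rate = unname(ifelse(n_eval > 0, n_err / n_eval, NA_real_))
  )
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of alternate-allele dosages over
#' pairwise-complete samples.
#'
#' @param x,y Dosage vectors coded 0/1/2 with `NA` for missing.
#' @return r^2, or `NA` when fewer than 2 complete pairs or either vector
#'   has zero variance (treated as 0 during pruning).
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window` variants (shifting by `step`),
#' while any retained pair has r^2 above `r2_max`, the later-positioned
#' member of the worst (highest r^2) pair is removed. Windows never span
#' chromosomes. Deterministic for fixed input.
#'
#' @param gm A [geno_matrix()] whose loci carry `chrom` and `pos`.
#' @param window,step Window length and shift, in variant counts.
#' @param r2_max Maximum tolerated pairwise r^2.
#' @return Character vector of retained locus ids (in input order).
#' @export
prune_ld <- function(gm, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(inherits(gm, "geno_matrix"))
  loci <- gm$loci
  ord <- order(loci$chrom, loci$pos)
  keep <- rep(TRUE, nrow(loci))
  for (ch in unique(loci$chrom[ord])) {
    ci <- ord[loci$chrom[ord] == ch] # matrix column indices, position-sorted
    L <- length(ci)
    if (L < 2) next
    starts <- unique(c(seq(1L, max(1L, L - 1L), by = step)))
    for (s in starts) {
      win <- ci[s:min(s + window - 1L, L)]
      repeat {
        active <- win[keep[win]]
        if (length(active) < 2) break
        r2 <- suppressWarnings(stats::cor(gm$calls[, active, drop = FALSE],
          use = "pairwise.complete.obs"
        )^2)
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        worst <- max(r2)
        if (worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1, ]
        # remove the later-positioned member of the worst pair
        keep[active[max(hit)]] <- FALSE
      }
    }
  }
  colnames(gm$calls)[keep]
}

#' Run the full sample- and marker-filter cascade
#'
#' Applies, in order: monomorphic-marker removal; markers shared across
#' colonies; sample missingness, median depth and heterozygosity filters;
#' marker MAF, minor allele count, (optional) observed heterozygosity,
#' mean depth, missingness and RAD-locus position filters; one SNP per RAD
#' locus; Hardy-Weinberg exact test; Mendelian error rate over trios; and
#' windowed LD pruning. Marker statistics are recomputed after each
#' sample-removal step. Steps whose threshold is `NULL` (or whose required
#' metadata is absent) remove nothing but are still reported.
#'
#' @param gm A [geno_matrix()].
#' @param trios Optional trio tibble for the Mendelian filter.
#' @param config A [filter_config()].
#' @return A list with `matrix` (the filtered [geno_matrix()]) and
#'   `report`, a tibble with one row per step: `step`, `scope`
#'   (`"sample"`/`"marker"`), `removed`, `samples_remaining`,
#'   `markers_remaining`.
#' @export
run_cascade <- function(gm, trios = NULL, config = filter_config()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "filter_config"))
  report <- list()
  record <- function(step, scope, removed) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      step = step, scope = scope, removed = as.integer(removed),
      samples_remaining = nrow(gm$calls), markers_remaining = ncol(gm$calls)
    )
  }
  drop_markers <- function(step, bad_ids) {
    bad_ids <- intersect(bad_ids, colnames(gm$calls))
    if (length(bad_ids)) gm <<- subset_geno(gm, loci = setdiff(colnames(gm$calls), bad_ids))
    record(step, "marker", length(bad_ids))
  }
  drop_samples <- function(step, bad_ids) {
    bad_ids <- intersect(bad_ids, rownames(gm$calls))
    if (length(bad_ids)) gm <<- subset_geno(gm, samples = setdiff(rownames(gm$calls), bad_ids))
    record(step, "sample", length(bad_ids))
  }
  # empty survivor sets are allowed: fall back to zero-row stats
  mstats <- function() {
    if (ncol(gm$calls) > 0 && nrow(gm$calls) > 0) return(marker_stats(gm))
    tibble::tibble(
      locus_id = colnames(gm$calls) %||% character(0),
      n_called = 0L, call_rate = 0, p_alt = NA_real_, maf = NA_real_,
      mac = NA_integer_, obs_het = NA_real_, mean_depth = NA_real_,
      monomorphic = FALSE
    )
  }

  ms <- mstats()
  drop_markers("monomorphic", ms$locus_id[ms$monomorphic | ms$n_called == 0])

  if ("colony" %in% names(gm$samples) && dplyr::n_distinct(gm$samples$colony) > 1) {
    called_everywhere <- Reduce(`&`, lapply(
      split(seq_len(nrow(gm$calls)), gm$samples$colony),
      function(i) colSums(!is.na(gm$calls[i, , drop = FALSE])) > 0
    ))
    drop_markers("shared_across_colonies", colnames(gm$calls)[!called_everywhere])
  } else {
    record("shared_across_colonies", "marker", 0L)
  }

  ss <- sample_stats(gm)
  drop_samples(
    "sample_missingness",
    if (is.null(config$sample_max_missing)) character(0) else ss$sample_id[ss$missing_frac > config$sample_max_missing]
  )
  ss <- sample_stats(gm)
  rng <- config$sample_median_depth_range
  drop_samples(
    "sample_median_depth",
    if (is.null(rng) || is.null(gm$depth)) character(0) else ss$sample_id[!is.na(ss$median_depth) & (ss$median_depth < rng[1] | ss$median_depth > rng[2])]
  )
  ss <- sample_stats(gm)
  rng <- config$sample_het_range
  drop_samples(
    "sample_heterozygosity",
    if (is.null(rng)) character(0) else ss$sample_id[!is.na(ss$het) & (ss$het < rng[1] | ss$het > rng[2])]
  )

  ms <- mstats()
  drop_markers(
    "marker_maf",
    if (is.null(config$marker_min_maf)) character(0) else ms$locus_id[!is.na(ms$maf) & ms$maf < config$marker_min_maf]
  )
  ms <- mstats()
  drop_markers(
    "marker_mac",
    if (is.null(config$marker_min_mac)) character(0) else ms$locus_id[!is.na(ms$mac) & ms$mac < config$marker_min_mac]
  )
  ms <- mstats()
  drop_markers(
    "marker_obs_het",
    if (is.null(config$marker_max_obs_het)) character(0) else ms$locus_id[!is.na(ms$obs_het) & ms$obs_het > config$marker_max_obs_het]
  )
  ms <- mstats()
  rng <- config$marker_mean_depth_range
  drop_markers(
    "marker_mean_depth",
    if (is.null(rng) || is.null(gm$depth)) character(0) else ms$locus_id[!is.na(ms$mean_depth) & (ms$mean_depth < rng[1] | ms$mean_depth > rng[2])]
  )
  ms <- mstats()
  drop_markers(
    "marker_missingness",
    if (is.null(config$marker_max_missing)) character(0) else ms$locus_id[1 - ms$call_rate > config$marker_max_missing]
  )

  win <- config$locus_position_window
  if (!is.null(win) && "pos_in_locus" %in% names(gm$loci)) {
    bad <- gm$loci$locus_id[gm$loci$pos_in_locus < win[1] | gm$loci$pos_in_locus > win[2]]
    drop_markers("locus_position", bad)
  } else {
    record("locus_position", "marker", 0L)
  }

  if (config$one_snp_per_locus && "rad_locus" %in% names(gm$loci)) {
    li <- gm$loci
    first <- li |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::arrange(.data$rad_locus, .data$pos) |>
      dplyr::distinct(.data$rad_locus, .keep_all = TRUE)
    drop_markers("one_snp_per_locus", setdiff(li$locus_id, first$locus_id))
  } else {
    record("one_snp_per_locus", "marker", 0L)
  }

  if (!is.null(config$hwe_alpha) && nrow(gm$calls) > 0 && ncol(gm$calls) > 0) {
    G <- gm$calls
    p <- hwe_exact_pvalue(
      colSums(G == 0L, na.rm = TRUE),
      colSums(G == 1L, na.rm = TRUE),
      colSums(G == 2L, na.rm = TRUE)
    )
    drop_markers("hwe", colnames(G)[p < config$hwe_alpha])
  } else {
    record("hwe", "marker", 0L)
  }

  if (!is.null(config$mendel_max_rate) && !is.null(trios) && nrow(trios) > 0) {
    tr <- trios_from_pedigree(
      tibble::tibble(id = trios$offspring, sire = trios$sire, dam = trios$dam),
      rownames(gm$calls)
    )
    if (nrow(tr) > 0) {
      me <- mendel_error_rate(gm, tr)
      drop_markers("mendel", me$locus_id[!is.na(me$rate) & me$rate > config$mendel_max_rate])
    } else {
      record("mendel", "marker", 0L)
    }
  } else {
    record("mendel", "marker", 0L)
  }

  if (!is.null(config$ld_r2_max) && nrow(gm$calls) > 1 && ncol(gm$calls) > 0) {
    kept <- prune_ld(gm, config$ld_window, config$ld_step, config$ld_r2_max)
    drop_markers("ld_prune", setdiff(colnames(gm$calls), kept))
  } else {
    record("ld_prune", "marker", 0L)
  }

  list(matrix = gm, report = dplyr::bind_rows(report))
}

#' Nested MAF-tier marker panels
#'
#' Tier `t` retains loci whose folded minor allele frequency is strictly
#' greater than `t`, giving nested panels for ascending tiers.
#'
#' @param gm A [geno_matrix()].
#' @param tiers Ascending numeric MAF thresholds
#'   (default `c(0.40, 0.45, 0.47, 0.48)`).
#' @return A named list of [geno_matrix()] panels
#'   (names like `"maf_gt_0.4"`).
#' @export
build_subsets <- function(gm, tiers = c(0.40, 0.45, 0.47, 0.48)) {
  stopifnot(inherits(gm, "geno_matrix"), !is.unsorted(tiers))
  ms <- marker_stats(gm)
  out <- lapply(tiers, function(t) {
    subset_geno(gm, loci = ms$locus_id[!is.na(ms$maf) & ms$maf > t])
  })
  names(out) <- paste0("maf_gt_", tiers)
  out
}
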