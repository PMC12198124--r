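#' Parentage simulation parameters
#'
#' Parameters for Monte-Carlo calibration of critical LOD thresholds and
#' for assignment. Defaults follow the study analysis: 10,000 simulated
#' offspring, 47 candidate parents, all candidates sampled, 95% of loci
#' typed, 5% mistyping, at least 50% of the panel typed per offspring,
#' full-sib relatedness (r = 0.5) between the true parent and the other
#' candidates, and relaxed/strict confidence levels of 80% and 95%.
#'
#' @param n_offspring Simulated offspring per calibration run.
#' @param n_candidates Candidate parents (or candidate pairs) per offspring.
#' @param prop_sampled Proportion of true parents among the sampled
#'   candidates (only 1.0 is supported: the true parent is always present).
#' @param prop_typed Probability that a locus is typed in any one sample.
#' @param mistype_rate Probability that a typed call is replaced by a
#'   random Hardy-Weinberg genotype.
#' @param min_typed_frac Minimum fraction of panel loci typed in an
#'   offspring for its assignment to be valid.
#' @param relatedness Relatedness r between each non-true candidate and the
#'   true parent of its sex: 0 (unrelated) or 0.5 (full sibs).
#' @param inbreeding_rate Fraction of simulated offspring whose true
#'   parents are full sibs of each other (those offspring have F = 0.25).
#' @param confidence_relaxed,confidence_strict Confidence levels for the
#'   relaxed and strict critical LOD thresholds.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_offspring = 10000, n_candidates = 47,
                       prop_sampled = 1.0, prop_typed = 0.95,
                       mistype_rate = 0.05, min_typed_frac = 0.5,
                       relatedness = 0.5, inbreeding_rate = 0,
                       confidence_relaxed = 0.80, confidence_strict = 0.95) {
  check_prob(prop_typed, "prop_typed")
  check_prob(mistype_rate, "mistype_rate", allow_one = FALSE)
  check_prob(inbreeding_rate, "inbreeding_rate")
  check_prob(min_typed_frac, "min_typed_frac")
  if (prop_sampled != 1.0) stop("only prop_sampled = 1.0 is supported", call. = FALSE)
  if (!relatedness %in% c(0, 0.5)) {
    stop("relatedness must be 0 (unrelated candidates) or 0.5 (full sibs)", call. = FALSE)
  }
  if (!(confidence_relaxed < confidence_strict)) {
    stop("confidence_relaxed must be below confidence_strict", call. = FALSE)
  }
  structure(
    list(
      n_offspring = as.integer(n_offspring), n_candidates = as.integer(n_candidates),
      prop_sampled = prop_sampled, prop_typed = prop_typed,
      mistype_rate = mistype_rate, min_typed_frac = min_typed_frac,
      relatedness = relatedness, inbreeding_rate = inbreeding_rate,
      confidence_relaxed = confidence_relaxed, confidence_strict = confidence_strict
    ),
    class = "sim_params"
  )
}

#' Estimate allele frequencies from genotypes
#'
#' @param gm A [geno_matrix()].
#' @return A tibble `locus_id`, `n_called`, `p_alt`, `maf`; loci with no
#'   calls at all are excluded from the panel.
#' @export
estimate_allele_freqs <- function(gm) {
  ms <- marker_stats(gm)
  dropped <- sum(ms$n_called == 0)
  if (dropped > 0) message(dropped, " all-missing locus/loci excluded from the panel")
  ms[ms$n_called > 0, c("locus_id", "n_called", "p_alt", "maf")]
}

# error-marginalised observation model: M[l, obs + 1, true + 1] =
# P(observed genotype | true genotype) under "replace with a random
# HWE genotype with probability e"
err_model_array <- function(p, e) {
  hw <- hwe_probs(p)
  L <- length(p)
  M <- array(0, c(L, 3, 3))
  for (obs in 1:3) {
    for (tr in 1:3) {
      M[, obs, tr] <- (if (obs == tr) 1 - e else 0) + e * hw[, obs]
    }
  }
  M
}

# single-parent transmission array T[l, to + 1, tc + 1]
trans_single_array <- function(p) {
  L <- length(p)
  T1 <- array(0, c(L, 3, 3))
  for (tc in 0:2) {
    a <- tc / 2
    T1[, 1, tc + 1] <- (1 - a) * (1 - p)
    T1[, 2, tc + 1] <- a * (1 - p) + (1 - a) * p
    T1[, 3, tc + 1] <- a * p
  }
  T1
}

# per-locus LOD lookup tables for all 3x3 (single) or 3x3x3 (pair)
# observed-genotype combinations; vectorised over loci
lod_table_single <- function(p, e) {
  L <- length(p)
  hw <- hwe_probs(p)
  M <- err_model_array(p, e)
  T1 <- trans_single_array(p)
  out <- array(NA_real_, c(L, 3, 3))
  for (oo in 1:3) {
    eo <- M[, oo, , drop = FALSE]
    dim(eo) <- c(L, 3)
    mo <- rowSums(hw * eo)
    for (oc in 1:3) {
      wc <- hw * M[, oc, ]
      num <- 0
      for (tc in 1:3) {
        s <- T1[, 1, tc] * eo[, 1] + T1[, 2, tc] * eo[, 2] + T1[, 3, tc] * eo[, 3]
        num <- num + wc[, tc] * s
      }
      out[, oo, oc] <- log(num) - log(rowSums(wc) * mo)
    }
  }
  out
}

lod_table_pair <- function(p, e) {
  L <- length(p)
  hw <- hwe_probs(p)
  M <- err_model_array(p, e)
  out <- array(NA_real_, c(L, 3, 3, 3))
  marg <- function(obs) {
    eo <- M[, obs, ]
    dim(eo) <- c(L, 3)
    list(eo = eo, m = rowSums(hw * eo))
  }
  mg <- lapply(1:3, marg)
  for (oo in 1:3) {
    eo <- mg[[oo]]$eo
    for (om in 1:3) {
      wm <- hw * mg[[om]]$eo
      for (of in 1:3) {
        wf <- hw * mg[[of]]$eo
        num <- 0
        for (tm in 1:3) {
          for (tf in 1:3) {
            s <- TRANS_PAIR[1, tm, tf] * eo[, 1] +
              TRANS_PAIR[2, tm, tf] * eo[, 2] +
              TRANS_PAIR[3, tm, tf] * eo[, 3]
            num <- num + wm[, tm] * wf[, tf] * s
          }
        }
        out[, oo, om, of] <- log(num) - log(mg[[oo]]$m * mg[[om]]$m * mg[[of]]$m)
      }
    }
  }
  out
}

#' Per-locus LOD score for a single candidate parent
#'
#' Natural-log likelihood ratio of "the candidate is a parent of the
#' offspring (the other parent drawn from the population)" against "the
#' candidate is unrelated", with both observed genotypes marginalised over
#' the mistyping model (a call is the true genotype with probability
#' `1 - e`, otherwise a random Hardy-Weinberg genotype). With `e = 0`,
#' opposing homozygotes give `-Inf` (Mendelian exclusion).
#'
#' @param g_o,g_c Observed offspring and candidate dosages (0/1/2, `NA`
#'   skips the locus and yields `NA`). Vectorised over loci.
#' @param freq Alternate-allele frequency per locus.
#' @param e Mistyping rate.
#' @return Per-locus log-likelihood ratios.
#' @export
lod_single <- function(g_o, g_c, freq, e = 0.05) {
  n <- max(length(g_o), length(g_c), length(freq))
  g_o <- rep_len(g_o, n)
  g_c <- rep_len(g_c, n)
  freq <- rep_len(freq, n)
  tab <- lod_table_single(freq, e)
  out <- rep(NA_real_, n)
  ok <- !is.na(g_o) & !is.na(g_c)
  out[ok] <- tab[cbind(which(ok), g_o[ok] + 1L, g_c[ok] + 1L)]
  out
}

#' Per-locus LOD score for a candidate parent pair
#'
#' Natural-log likelihood ratio of "the candidate pair are the parents"
#' against "offspring unrelated to both", error-marginalised as in
#' [lod_single()].
#'
#' @param g_o,g_m,g_f Observed offspring, candidate-mother and
#'   candidate-father dosages (vectorised over loci; any `NA` skips the
#'   locus).
#' @param freq Alternate-allele frequency per locus.
#' @param e Mistyping rate.
#' @return Per-locus log-likelihood ratios.
#' @export
lod_pair <- function(g_o, g_m, g_f, freq, e = 0.05) {
  n <- max(length(g_o), length(g_m), length(g_f), length(freq))
  g_o <- rep_len(g_o, n)
  g_m <- rep_len(g_m, n)
  g_f <- rep_len(g_f, n)
  freq <- rep_len(freq, n)
  tab <- lod_table_pair(freq, e)
  out <- rep(NA_real_, n)
  ok <- !is.na(g_o) & !is.na(g_m) & !is.na(g_f)
  out[ok] <- tab[cbind(which(ok), g_o[ok] + 1L, g_m[ok] + 1L, g_f[ok] + 1L)]
  out
}

# Mendelian child of two parent dosage vectors
mendel_child <- function(a, b) {
  stats::rbinom(length(a), 1L, a / 2) + stats::rbinom(length(b), 1L, b / 2)
}

# observation process: mistype with probability e, untyped with
# probability 1 - prop_typed (p is the scalar locus frequency)
observe_calls <- function(g, p, e, prop_typed) {
  n <- length(g)
  if (e > 0) {
    hit <- stats::runif(n) < e
    nh <- sum(hit)
    if (nh) g[hit] <- stats::rbinom(nh, 2L, p)
  }
  if (prop_typed < 1) g[stats::runif(n) >= prop_typed] <- NA_integer_
  g
}

# smallest threshold t (over observed most-likely A-LOD values) such that
# the fraction of true parents among assignments with A-LOD >= t reaches
# gamma; -999 when no thresholding is needed, +999 when unattainable
find_c_lod <- function(a_lod, is_true, gamma) {
  o <- order(a_lod, decreasing = TRUE)
  a_s <- a_lod[o]
  prop <- cumsum(is_true[o]) / seq_along(o)
  n <- length(a_s)
  if (prop[n] >= gamma) return(-999.0)
  # only cut points where the next value is strictly smaller are realisable
  cuts <- which(c(a_s[-n] > a_s[-1], TRUE))
  ok <- cuts[prop[cuts] >= gamma]
  if (!length(ok)) return(999.0)
  a_s[max(ok)]
}

#' Calibrate critical LOD thresholds by Monte-Carlo simulation
#'
#' Simulates `params$n_offspring` offspring from parents drawn under
#' Hardy-Weinberg proportions at the panel's allele frequencies. For each
#' offspring the candidate set contains the true parent (or pair) plus
#' `n_candidates - 1` relatives of the true parent(s) (full sibs when
#' `relatedness = 0.5`); with probability `inbreeding_rate` the offspring's
#' own parents are full sibs. Typing and mistyping are applied to offspring
#' and candidates, every candidate is scored, and the most-likely
#' candidate's A-LOD together with its true/false status yields the
#' critical LOD (C-LOD) at the relaxed and strict confidence levels: the
#' smallest threshold above which the desired fraction of most-likely
#' candidates are true parents. `-999.0` flags complete separation (no
#' threshold needed); `+999.0` flags an unattainable confidence level.
#'
#' @param freqs Tibble with per-locus `p_alt` (e.g. from
#'   [estimate_allele_freqs()] or [sample_founder_frequencies()]).
#' @param params A [sim_params()].
#' @param mode `"male"`, `"female"` or `"parent_pair"`.
#' @param seed Integer seed.
#' @param keep_draws Keep the per-offspring simulation draws (A-LOD of the
#'   most-likely candidate, its status, typed-locus count) in the result.
#' @return An object of class `pa_calibration`: mode, the two C-LOD values,
#'   the unthresholded accuracy, counts, parameters and seed.
#' @export
calibrate <- function(freqs, params = sim_params(), mode = c("male", "female", "parent_pair"),
                      seed = 1, keep_draws = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sim_params"))
  p_vec <- freqs$p_alt
  L <- length(p_vec)
  if (L < 1) stop("empty panel", call. = FALSE)
  set.seed(derive_seed(seed, 71L))
  N <- params$n_offspring
  K <- params$n_candidates
  e <- params$mistype_rate
  pt <- params$prop_typed
  related <- params$relatedness == 0.5
  inb <- stats::runif(N) < params$inbreeding_rate
  tab_s <- if (mode != "parent_pair") lod_table_single(p_vec, e) else NULL
  tab_p <- if (mode == "parent_pair") lod_table_pair(p_vec, e) else NULL
  total <- matrix(0, N, K)
  n_typed_o <- integer(N)
  rep_idx <- rep(seq_len(N), K - 1L)
  for (l in seq_len(L)) {
    p <- p_vec[l]
    # paternal grandparents and the true father
    g1 <- stats::rbinom(N, 2L, p)
    g2 <- stats::rbinom(N, 2L, p)
    father <- mendel_child(g1, g2)
    # maternal side: full sibs of the father when the mating is inbred
    h1 <- stats::rbinom(N, 2L, p)
    h2 <- stats::rbinom(N, 2L, p)
    mg1 <- ifelse(inb, g1, h1)
    mg2 <- ifelse(inb, g2, h2)
    mother <- mendel_child(mg1, mg2)
    off <- mendel_child(father, mother)
    obs_o <- observe_calls(off, p, e, pt)
    n_typed_o <- n_typed_o + !is.na(obs_o)
    sib_of <- function(a, b) {
      if (related) mendel_child(a[rep_idx], b[rep_idx]) else stats::rbinom(N * (K - 1L), 2L, p)
    }
    if (mode == "male") {
      cand <- cbind(father, matrix(sib_of(g1, g2), N, K - 1L))
    } else if (mode == "female") {
      cand <- cbind(mother, matrix(sib_of(mg1, mg2), N, K - 1L))
    } else {
      cand_m <- observe_calls(cbind(father, matrix(sib_of(g1, g2), N, K - 1L)), p, e, pt)
      cand_f <- observe_calls(cbind(mother, matrix(sib_of(mg1, mg2), N, K - 1L)), p, e, pt)
      flat <- (obs_o + 1L) + 3L * cand_m + 9L * cand_f
      contrib <- tab_p[l, , , ][flat]
      contrib[is.na(contrib)] <- 0
      total <- total + contrib
      next
    }
    cand <- observe_calls(cand, p, e, pt)
    flat <- (obs_o + 1L) + 3L * cand
    contrib <- tab_s[l, , ][flat]
    contrib[is.na(contrib)] <- 0
    total <- total + contrib
  }
  valid <- n_typed_o >= ceiling(params$min_typed_frac * L)
  best_idx <- max.col(total, ties.method = "first") # candidate 1 is the truth
  a_lod <- total[cbind(seq_len(N), best_idx)]
  is_true <- best_idx == 1L
  a <- a_lod[valid]
  tr <- is_true[valid]
  res <- structure(
    list(
      mode = mode,
      c_lod_relaxed = find_c_lod(a, tr, params$confidence_relaxed),
      c_lod_strict = find_c_lod(a, tr, params$confidence_strict),
      accuracy = mean(tr),
      n_offspring = N,
      n_valid = sum(valid),
      n_loci = L,
      params = params,
      seed = seed
    ),
    class = "pa_calibration"
  )
  if (keep_draws) {
    res$draws <- tibble::tibble(a_lod = a_lod, is_true = is_true, n_typed = n_typed_o, valid = valid)
  }
  res
}

#' @export
print.pa_calibration <- function(x, ...) {
  cat(sprintf(
    "<pa_calibration> mode=%s loci=%d offspring=%d\n  C-LOD relaxed (%.0f%%): %.2f   strict (%.0f%%): %.2f   accuracy: %.3f\n",
    x$mode, x$n_loci, x$n_offspring,
    100 * x$params$confidence_relaxed, x$c_lod_relaxed,
    100 * x$params$confidence_strict, x$c_lod_strict, x$accuracy
  ))
  invisible(x)
}

classify_assignment <- function(a_lod, c_relaxed, c_strict) {
  dplyr::case_when(
    is.na(a_lod) | is.na(c_relaxed) | is.na(c_strict) ~ NA_character_,
    a_lod >= c_strict ~ "strict",
    a_lod >= c_relaxed ~ "relaxed",
    a_lod > 0 ~ "unassigned_most_likely",
    TRUE ~ "unassigned_not_most_likely"
  )
}

confidence_classes <- c(
  "strict", "relaxed", "unassigned_most_likely", "unassigned_not_most_likely"
)

# score one offspring against a candidate set on a fixed panel;
# returns a_lod and loci-compared per candidate
score_candidates <- function(G, off_id, cand_a, cand_b = NULL, tab_s = NULL, tab_p = NULL) {
  L <- ncol(G)
  go <- G[off_id, ]
  li <- seq_len(L)
  n <- length(cand_a)
  a_lod <- numeric(n)
  n_cmp <- integer(n)
  for (k in seq_len(n)) {
    if (is.null(cand_b)) {
      gc <- G[cand_a[k], ]
      ok <- !is.na(go) & !is.na(gc)
      v <- tab_s[cbind(li[ok], go[ok] + 1L, gc[ok] + 1L)]
    } else {
      gmr <- G[cand_a[k], ]
      gfr <- G[cand_b[k], ]
      ok <- !is.na(go) & !is.na(gmr) & !is.na(gfr)
      v <- tab_p[cbind(li[ok], go[ok] + 1L, gmr[ok] + 1L, gfr[ok] + 1L)]
    }
    a_lod[k] <- sum(v)
    n_cmp[k] <- sum(ok)
  }
  list(a_lod = a_lod, n_compared = n_cmp)
}

#' Batch parentage assignment restricted by colony and generation
#'
#' For every offspring, the candidate set is restricted to retained couples
#' from the same colony whose generation is the offspring's generation
#' minus one. In `"male"`/`"female"` mode candidates are the couples' sires
#' or dams; in `"parent_pair"` mode the couples themselves. The candidate
#' (or pair) with the highest summed A-LOD is selected; when thresholds are
#' supplied each assignment also receives one of the four confidence
#' classes (strict, relaxed, unassigned-most-likely,
#' unassigned-not-most-likely).
#'
#' @param gm A [geno_matrix()] holding all offspring and candidate genotypes.
#' @param couples Tibble with `couple_id`, `sire`, `dam`, `colony`,
#'   `generation` (e.g. from [subsample_to_study()]).
#' @param offspring Tibble with `id`, `colony`, `generation` and (for
#'   accuracy scoring) `sire`, `dam` of the true parents.
#' @param panels Named list of panels: character vectors of locus ids or
#'   [geno_matrix()] objects.
#' @param params A [sim_params()] (supplies the mistyping rate and the
#'   minimum typed-locus fraction).
#' @param thresholds Optional tibble with columns `panel`, `mode`,
#'   `c_lod_relaxed`, `c_lod_strict` (e.g. built from [calibrate()] runs);
#'   without it classes are `NA`.
#' @param modes Subset of `c("male", "female", "parent_pair")`.
#' @param freqs Optional per-panel allele frequencies; defaults to
#'   frequencies estimated from `gm` per panel.
#' @return A tibble with one row per offspring x panel x mode: `panel`,
#'   `mode`, `offspring`, `candidate`, `a_lod`, `n_compared`, `valid`,
#'   `class`, `true_candidate`, `correct`. Offspring with an empty
#'   restricted candidate set are skipped with a warning.
#' @export
batch_assign <- function(gm, couples, offspring, panels,
                         params = sim_params(), thresholds = NULL,
                         modes = c("male", "female", "parent_pair"),
                         freqs = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  skipped <- 0L
  for (pn in names(panels)) {
    panel <- panels[[pn]]
    loci <- if (inherits(panel, "geno_matrix")) panel$loci$locus_id else panel
    sub <- subset_geno(gm, loci = loci)
    fr <- if (is.null(freqs)) estimate_allele_freqs(sub) else freqs[[pn]]
    sub <- subset_geno(sub, loci = fr$locus_id)
    G <- sub$calls
    L <- ncol(G)
    min_typed <- ceiling(params$min_typed_frac * L)
    e <- params$mistype_rate
    tab_s <- if (any(modes != "parent_pair")) lod_table_single(fr$p_alt, e) else NULL
    tab_p <- if ("parent_pair" %in% modes) lod_table_pair(fr$p_alt, e) else NULL
    for (i in seq_len(nrow(offspring))) {
      off <- offspring[i, ]
      cc <- dplyr::filter(
        couples,
        .data$colony == off$colony, .data$generation == off$generation - 1L
      )
      cc <- dplyr::arrange(cc, .data$couple_id) # deterministic tie-breaking
      if (nrow(cc) == 0) {
        skipped <- skipped + 1L
        next
      }
      n_typed_off <- sum(!is.na(G[off$id, ]))
      for (md in modes) {
        if (md == "male") {
          sc <- score_candidates(G, off$id, cc$sire, tab_s = tab_s)
          cand_ids <- cc$sire
          truth <- off$sire
        } else if (md == "female") {
          sc <- score_candidates(G, off$id, cc$dam, tab_s = tab_s)
          cand_ids <- cc$dam
          truth <- off$dam
        } else {
          sc <- score_candidates(G, off$id, cc$dam, cc$sire, tab_p = tab_p)
          cand_ids <- cc$couple_id
          truth <- cc$couple_id[match(off$sire, cc$sire)]
        }
        best <- which.max(sc$a_lod)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          panel = pn, mode = md, offspring = off$id,
          candidate = cand_ids[best],
          a_lod = sc$a_lod[best], n_compared = sc$n_compared[best],
          valid = n_typed_off >= min_typed,
          true_candidate = if (length(truth) && !is.na(truth)) truth else NA_character_,
          correct = identical(cand_ids[best], truth)
        )
      }
    }
  }
  if (skipped > 0) warning(skipped, " offspring skipped: empty candidate set")
  out <- dplyr::bind_rows(rows)
  if (!is.null(thresholds)) out <- classify_assignments(out, thresholds)
  out
}

#' Attach confidence classes to assignments
#'
#' Joins simulation-derived critical LOD thresholds onto an assignment
#' table (by `panel` and `mode`; extra threshold columns such as
#' `inbreeding` are carried through, replicating assignments once per
#' threshold set) and classifies each assignment: `strict` when
#' `a_lod >= c_lod_strict`, `relaxed` when `c_lod_relaxed <= a_lod <
#' c_lod_strict`, otherwise unassigned-most-likely (positive A-LOD) or
#' unassigned-not-most-likely. Sentinel thresholds behave naturally:
#' -999 is always met, +999 never. Assignments with too few typed loci
#' (`valid == FALSE`) get class `NA`.
#'
#' @param assignments Tibble from [batch_assign()].
#' @param thresholds Tibble with `panel`, `mode`, `c_lod_relaxed`,
#'   `c_lod_strict` and optional extra key columns.
#' @return The assignment tibble with a `class` column (plus any extra
#'   threshold key columns).
#' @export
classify_assignments <- function(assignments, thresholds) {
  keys <- intersect(c("panel", "mode"), names(thresholds))
  out <- dplyr::left_join(assignments, thresholds,
    by = keys,
    relationship = "many-to-many"
  )
  out$class <- ifelse(
    out$valid,
    classify_assignment(out$a_lod, out$c_lod_relaxed, out$c_lod_strict),
    NA_character_
  )
  dplyr::select(out, -"c_lod_relaxed", -"c_lod_strict")
}

#' Confidence-class summary of assignments
#'
#' Percentage of assignments in each of the four confidence classes,
#' within groups defined by any of `panel`, `mode` and `inbreeding`
#' columns present in the input. Percentages sum to 100 within each group
#' (offspring with an undetermined class, e.g. too few typed loci, are
#' excluded).
#'
#' @param assignments Tibble from [batch_assign()] (with a `class` column).
#' @return A tibble with the grouping columns, `class`, `n` and `pct`.
#' @export
summarize_confidence <- function(assignments) {
  stopifnot(nrow(assignments) > 0, "class" %in% names(assignments))
  keys <- intersect(c("panel", "mode", "inbreeding"), names(assignments))
  df <- dplyr::filter(assignments, !is.na(.data$class))
  df$class <- factor(df$class, levels = confidence_classes)
  df |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$class, .drop = FALSE, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
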