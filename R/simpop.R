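#' Study design configuration
#'
#' Describes the multigeneration full-sib breeding design to simulate:
#' per colony, `n_families` independent family lines; in each family and
#' each breeding round, `n_pairs_per_family` candidate full-sib mating
#' pairs are formed, one of which is retained and sequenced together with
#' `n_larvae_per_pair` of its offspring larvae. The default values give
#' 2 colonies x 12 families x 3 generations x (2 parents + 2 larvae)
#' = 288 sequenced samples.
#'
#' @param n_colonies Number of colonies (default 2).
#' @param n_families Families per colony (default 12).
#' @param n_generations Number of breeding rounds / larval generations
#'   (default 3).
#' @param n_pairs_per_family Candidate mating pairs per family per round
#'   (default 4); the first pair is retained.
#' @param n_larvae_per_pair Offspring larvae sequenced per retained pair
#'   per round (default 2).
#' @param n_loci Number of simulated biallelic loci (default 500).
#' @param maf_low,maf_high Bounds of the founder minor-allele-frequency
#'   interval; MAFs are drawn uniformly in `(maf_low, maf_high]` and must
#'   satisfy `0 < maf_low <= maf_high <= 0.5`.
#'
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_colonies = 2, n_families = 12, n_generations = 3,
                          n_pairs_per_family = 4, n_larvae_per_pair = 2,
                          n_loci = 500, maf_low = 0.05, maf_high = 0.5) {
  counts <- c(
    n_colonies = n_colonies, n_families = n_families,
    n_generations = n_generations, n_pairs_per_family = n_pairs_per_family,
    n_larvae_per_pair = n_larvae_per_pair, n_loci = n_loci
  )
  if (any(counts < 1) || any(counts != as.integer(counts))) {
    stop("all design counts must be integers >= 1", call. = FALSE)
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  structure(
    list(
      n_colonies = as.integer(n_colonies), n_families = as.integer(n_families),
      n_generations = as.integer(n_generations),
      n_pairs_per_family = as.integer(n_pairs_per_family),
      n_larvae_per_pair = as.integer(n_larvae_per_pair),
      n_loci = as.integer(n_loci), maf_low = maf_low, maf_high = maf_high
    ),
    class = "design_config"
  )
}

colony_labels <- function(n) {
  base <- c("ES", "UL")
  if (n <= 2) base[seq_len(n)] else c(base, sprintf("C%02d", 3:n))
}

#' Draw founder allele frequencies and locus metadata
#'
#' Per-locus minor allele frequencies are drawn uniformly in
#' `(maf_low, maf_high]`; which allele (reference or alternate) is the
#' minor one is randomised. Loci are laid out on `n_chrom` chromosome-scale
#' sequences, one SNP per reduced-representation (RAD) locus, with a random
#' position of the SNP within its ~100 bp locus so position-based filters
#' are exercisable.
#'
#' @param n_loci Number of loci.
#' @param maf_low,maf_high MAF interval bounds, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes to spread loci over (default 7).
#'
#' @return A tibble with columns `locus_id`, `chrom`, `pos`, `rad_locus`,
#'   `pos_in_locus`, `ref`, `alt`, `p_alt` (alternate-allele frequency) and
#'   `maf`.
#' @export
sample_founder_frequencies <- function(n_loci, maf_low = 0.05, maf_high = 0.5,
                                       seed = 1, n_chrom = 7) {
  if (!(is.numeric(maf_low) && is.numeric(maf_high) &&
        maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  set.seed(derive_seed(seed, 11L))
  # uniform on (maf_low, maf_high]: runif gives [0, 1), so subtract from the top
  maf <- maf_high - stats::runif(n_loci) * (maf_high - maf_low)
  alt_is_minor <- stats::runif(n_loci) < 0.5
  p_alt <- ifelse(alt_is_minor, maf, 1 - maf)
  pos_in_locus <- sample.int(100L, n_loci, replace = TRUE)
  # loci laid out in blocks along n_chrom chromosomes, one SNP per RAD locus
  chrom_idx <- rep_len(seq_len(n_chrom), n_loci)[order(rep_len(seq_len(n_chrom), n_loci))]
  within_chrom <- stats::ave(seq_len(n_loci), chrom_idx, FUN = seq_along)
  tibble::tibble(
    locus_id = sprintf("snp%05d", seq_len(n_loci)),
    chrom = sprintf("chr%d", chrom_idx),
    rad_locus = sprintf("chr%d_rl%05d", chrom_idx, within_chrom),
    pos_in_locus = pos_in_locus,
    pos = within_chrom * 5000L + pos_in_locus,
    ref = "A",
    alt = "C",
    p_alt = p_alt,
    maf = maf
  )
}

#' Build the experimental pedigree
#'
#' Constructs the full multigeneration pedigree implied by a
#' [design_config()]. In each family, generation-0 founder pairs are
#' unrelated; the first (retained) pair of each breeding round produces the
#' next round's candidate pairs (full sibs) and the sequenced larvae, so
#' family lines are maintained by strict full-sib mating. Sequenced samples
#' are the retained sires and dams of each round plus the larvae; with the
#' default design this set has exactly 288 members.
#'
#' @param config A [design_config()].
#' @param seed Integer seed (the design itself is deterministic; the seed is
#'   recorded for provenance).
#' @return A tibble with one row per individual: `id`, `colony`,
#'   `generation`, `family`, `role` (`"sire"`, `"dam"` or `"larva"`), `pair`,
#'   `sire`, `dam` (parent ids, `NA` for founders), `retained`, `sequenced`.
#' @export
build_design <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  rows <- vector("list", 0L)
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble::tibble(...)
  for (colony in colony_labels(config$n_colonies)) {
    for (f in seq_len(config$n_families)) {
      fam <- sprintf("F%02d", f)
      stem <- function(g, p, r) sprintf("%s_%s_G%d_P%d_%s", colony, fam, g, p, r)
      # generation 0: founder pairs, unrelated
      for (p in seq_len(config$n_pairs_per_family)) {
        add(
          id = c(stem(0L, p, "S"), stem(0L, p, "D")),
          colony = colony, generation = 0L, family = fam,
          role = c("sire", "dam"), pair = p,
          sire = NA_character_, dam = NA_character_,
          retained = p == 1L, sequenced = p == 1L
        )
      }
      for (g in seq_len(config$n_generations)) {
        s_par <- stem(g - 1L, 1L, "S")
        d_par <- stem(g - 1L, 1L, "D")
        # next round's candidate pairs (full sibs of each other)
        if (g < config$n_generations) {
          for (p in seq_len(config$n_pairs_per_family)) {
            add(
              id = c(stem(g, p, "S"), stem(g, p, "D")),
              colony = colony, generation = g, family = fam,
              role = c("sire", "dam"), pair = p,
              sire = s_par, dam = d_par,
              retained = p == 1L, sequenced = p == 1L
            )
          }
        }
        # sequenced larvae of this round
        for (l in seq_len(config$n_larvae_per_pair)) {
          add(
            id = sprintf("%s_%s_G%d_L%d", colony, fam, g, l),
            colony = colony, generation = g, family = fam,
            role = "larva", pair = NA_integer_,
            sire = s_par, dam = d_par,
            retained = FALSE, sequenced = TRUE
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "design_seed") <- seed
  attr(out, "config") <- config
  out
}

#' Wright's inbreeding coefficient from a pedigree
#'
#' Computes F by recursive kinship (coancestry) over the pedigree:
#' F(x) is the kinship between x's parents, with founders assumed
#' unrelated and non-inbred. Equivalent to Wright's path-counting.
#'
#' @param pedigree A pedigree tibble as from [build_design()] (columns
#'   `id`, `sire`, `dam`, `generation`).
#' @param id Character vector of individual ids.
#' @return Numeric vector of inbreeding coefficients.
#' @export
expected_inbreeding <- function(pedigree, id) {
  ids <- pedigree$id
  miss <- setdiff(id, ids)
  if (length(miss)) stop("unknown id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sire <- stats::setNames(pedigree$sire, ids)
  dam <- stats::setNames(pedigree$dam, ids)
  gen <- stats::setNames(pedigree$generation, ids)
  memo <- new.env(parent = emptyenv())
  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (a <= b) paste0(a, "\r", b) else paste0(b, "\r", a)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      0.5 * (1 + kin(sire[[a]], dam[[a]]))
    } else {
      # recurse on the later-generation individual (cannot be the other's
      # descendant's ancestor loop because the pedigree is acyclic by design)
      x <- a
      y <- b
      if (gen[[b]] > gen[[a]]) {
        x <- b
        y <- a
      }
      0.5 * (kin(sire[[x]], y) + kin(dam[[x]], y))
    }
    memo[[key]] <- val
    val
  }
  unname(vapply(id, function(i) kin(sire[[i]], dam[[i]]), numeric(1)))
}

#' Drop error-free genotypes down a pedigree
#'
#' Founders receive genotypes drawn under Hardy-Weinberg proportions from
#' the supplied allele frequencies; every non-founder receives one
#' uniformly random allele from each parent at each locus (Mendelian
#' transmission).
#'
#' @param pedigree Pedigree tibble from [build_design()].
#' @param freqs Locus tibble from [sample_founder_frequencies()] (needs
#'   `locus_id` and `p_alt`).
#' @param seed Integer seed.
#' @return A [geno_matrix()] of true genotypes for all pedigree members.
#' @export
drop_genotypes <- function(pedigree, freqs, seed = 1) {
  set.seed(derive_seed(seed, 23L))
  p <- freqs$p_alt
  L <- length(p)
  n <- nrow(pedigree)
  G <- matrix(NA_integer_, n, L, dimnames = list(pedigree$id, freqs$locus_id))
  row_of <- stats::setNames(seq_len(n), pedigree$id)
  ord <- order(pedigree$generation)
  for (i in ord) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) {
      G[i, ] <- stats::rbinom(L, 2L, p)
    } else {
      if (is.na(s) || is.na(d) || !(s %in% names(row_of)) || !(d %in% names(row_of))) {
        stop("unresolved parent link for ", pedigree$id[i], call. = FALSE)
      }
      a1 <- stats::rbinom(L, 1L, G[row_of[[s]], ] / 2)
      a2 <- stats::rbinom(L, 1L, G[row_of[[d]], ] / 2)
      G[i, ] <- a1 + a2
    }
  }
  samples <- dplyr::rename(pedigree, sample_id = "id")
  geno_matrix(G, samples, freqs)
}

#' Genotyping error model
#'
#' @param mistype_rate Probability that a call is replaced by a random
#'   Hardy-Weinberg genotype at that locus (default 0.05).
#' @param missing_rate Probability that a call is set missing (default 0.05).
#' @param depth_mean Optional grand-mean read depth; when given, per-call
#'   depths are simulated as Poisson draws around marker-level means that
#'   vary lognormally across markers (reduced-representation loci differ
#'   systematically in coverage), with depth 0 for missing calls.
#' @param depth_log_sd Standard deviation of the marker-level log-mean
#'   depth (default 0.3).
#' @return A list of class `error_model`.
#' @export
error_model <- function(mistype_rate = 0.05, missing_rate = 0.05,
                        depth_mean = NULL, depth_log_sd = 0.3) {
  check_prob(mistype_rate, "mistype_rate", allow_one = FALSE)
  check_prob(missing_rate, "missing_rate", allow_one = FALSE)
  structure(
    list(
      mistype_rate = mistype_rate, missing_rate = missing_rate,
      depth_mean = depth_mean, depth_log_sd = depth_log_sd
    ),
    class = "error_model"
  )
}

#' Apply genotyping errors and missingness to a true genotype matrix
#'
#' Each call is independently replaced, with probability `mistype_rate`, by
#' a genotype drawn from Hardy-Weinberg proportions at that locus, and
#' independently set missing with probability `missing_rate`. When the
#' error model carries a depth model, per-call depths are simulated.
#'
#' @param truth A [geno_matrix()] of true genotypes.
#' @param model An [error_model()].
#' @param freqs Optional locus tibble with `p_alt`; defaults to
#'   `truth$loci`.
#' @param seed Integer seed.
#' @return A corrupted [geno_matrix()].
#' @export
corrupt <- function(truth, model = error_model(), freqs = NULL, seed = 1) {
  stopifnot(inherits(truth, "geno_matrix"), inherits(model, "error_model"))
  loci <- freqs %||% truth$loci
  if (nrow(loci) != ncol(truth$calls)) stop("freqs do not match matrix loci", call. = FALSE)
  set.seed(derive_seed(seed, 37L))
  G <- truth$calls
  nm <- length(G)
  p_cell <- rep(loci$p_alt, each = nrow(G))
  if (model$mistype_rate > 0) {
    hit <- stats::runif(nm) < model$mistype_rate
    G[hit] <- stats::rbinom(sum(hit), 2L, p_cell[hit])
  }
  if (model$missing_rate > 0) {
    G[stats::runif(nm) < model$missing_rate] <- NA_integer_
  }
  depth <- NULL
  if (!is.null(model$depth_mean)) {
    mu <- stats::rlnorm(
      ncol(G),
      log(model$depth_mean) - model$depth_log_sd^2 / 2, model$depth_log_sd
    )
    depth <- matrix(stats::rpois(nm, rep(mu, each = nrow(G))), nrow(G), ncol(G))
    depth[is.na(G)] <- 0
  }
  geno_matrix(G, truth$samples, truth$loci, depth = depth)
}

#' Subsample the simulated design to the post-QC study size
#'
#' The sequencing study retained, after quality control, 47 mated couples
#' (19 and 28 from the two colonies) and 75 offspring larvae (23 and 52).
#' This helper reproduces those counts from a simulated pedigree by seeded
#' subsampling of retained couples and of sequenced larvae whose parent
#' couple was kept, so every retained larva has its true parents among the
#' candidate couples.
#'
#' @param pedigree Pedigree tibble from [build_design()].
#' @param n_couples Named integer vector: couples to keep per colony
#'   (default `c(ES = 19, UL = 28)`).
#' @param n_larvae Named integer vector: larvae to keep per colony
#'   (default `c(ES = 23, UL = 52)`).
#' @param seed Integer seed.
#' @return A list with tibbles `couples` (`couple_id`, `sire`, `dam`,
#'   `colony`, `generation` of the parents) and `larvae` (pedigree rows of
#'   the kept larvae).
#' @export
subsample_to_study <- function(pedigree, n_couples = c(ES = 19, UL = 28),
                               n_larvae = c(ES = 23, UL = 52), seed = 1) {
  set.seed(derive_seed(seed, 53L))
  retained <- dplyr::filter(pedigree, .data$retained, .data$role == "sire")
  couples <- tibble::tibble(
    couple_id = sub("_S$", "", retained$id),
    sire = retained$id,
    dam = sub("_S$", "_D", retained$id),
    colony = retained$colony,
    generation = retained$generation,
    family = retained$family
  )
  larvae <- dplyr::filter(pedigree, .data$role == "larva", .data$sequenced)
  keep_c <- list()
  keep_l <- list()
  for (col in names(n_couples)) {
    cc <- dplyr::filter(couples, .data$colony == col)
    if (nrow(cc) < n_couples[[col]]) stop("not enough couples in colony ", col, call. = FALSE)
    cc <- cc[sort(sample.int(nrow(cc), n_couples[[col]])), ]
    keep_c[[col]] <- cc
    ll <- dplyr::filter(larvae, .data$colony == col, .data$sire %in% cc$sire)
    if (nrow(ll) < n_larvae[[col]]) stop("not enough eligible larvae in colony ", col, call. = FALSE)
    keep_l[[col]] <- ll[sort(sample.int(nrow(ll), n_larvae[[col]])), ]
  }
  list(couples = dplyr::bind_rows(keep_c), larvae = dplyr::bind_rows(keep_l))
}
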