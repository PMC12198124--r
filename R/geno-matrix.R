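#' Genotype matrix container
#'
#' A `geno_matrix` bundles a samples-by-loci matrix of biallelic genotype
#' calls (coded as the dosage of the alternate allele: 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing)
#' with a samples metadata tibble and a loci metadata tibble, plus an
#' optional read-depth matrix of the same shape.
#'
#' @param calls Integer matrix, samples in rows and loci in columns, values
#'   in `{0, 1, 2, NA}`. Row and column names must match `samples$sample_id`
#'   and `loci$locus_id`.
#' @param samples Tibble with at least a `sample_id` column; typically also
#'   `colony`, `generation`, `family`, `role`, `sire`, `dam`, `sequenced`.
#' @param loci Tibble with at least a `locus_id` column; typically also
#'   `chrom`, `pos`, `rad_locus`, `pos_in_locus`, `ref`, `alt`.
#' @param depth Optional numeric matrix of per-call read depths, same
#'   dimensions and dimnames as `calls`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, samples, loci, depth = NULL) {
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  loci <- tibble::as_tibble(loci)
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column", call. = FALSE)
  if (!"locus_id" %in% names(loci)) stop("loci needs a locus_id column", call. = FALSE)
  if (nrow(samples) != nrow(calls) || nrow(loci) != ncol(calls)) {
    stop("dimensions of calls do not match samples/loci tables", call. = FALSE)
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- loci$locus_id
  if (!is.null(depth)) {
    stopifnot(all(dim(depth) == dim(calls)))
    dimnames(depth) <- dimnames(calls)
  }
  structure(
    list(calls = calls, samples = samples, loci = loci, depth = depth),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d loci (%.1f%% missing%s)\n",
    nrow(x$calls), ncol(x$calls),
    100 * mean(is.na(x$calls)),
    if (is.null(x$depth)) "" else ", with depth"
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm A [geno_matrix()].
#' @param samples,loci Character vectors of ids (or logical/integer indices)
#'   to keep; `NULL` keeps everything.
#' @return A `geno_matrix` restricted to the requested samples and loci.
#' @export
subset_geno <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(gm$calls)) else index_of(samples, gm$samples$sample_id, "sample")
  li <- if (is.null(loci)) seq_len(ncol(gm$calls)) else index_of(loci, gm$loci$locus_id, "locus")
  geno_matrix(
    gm$calls[si, li, drop = FALSE],
    gm$samples[si, , drop = FALSE],
    gm$loci[li, , drop = FALSE],
    depth = if (is.null(gm$depth)) NULL else gm$depth[si, li, drop = FALSE]
  )
}

index_of <- function(keys, ids, what) {
  if (is.logical(keys) || is.numeric(keys)) return(seq_along(ids)[keys])
  i <- match(keys, ids)
  if (anyNA(i)) stop("unknown ", what, " id(s): ", paste(keys[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Convert a genotype matrix to a long tibble
#'
#' One row per (sample, locus) call; convenient for dplyr/ggplot2 work.
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with columns `sample_id`, `locus_id`, `call` and,
#'   when depths are present, `depth`.
#' @export
geno_tidy <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  out <- tibble::tibble(
    sample_id = rep(rownames(gm$calls), times = ncol(gm$calls)),
    locus_id = rep(colnames(gm$calls), each = nrow(gm$calls)),
    call = as.integer(gm$calls)
  )
  if (!is.null(gm$depth)) out$depth <- as.numeric(gm$depth)
  out
}
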