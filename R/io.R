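#' Write a genotype matrix as VCF v4.2
#'
#' Emits an uncompressed VCF v4.2 text file with contig header lines, one
#' biallelic SNP record per locus, and `GT` (plus `DP` when depths are
#' present) sample fields. Positions are 1-based as required by VCF.
#'
#' @param gm A [geno_matrix()] whose loci carry `chrom`, `pos`, `ref`, `alt`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  li <- gm$loci
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(li))) stop("loci need columns: ", paste(need, collapse = ", "), call. = FALSE)
  contigs <- vapply(
    split(li$pos, li$chrom),
    function(p) max(p) + 1000L, numeric(1)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsfparentage",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(gm$depth)) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      rownames(gm$calls)
    ), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  fmt <- if (is.null(gm$depth)) "GT" else "GT:DP"
  body <- vapply(seq_len(nrow(li)), function(j) {
    g <- gm$calls[, j]
    cell <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    if (!is.null(gm$depth)) cell <- paste0(cell, ":", as.integer(gm$depth[, j]))
    paste(c(
      li$chrom[j], li$pos[j], li$locus_id[j], li$ref[j], li$alt[j],
      ".", "PASS", ".", fmt, cell
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF or PED/MAP
#'
#' VCF files are parsed with vcfR; only biallelic SNP records are kept
#' (others are skipped with a message). Genotypes are coded as
#' alternate-allele dosage 0/1/2 with `NA` for missing; `DP` is read into
#' the depth matrix when present.
#'
#' @param path VCF path, or the `.ped` path for PED/MAP input.
#' @param format `"vcf"` or `"pedmap"`.
#' @param pedigree Optional sample-metadata tibble (with `id` or
#'   `sample_id`) joined onto the samples table.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "pedmap"), pedigree = NULL) {
  format <- match.arg(format)
  gm <- if (format == "vcf") read_vcf_impl(path) else read_ped_map(path)
  if (!is.null(pedigree)) {
    meta <- tibble::as_tibble(pedigree)
    if ("id" %in% names(meta) && !"sample_id" %in% names(meta)) {
      meta <- dplyr::rename(meta, sample_id = "id")
    }
    gm$samples <- dplyr::left_join(gm$samples, meta, by = "sample_id")
  }
  gm
}

read_vcf_impl <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snp)) {
    message(sum(!snp), " non-biallelic/non-SNP record(s) skipped")
    v <- v[snp, ]
    fix <- fix[snp, ]
  }
  gt <- vcfR::extract.gt(v)
  g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g[gt %in% c("0/0", "0|0")] <- 0L
  g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  g[gt %in% c("1/1", "1|1")] <- 2L
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    depth <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  geno_matrix(
    t(g),
    samples = tibble::tibble(sample_id = colnames(gt)),
    loci = tibble::tibble(
      locus_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    ),
    depth = depth
  )
}

#' Write a genotype matrix as PED/MAP text
#'
#' Alleles are recoded 1 (reference) / 2 (alternate); missing calls are
#' written as `0 0`. Family, parent and sex fields are filled from the
#' samples table when available.
#'
#' @param gm A [geno_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_ped_map <- function(gm, prefix) {
  stopifnot(inherits(gm, "geno_matrix"))
  li <- gm$loci
  map <- data.frame(
    chrom = li$chrom %||% "0",
    id = li$locus_id,
    cm = 0,
    pos = li$pos %||% seq_len(nrow(li))
  )
  utils::write.table(map, paste0(prefix, ".map"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  sm <- gm$samples
  fid <- if (all(c("colony", "family") %in% names(sm))) paste(sm$colony, sm$family, sep = "_") else rep("0", nrow(sm))
  pat <- if ("sire" %in% names(sm)) ifelse(is.na(sm$sire), "0", sm$sire) else rep("0", nrow(sm))
  mat <- if ("dam" %in% names(sm)) ifelse(is.na(sm$dam), "0", sm$dam) else rep("0", nrow(sm))
  sex <- if ("role" %in% names(sm)) c(sire = 1L, dam = 2L, larva = 0L)[sm$role] else rep(0L, nrow(sm))
  allele_strings <- c("1 1", "1 2", "2 2")
  geno_txt <- apply(gm$calls, 1, function(g) {
    paste(ifelse(is.na(g), "0 0", allele_strings[g + 1L]), collapse = " ")
  })
  lines <- paste(fid, sm$sample_id, pat, mat, sex, -9, geno_txt)
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PED/MAP text genotypes
#'
#' @param path Path to the `.ped` file (the `.map` is looked up next to it)
#'   or a prefix without extension.
#' @return A [geno_matrix()].
#' @export
read_ped_map <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  map <- utils::read.table(paste0(prefix, ".map"),
    sep = "\t",
    col.names = c("chrom", "locus_id", "cm", "pos"),
    colClasses = c("character", "character", "numeric", "integer")
  )
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  L <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * L)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(L) - 1])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(L)])
  g <- (a1 == "2") + (a2 == "2")
  g[a1 == "0" | a2 == "0"] <- NA
  storage.mode(g) <- "integer"
  samples <- tibble::tibble(
    sample_id = ped[[2]],
    family = ped[[1]],
    sire = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    dam = ifelse(ped[[4]] == "0", NA_character_, ped[[4]])
  )
  geno_matrix(
    g, samples,
    tibble::tibble(
      locus_id = map$locus_id, chrom = map$chrom, pos = map$pos,
      ref = "A", alt = "C"
    )
  )
}

#' Write the pedigree table as CSV
#'
#' One row per individual with colony, generation, family, role, parent
#' links and the pedigree inbreeding coefficient F.
#'
#' @param pedigree Pedigree tibble from [build_design()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  out <- dplyr::mutate(pedigree, F = expected_inbreeding(pedigree, .data$id))
  readr::write_csv(out, path)
  invisible(path)
}
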