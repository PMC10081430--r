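#' Cohort variant container
#'
#' An annotated, biallelic (post-decomposition) set of variant sites together
#' with per-sample genotype calls. This is the internal data model every
#' scoring, QC and prioritization step operates on.
#'
#' @param tab data.frame with one row per biallelic variant and columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `cadd_phred`, `pop_af`,
#'   `coding_distance`, `mane_coding` (logical), `clinvar`, `acmg`,
#'   `callset_af`.
#' @param gene_ids list of character vectors, one per variant row: the gene
#'   symbols whose regions the variant overlaps.
#' @param dosage,depth,gq integer matrices (variants x samples); `dosage` is
#'   the alternate-allele count in 0/1/2 with `NA` for missing calls.
#' @param samples character vector of sample identifiers (column order of the
#'   genotype matrices).
#'
#' @return An object of class `genepy_variants`.
#' @export
genepy_variants <- function(tab, gene_ids, dosage, depth, gq, samples) {
  stopifnot(is.data.frame(tab), nrow(tab) == length(gene_ids))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids in genotype matrix")
  for (m in list(dosage, depth, gq)) {
    stopifnot(is.matrix(m), nrow(m) == nrow(tab), ncol(m) == length(samples))
  }
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  with_nm <- function(m) { dimnames(m) <- list(NULL, samples); m }
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  if (any(tab$pos < 1L)) stop("positions must be >= 1")
  ok_af <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok_af(tab$pop_af)) stop("pop_af outside [0, 1]")
  if (!ok_af(tab$callset_af)) stop("callset_af outside [0, 1]")
  if (any(tab$cadd_phred < 0, na.rm = TRUE)) stop("cadd_phred must be >= 0")
  structure(
    list(tab = tab, gene_ids = gene_ids, dosage = with_nm(dosage),
         depth = with_nm(depth), gq = with_nm(gq), samples = samples),
    class = "genepy_variants"
  )
}

#' @export
print.genepy_variants <- function(x, ...) {
  cat(sprintf("<genepy_variants> %d variants x %d samples\n",
              nrow(x$tab), length(x$samples)))
  genes <- unique(unlist(x$gene_ids))
  cat(sprintf("  genes overlapped: %d; CADD range: %s\n", length(genes),
              paste(signif(range(x$tab$cadd_phred, na.rm = TRUE), 4),
                    collapse = "-")))
  invisible(x)
}

#' @export
dim.genepy_variants <- function(x) c(nrow(x$tab), length(x$samples))

#' Subset a variant container by row
#' @param v `genepy_variants` object.
#' @param i row (variant) index.
#' @return A `genepy_variants` with the selected variant rows.
#' @export
subset_variants <- function(v, i) {
  genepy_variants(v$tab[i, , drop = FALSE], v$gene_ids[i],
                  v$dosage[i, , drop = FALSE], v$depth[i, , drop = FALSE],
                  v$gq[i, , drop = FALSE], v$samples)
}

variant_key <- function(tab) {
  paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
}

CLINVAR_LEVELS <- c("P", "LP", "VUS", "LB", "B", "conflicting", "absent")

normalize_clinvar <- function(x) {
  x <- toupper(as.character(x))
  out <- rep("absent", length(x))
  out[x %in% c("P", "PATHOGENIC")] <- "P"
  out[x %in% c("LP", "LIKELY_PATHOGENIC")] <- "LP"
  out[x == "VUS"] <- "VUS"
  out[x %in% c("LB", "LIKELY_BENIGN")] <- "LB"
  out[x %in% c("B", "BENIGN")] <- "B"
  out[x == "CONFLICTING"] <- "conflicting"
  out
}

## Take per-alt entries out of an INFO field that may be declared Number=1
## (recycled across alts) or Number=A/. (per-alt list). `rec_idx`/`alt_j`
## index the decomposed biallelic rows back into the VCF records.
info_for_alts <- function(field, rec_idx, alt_j) {
  if (is.null(field)) return(rep(NA, length(rec_idx)))
  listy <- is.list(field) || methods::is(field, "List")
  if (listy) field <- as.list(field)
  sapply(seq_along(rec_idx), function(r) {
    x <- if (listy) field[[rec_idx[r]]] else field[rec_idx[r]]
    if (length(x) == 0L || all(is.na(x))) NA else x[[min(alt_j[r], length(x))]]
  })
}

#' Read a multi-sample cohort VCF restricted to gene regions
#'
#' Reads a VCF (v4.2+) with per-genotype `DP`/`GQ` and the annotation INFO
#' fields `CADD_PHRED`, `POP_AF`, `GENE`, `CODING_DIST`, `MANE_CODING` and
#' `CLINVAR` (optionally `ACMG`). Multi-allelic records are decomposed into
#' one biallelic variant per alternate allele; variants that overlap none of
#' the supplied gene regions are dropped and `gene_ids` is assigned by
#' interval overlap with the regions (not the GENE tag, which is advisory).
#'
#' Records whose annotations cannot be parsed (e.g. a negative CADD) are
#' skipped with a warning; the number skipped is available as
#' `attr(x, "n_skipped")`.
#'
#' @param path path to the VCF file (plain text or bgzip).
#' @param gene_regions `GRanges` of gene regions as returned by
#'   [read_gene_regions()].
#' @param hemizygous `"hom"` (default) scores haploid calls (e.g. chrX in
#'   males) as homozygous-equivalent dosage 2; `"het"` scores them as
#'   dosage 1.
#' @return A [genepy_variants] object. `callset_af` is initialized from the
#'   raw genotypes and is recomputed by [apply_site_qc()].
#' @export
read_cohort_vcf <- function(path, gene_regions, hemizygous = c("hom", "het")) {
  hemizygous <- match.arg(hemizygous)
  stopifnot(file.exists(path))
  vcf <- VariantAnnotation::readVcf(path)
  gmat <- VariantAnnotation::geno(vcf)
  for (f in c("GT", "DP", "GQ")) {
    if (!f %in% names(gmat)) {
      stop(sprintf("required FORMAT field '%s' is missing from %s", f, path))
    }
  }
  samples <- colnames(gmat$GT)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alts)

  ## decomposition index: one biallelic row per (record, alt)
  rec_idx <- rep(seq_along(n_alt), n_alt)
  alt_j <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  ## genotype dosage per alt, via a lookup over unique GT strings
  gt <- gmat$GT
  u <- unique(as.vector(gt))
  spl <- strsplit(u, "[/|]")
  uidx <- matrix(match(gt, u), nrow(gt), ncol(gt))
  hemi_mult <- if (hemizygous == "hom") 2L else 1L
  lookup <- lapply(seq_len(max(alt_j)), function(j) {
    vapply(spl, function(a) {
      if (length(a) == 0L || any(a == ".")) return(NA_integer_)
      d <- sum(a == as.character(j))
      if (length(a) == 1L) min(d * hemi_mult, 2L) else d
    }, integer(1))
  })
  dosage <- matrix(NA_integer_, length(rec_idx), ncol(gt))
  for (r in seq_along(rec_idx)) {
    dosage[r, ] <- lookup[[alt_j[r]]][uidx[rec_idx[r], ]]
  }
  as_int <- function(m) { mode(m) <- "integer"; m }
  depth <- as_int(gmat$DP[rec_idx, , drop = FALSE])
  gq <- as_int(gmat$GQ[rec_idx, , drop = FALSE])

  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[rec_idx],
    pos = GenomicRanges::start(rr)[rec_idx],
    ref = as.character(VariantAnnotation::ref(vcf))[rec_idx],
    alt = unlist(lapply(alts, as.character), use.names = FALSE),
    cadd_phred = suppressWarnings(
      as.numeric(info_for_alts(info$CADD_PHRED, rec_idx, alt_j))),
    pop_af = suppressWarnings(
      as.numeric(info_for_alts(info$POP_AF, rec_idx, alt_j))),
    coding_distance = suppressWarnings(
      as.integer(info_for_alts(info$CODING_DIST, rec_idx, alt_j))),
    stringsAsFactors = FALSE)
  mane <- info_for_alts(info$MANE_CODING, rec_idx, alt_j)
  tab$mane_coding <- if (is.logical(mane)) !is.na(mane) & mane
    else !is.na(suppressWarnings(as.integer(mane))) &
      suppressWarnings(as.integer(mane)) == 1L
  tab$clinvar <- normalize_clinvar(info_for_alts(info$CLINVAR, rec_idx, alt_j))
  tab$acmg <- normalize_clinvar(info_for_alts(info$ACMG, rec_idx, alt_j))

  bad <- (!is.na(tab$cadd_phred) & tab$cadd_phred < 0) |
    (!is.na(tab$pop_af) & (tab$pop_af < 0 | tab$pop_af > 1))
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d variant record(s) with malformed annotations",
                    n_skipped))
    tab <- tab[!bad, , drop = FALSE]
    dosage <- dosage[!bad, , drop = FALSE]
    depth <- depth[!bad, , drop = FALSE]
    gq <- gq[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no parseable variant records in ", path)

  vr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$pos, tab$pos + nchar(tab$ref) - 1L))
  hits <- GenomicRanges::findOverlaps(vr, gene_regions)
  gene_ids <- rep(list(character(0)), nrow(tab))
  if (length(hits) > 0L) {
    sp <- split(gene_regions$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    gene_ids[as.integer(names(sp))] <- lapply(sp, function(g) sort(unique(g)))
  }
  keep <- lengths(gene_ids) > 0L
  tab <- tab[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]
  dosage <- dosage[keep, , drop = FALSE]
  depth <- depth[keep, , drop = FALSE]
  gq <- gq[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no variants overlap the supplied gene regions")

  tab$callset_af <- compute_callset_af(dosage)
  rownames(tab) <- NULL
  out <- genepy_variants(tab, gene_ids, dosage, depth, gq, samples)
  attr(out, "n_skipped") <- n_skipped
  out
}

compute_callset_af <- function(dosage) {
  n_called <- rowSums(!is.na(dosage))
  af <- rowSums(dosage, na.rm = TRUE) / (2 * n_called)
  af[n_called == 0L] <- NA_real_
  af
}
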