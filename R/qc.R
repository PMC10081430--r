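#' Genotype-level quality control
#'
#' Sets to missing any genotype call with read depth below `min_depth` or
#' genotype quality below `min_gq` (both thresholds inclusive: a call at
#' exactly the minimum is retained). Genotypes whose DP or GQ is itself
#' missing are set to missing. The transformation is pure and idempotent.
#'
#' @param v `genepy_variants` object.
#' @param min_depth minimum read depth to keep a call (default 10).
#' @param min_gq minimum genotype quality to keep a call (default 20).
#' @return The container with failing genotypes set to `NA`.
#' @export
apply_genotype_qc <- function(v, min_depth = 10, min_gq = 20) {
  stopifnot(inherits(v, "genepy_variants"))
  fail <- is.na(v$depth) | is.na(v$gq) | v$depth < min_depth | v$gq < min_gq
  v$dosage[fail] <- NA_integer_
  attr(v, "genotype_qc") <- list(min_depth = min_depth, min_gq = min_gq)
  v
}

#' Site-level quality control predicate
#'
#' A site passes when the mean GQ over its non-missing genotypes is strictly
#' greater than `min_mean_gq` and the fraction of non-missing genotypes
#' (call rate) is at least `min_call_rate`. Genotypes already removed by
#' [apply_genotype_qc()] count as not genotyped for both statistics. A site
#' with zero non-missing genotypes fails.
#'
#' @param v `genepy_variants` object, after genotype-level QC.
#' @param min_mean_gq mean-GQ threshold, strict inequality (default 35).
#' @param min_call_rate minimum fraction genotyped, inclusive (default 0.70).
#' @return Logical vector, one element per variant row.
#' @export
site_passes_qc <- function(v, min_mean_gq = 35, min_call_rate = 0.70) {
  stopifnot(inherits(v, "genepy_variants"))
  called <- !is.na(v$dosage)
  n_called <- rowSums(called)
  gq <- v$gq
  gq[!called] <- NA_integer_
  mean_gq <- rowMeans(gq, na.rm = TRUE)
  pass <- n_called > 0L &
    mean_gq > min_mean_gq &
    (n_called / length(v$samples)) >= min_call_rate
  if (any(n_called == 0L)) {
    message(sprintf("%d site(s) with zero non-missing genotypes failed site QC",
                    sum(n_called == 0L)))
  }
  unname(pass)
}

#' Apply site-level QC and refresh within-callset allele frequencies
#'
#' Drops sites failing [site_passes_qc()] and recomputes `callset_af` from
#' the genotypes retained after genotype-level QC.
#'
#' @inheritParams site_passes_qc
#' @return A filtered `genepy_variants` object.
#' @export
apply_site_qc <- function(v, min_mean_gq = 35, min_call_rate = 0.70) {
  keep <- site_passes_qc(v, min_mean_gq = min_mean_gq,
                         min_call_rate = min_call_rate)
  out <- subset_variants(v, which(keep))
  out$tab$callset_af <- compute_callset_af(out$dosage)
  out
}

#' Select variants eligible for scoring
#'
#' A variant enters the score when it is coding or near-coding
#' (`coding_distance <= max_coding_distance`, on the most favorable
#' transcript) and its CADD phred score is at least `min_cadd`; both
#' thresholds are inclusive. Variants with no CADD annotation are excluded
#' conservatively with a warning.
#'
#' @param v `genepy_variants` object.
#' @param max_coding_distance maximum distance (bp) from coding sequence
#'   (default 8).
#' @param min_cadd minimum CADD phred score (default 15).
#' @return Logical vector, one element per variant row.
#' @export
select_scoring_variant <- function(v, max_coding_distance = 8, min_cadd = 15) {
  stopifnot(inherits(v, "genepy_variants"))
  cadd <- v$tab$cadd_phred
  if (anyNA(cadd)) {
    warning(sprintf("%d variant(s) without a CADD score excluded from scoring",
                    sum(is.na(cadd))))
  }
  cdist <- v$tab$coding_distance
  out <- !is.na(cadd) & cadd >= min_cadd &
    !is.na(cdist) & cdist <= max_coding_distance
  unname(out)
}
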