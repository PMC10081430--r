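#' Deleteriousness model for the per-variant weight D
#'
#' The GenePy statistic weights each variant by a deleteriousness metric D.
#' CADD phred scores are used here; in the default `normalized_phred` mode
#' D = min(cadd / scale, 1), mapping phred scores onto \[0, 1\] (scale 99 is
#' the ceiling of the phred scale). `raw_phred` uses the score unchanged.
#' The normalization choice is a modelling convention, not part of the
#' statistic's definition, and is deliberately explicit and swappable.
#'
#' @param mode `"normalized_phred"` (default) or `"raw_phred"`.
#' @param scale positive divisor for normalized mode (default 99).
#' @return An object of class `deleteriousness_model`.
#' @export
deleteriousness_model <- function(mode = c("normalized_phred", "raw_phred"),
                                  scale = 99) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(scale), scale > 0)
  structure(list(mode = mode, scale = scale), class = "deleteriousness_model")
}

#' Map a CADD phred score to the deleteriousness weight D
#'
#' @param cadd_phred numeric vector of CADD phred scores (>= 0).
#' @param model a [deleteriousness_model()].
#' @return D, numeric vector; in normalized mode D lies in \[0, 1\].
#' @export
deleteriousness <- function(cadd_phred, model = deleteriousness_model()) {
  stopifnot(inherits(model, "deleteriousness_model"))
  if (any(cadd_phred < 0, na.rm = TRUE)) stop("cadd_phred must be >= 0")
  switch(model$mode,
         normalized_phred = pmin(cadd_phred / model$scale, 1),
         raw_phred = cadd_phred)
}

#' Allele-frequency policy
#'
#' Where the per-variant allele frequencies f come from and how zero or
#' missing frequencies are handled. Frequencies are taken from the first
#' non-missing source in `source_priority` (columns of the variant table,
#' e.g. gnomAD-style `pop_af`), optionally falling back to the within-callset
#' frequency, and finally to `floor`. All frequencies are clamped to
#' \[floor, 1\] so that -log10 never diverges; the reference-allele
#' frequency 1 - f is floored the same way.
#'
#' @param floor small positive frequency assigned to unobserved alleles
#'   (default 1e-5, roughly one allele in a large reference panel).
#' @param source_priority ordered character vector of frequency columns.
#' @param fallback_to_callset use `callset_af` when all sources are missing?
#' @return An object of class `frequency_policy`.
#' @export
frequency_policy <- function(floor = 1e-5, source_priority = "pop_af",
                             fallback_to_callset = FALSE) {
  stopifnot(is.numeric(floor), floor > 0, floor < 1)
  structure(list(floor = floor, source_priority = source_priority,
                 fallback_to_callset = fallback_to_callset),
            class = "frequency_policy")
}

#' Resolve alternate/reference allele frequencies for scoring
#'
#' @param v `genepy_variants` object.
#' @param policy a [frequency_policy()].
#' @return data.frame with columns `f_alt`, `f_ref`, one row per variant;
#'   both in \[floor, 1\].
#' @export
allele_frequencies <- function(v, policy = frequency_policy()) {
  stopifnot(inherits(v, "genepy_variants"), inherits(policy, "frequency_policy"))
  f <- rep(NA_real_, nrow(v$tab))
  for (src in policy$source_priority) {
    if (!src %in% names(v$tab)) next
    take <- is.na(f) & !is.na(v$tab[[src]])
    f[take] <- v$tab[[src]][take]
  }
  if (policy$fallback_to_callset) {
    take <- is.na(f) & !is.na(v$tab$callset_af)
    f[take] <- v$tab$callset_af[take]
  }
  f[is.na(f)] <- policy$floor
  f_alt <- pmin(pmax(f, policy$floor), 1)
  f_ref <- pmax(1 - f_alt, policy$floor)
  data.frame(f_alt = f_alt, f_ref = f_ref)
}

#' Per-variant, per-individual GenePy score
#'
#' The score of one variant in one individual is
#' \deqn{s = -D \log_{10}(f_1 f_2)}
#' where f1, f2 are the frequencies of the individual's two alleles at the
#' site: a homozygous-reference call (dosage 0) scores 0, a heterozygote
#' (dosage 1) uses f_ref * f_alt, and a homozygote (dosage 2) uses
#' f_alt^2 — the zygosity weighting under which a homozygote scores two
#' "points" and a heterozygote one. Missing dosages contribute 0 (a missing
#' call cannot add pathogenicity burden).
#'
#' @param D deleteriousness weight(s), >= 0.
#' @param f_alt,f_ref alternate/reference allele frequencies in (0, 1].
#' @param dosage alternate-allele count, 0/1/2 (NA allowed, scores 0).
#' @return Nonnegative numeric score(s).
#' @export
variant_score <- function(D, f_alt, f_ref, dosage) {
  if (any(D < 0, na.rm = TRUE)) stop("D must be >= 0")
  if (any(f_alt <= 0 | f_alt > 1 | f_ref <= 0 | f_ref > 1)) {
    stop("allele frequencies must lie in (0, 1]; apply a frequency_policy first")
  }
  n <- max(length(D), length(f_alt), length(f_ref), length(dosage))
  D <- rep_len(D, n); f_alt <- rep_len(f_alt, n)
  f_ref <- rep_len(f_ref, n); dosage <- rep_len(dosage, n)
  s <- numeric(n)
  het <- !is.na(dosage) & dosage == 1L
  hom <- !is.na(dosage) & dosage == 2L
  s[het] <- D[het] * -log10(f_ref[het] * f_alt[het])
  s[hom] <- D[hom] * -log10(f_alt[hom] * f_alt[hom])
  s
}

#' Aggregate a sample's variant scores over one gene
#'
#' GenePy is additive across the qualifying variants of a gene: the gene
#' score is the sum of [variant_score()] over the sample's dosages at those
#' variants. An empty variant set scores 0.
#'
#' @param sample_id sample to score.
#' @param gene_id gene whose variants to aggregate.
#' @param v `genepy_variants` with QC and scoring selection already applied.
#' @param model a [deleteriousness_model()].
#' @param policy a [frequency_policy()].
#' @return A single nonnegative number.
#' @export
gene_score <- function(sample_id, gene_id, v,
                       model = deleteriousness_model(),
                       policy = frequency_policy()) {
  stopifnot(sample_id %in% v$samples)
  rows <- which(vapply(v$gene_ids, function(g) gene_id %in% g, logical(1)))
  if (length(rows) == 0L) return(0)
  fr <- allele_frequencies(subset_variants(v, rows), policy)
  D <- deleteriousness(v$tab$cadd_phred[rows], model)
  sum(variant_score(D, fr$f_alt, fr$f_ref, v$dosage[rows, sample_id]))
}

#' Fit the GenePy score matrix for a cohort
#'
#' The central computation: for every sample and every gene, sum the
#' per-variant scores -D * log10(f1 * f2) over the sample's qualifying
#' variants in that gene, producing the dense samples x genes score matrix
#' on which all ranking and triage is based. QC
#' ([apply_genotype_qc()], [apply_site_qc()]) and scoring selection
#' ([select_scoring_variant()]) are expected to have been applied already;
#' `genepy()` only aggregates.
#'
#' @param v `genepy_variants`, filtered and selected for scoring.
#' @param genes character vector of gene ids defining the matrix columns
#'   (default: all genes seen in `v`, sorted). Genes without qualifying
#'   variants yield an all-zero column.
#' @param samples sample ids defining the rows (default: all samples in `v`).
#' @param model a [deleteriousness_model()].
#' @param policy a [frequency_policy()].
#' @return An object of class `genepy_matrix`; use [as.matrix()] to obtain
#'   the numeric samples x genes matrix.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_samples = 40, n_trios = 5,
#'                                          n_genes = 6, seed = 1),
#'                        dir = tempfile())
#' v <- read_cohort_vcf(sim$paths$vcf, read_gene_regions(sim$paths$bed))
#' v <- apply_site_qc(apply_genotype_qc(v))
#' fit <- genepy(subset_variants(v, which(select_scoring_variant(v))))
#' fit
#' @export
genepy <- function(v, genes = NULL, samples = v$samples,
                   model = deleteriousness_model(),
                   policy = frequency_policy()) {
  stopifnot(inherits(v, "genepy_variants"))
  if (is.null(genes)) genes <- sort(unique(unlist(v$gene_ids)))
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (!all(samples %in% v$samples)) stop("unknown sample id(s)")

  fr <- allele_frequencies(v, policy)
  D <- deleteriousness(v$tab$cadd_phred, model)
  s_het <- D * -log10(fr$f_ref * fr$f_alt)
  s_hom <- D * -log10(fr$f_alt^2)
  dos <- v$dosage[, samples, drop = FALSE]
  contrib <- s_het * (!is.na(dos) & dos == 1L) + s_hom * (!is.na(dos) & dos == 2L)

  scores <- matrix(0, nrow = length(samples), ncol = length(genes),
                   dimnames = list(samples, genes))
  for (j in seq_along(genes)) {
    rows <- which(vapply(v$gene_ids, function(g) genes[j] %in% g, logical(1)))
    if (length(rows) > 0L) {
      scores[, j] <- colSums(contrib[rows, , drop = FALSE])
    }
  }
  structure(list(scores = scores, model = model, policy = policy,
                 n_variants = nrow(v$tab)),
            class = "genepy_matrix")
}
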