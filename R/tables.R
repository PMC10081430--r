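#' Read gene regions from a 4-column BED file
#'
#' BED intervals are 0-based half-open on disk; the returned `GRanges` uses
#' the usual 1-based closed convention. The fourth BED column is the gene
#' symbol. Overlapping genes are all retained.
#'
#' @param path path to a BED file (chrom, start, end, gene_id).
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
read_gene_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop("gene BED file must have a 4th column with gene ids: ", path)
  }
  gr$gene_id <- gr$name
  gr$name <- NULL
  if (any(GenomicRanges::width(gr) < 1L)) stop("gene regions must satisfy start < end")
  gr
}

split_hpo <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(t) unique(t[nzchar(t)]))
}

#' Read the participant phenotype table
#'
#' Tab-separated with header columns `sample_id`, `affected` (0/1),
#' `hpo_terms` (semicolon-separated HPO IDs, may be empty),
#' `diagnosis_gene` and `diagnosis_variants` (both optional/empty for
#' undiagnosed participants).
#'
#' @param path path to the TSV file.
#' @return data.frame with list-column `hpo_terms`; class
#'   `genepy_participants`.
#' @export
read_participants <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "affected", "hpo_terms")
  if (!all(need %in% names(d))) {
    stop("participant table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in participant table: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(d$sample_id),
                    affected = as.integer(d$affected) == 1L,
                    stringsAsFactors = FALSE)
  out$hpo_terms <- split_hpo(d$hpo_terms)
  out$diagnosis_gene <- if ("diagnosis_gene" %in% names(d))
    as.character(d$diagnosis_gene) else NA_character_
  out$diagnosis_variants <- if ("diagnosis_variants" %in% names(d))
    as.character(d$diagnosis_variants) else NA_character_
  class(out) <- c("genepy_participants", "data.frame")
  out
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-separated, no header: family, individual, father, mother, sex,
#' phenotype; `0` marks a missing parent.
#'
#' @param path path to the PED file.
#' @return data.frame with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`; missing parents are `NA`.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, stringsAsFactors = FALSE,
                         col.names = c("family_id", "sample_id", "father_id",
                                       "mother_id", "sex", "phenotype"),
                         colClasses = c(rep("character", 4), "integer", "integer"))
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in pedigree: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  d$father_id[d$father_id == "0"] <- NA_character_
  d$mother_id[d$mother_id == "0"] <- NA_character_
  d
}

#' Read the gene-to-phenotype association table
#'
#' TSV with header `gene_id`, `hpo_terms` (semicolon-separated HPO IDs
#' characterizing the associated disease) and `acmg_incidental` (0/1 flag:
#' the gene is on the ACMG incidental-findings list).
#'
#' @param path path to the TSV file.
#' @return data.frame with list-column `hpo_terms`.
#' @export
read_gene_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("gene_id", "hpo_terms", "acmg_incidental")
  if (!all(need %in% names(d))) {
    stop("gene-phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$gene_id)) stop("duplicate gene_id in gene-phenotype table")
  out <- data.frame(gene_id = as.character(d$gene_id), stringsAsFactors = FALSE)
  out$hpo_terms <- split_hpo(d$hpo_terms)
  out$acmg_incidental <- as.integer(d$acmg_incidental) == 1L
  out
}

#' Read a manual triage override table
#'
#' TSV with header `sample_id`, `gene_id`, `verdict`; a listed
#' (sample, gene) pair's verdict supersedes the automatic phenotype-overlap
#' call. This is the editable stand-in for expert clinical review.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `gene_id`, `verdict`.
#' @export
read_override_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "verdict")
  if (!all(need %in% names(d))) {
    stop("override table must have columns: ", paste(need, collapse = ", "))
  }
  ok <- c("overlap", "no_overlap", "acmg_incidental")
  if (!all(d$verdict %in% ok)) {
    stop("override verdicts must be one of: ", paste(ok, collapse = ", "))
  }
  d[c("sample_id", "gene_id", "verdict")]
}
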