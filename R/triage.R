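TRIAGE_CATEGORIES <- c("unaffected_dropped", "insufficient_hpo",
                       "diagnosed_in_top_gene", "diagnosed_other_gene",
                       "overlap", "no_overlap", "acmg_incidental")

#' Stratify participants ahead of phenotype review
#'
#' Unaffected individuals are dropped regardless of phenotype data; affected
#' individuals with fewer than `min_hpo_terms` recorded HPO terms are set
#' aside as phenotypically insufficient; the rest are split by whether a
#' molecular diagnosis has already been returned.
#'
#' @param participants a `genepy_participants` table.
#' @param min_hpo_terms minimum number of recorded HPO terms for an affected
#'   participant to be assessable (default 1).
#' @return The table with an added factor column `stratum` in
#'   \{unaffected_dropped, insufficient_hpo, diagnosed, undiagnosed\}.
#' @export
stratify <- function(participants, min_hpo_terms = 1) {
  n_hpo <- lengths(participants$hpo_terms)
  stratum <- ifelse(!participants$affected, "unaffected_dropped",
             ifelse(n_hpo < min_hpo_terms, "insufficient_hpo",
             ifelse(!is.na(participants$diagnosis_gene), "diagnosed",
                    "undiagnosed")))
  participants$stratum <- factor(stratum, levels = c("unaffected_dropped",
                                                     "insufficient_hpo",
                                                     "diagnosed", "undiagnosed"))
  participants
}

#' Is a participant's established diagnosis in one of their top-ranked genes?
#'
#' @param diagnosis_gene the gene of the returned diagnosis.
#' @param topgenes character vector of genes for which the participant is
#'   top-ranked.
#' @return TRUE iff the diagnosis gene is among the top-ranked genes.
#' @export
diagnosis_in_top_gene <- function(diagnosis_gene, topgenes) {
  !is.na(diagnosis_gene) && diagnosis_gene %in% topgenes
}

#' Phenotype overlap between a patient and a disease gene
#'
#' Counts HPO terms shared between the patient's terms and the gene's
#' characteristic phenotype, matching directly or through the ontology
#' ancestor closure (root and depth < 2 terms never count). The pair
#' overlaps when at least `min_shared` terms are shared; a non-overlapping
#' pair whose gene is on the ACMG incidental-findings list is classed as a
#' potential incidental finding instead.
#'
#' @param patient_hpo character vector of the patient's HPO IDs (nonempty).
#' @param gene_hpo character vector of the gene's phenotype HPO IDs.
#' @param ontology an `hpo_ontology`.
#' @param min_shared minimum shared-term count for overlap (default 1).
#' @param use_ancestors match through ancestor closure (default TRUE);
#'   otherwise direct term identity only.
#' @param acmg_incidental is the gene on the ACMG incidental list?
#' @return One of `"overlap"`, `"no_overlap"`, `"acmg_incidental"`.
#' @export
phenotype_overlap <- function(patient_hpo, gene_hpo, ontology,
                              min_shared = 1, use_ancestors = TRUE,
                              acmg_incidental = FALSE) {
  stopifnot(length(patient_hpo) > 0, length(gene_hpo) > 0)
  if (use_ancestors) {
    a <- hpo_closure(patient_hpo, ontology)
    b <- hpo_closure(gene_hpo, ontology)
  } else {
    a <- patient_hpo; b <- gene_hpo
  }
  overlap_verdict(a, b, min_shared, acmg_incidental)
}

overlap_verdict <- function(a, b, min_shared, acmg_incidental) {
  shared <- length(intersect(a, b))
  if (shared >= min_shared) "overlap"
  else if (acmg_incidental) "acmg_incidental"
  else "no_overlap"
}

#' Triage all top-ranked (sample, gene) pairs
#'
#' Applies the full triage cascade to every pair in `topsets`: unaffected
#' participants are dropped, affected participants without sufficient HPO
#' terms are set aside, already-diagnosed participants are classed by
#' whether their diagnosis gene is itself top-ranked, and undiagnosed
#' participants are screened for phenotype overlap with the implicated gene
#' (with ACMG incidental-findings handling). An override table supersedes
#' the automatic overlap verdict for listed (sample, gene) pairs.
#'
#' Every pair receives exactly one category, so the category counts
#' partition the pair count.
#'
#' @param topsets a `top_set` data.frame from [top_sets()].
#' @param participants a `genepy_participants` table covering all top-ranked
#'   samples.
#' @param gene_phenotypes table from [read_gene_phenotypes()].
#' @param ontology an `hpo_ontology`.
#' @param min_hpo_terms,min_shared,use_ancestors see [stratify()] and
#'   [phenotype_overlap()].
#' @param overrides optional override table from [read_override_table()].
#' @return data.frame (class `triage_verdicts`) with columns `sample_id`,
#'   `gene_id`, `rank`, `score`, `category`.
#' @export
triage <- function(topsets, participants, gene_phenotypes, ontology,
                   min_hpo_terms = 1, min_shared = 1, use_ancestors = TRUE,
                   overrides = NULL) {
  missing <- setdiff(unique(topsets$sample_id), participants$sample_id)
  if (length(missing) > 0L) {
    stop("top-ranked sample(s) absent from participant table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  participants <- stratify(participants, min_hpo_terms = min_hpo_terms)
  pidx <- match(topsets$sample_id, participants$sample_id)
  gidx <- match(topsets$gene_id, gene_phenotypes$gene_id)
  topgenes_by_sample <- invert_topsets(topsets)

  ## closures are recomputed many times across pairs; cache per term set
  closure_of <- if (use_ancestors) {
    cache <- new.env(parent = emptyenv())
    function(terms) {
      key <- paste(sort(terms), collapse = "|")
      if (is.null(cache[[key]])) cache[[key]] <- hpo_closure(terms, ontology)
      cache[[key]]
    }
  } else identity

  category <- character(nrow(topsets))
  for (i in seq_len(nrow(topsets))) {
    p <- participants[pidx[i], ]
    stratum <- as.character(p$stratum)
    if (stratum %in% c("unaffected_dropped", "insufficient_hpo")) {
      category[i] <- stratum
      next
    }
    if (stratum == "diagnosed") {
      category[i] <- if (diagnosis_in_top_gene(
        p$diagnosis_gene, topgenes_by_sample[[p$sample_id]]))
        "diagnosed_in_top_gene" else "diagnosed_other_gene"
      next
    }
    ## undiagnosed: phenotype overlap with the implicated gene
    ov <- if (!is.null(overrides)) {
      hit <- overrides$sample_id == p$sample_id &
        overrides$gene_id == topsets$gene_id[i]
      if (any(hit)) overrides$verdict[which(hit)[1]] else NA_character_
    } else NA_character_
    if (!is.na(ov)) {
      category[i] <- ov
      next
    }
    if (is.na(gidx[i]) || length(gene_phenotypes$hpo_terms[[gidx[i]]]) == 0L) {
      warning("no phenotype annotation for gene ", topsets$gene_id[i],
              "; treated as no_overlap")
      category[i] <- "no_overlap"
      next
    }
    category[i] <- overlap_verdict(
      closure_of(p$hpo_terms[[1]]),
      closure_of(gene_phenotypes$hpo_terms[[gidx[i]]]),
      min_shared,
      isTRUE(gene_phenotypes$acmg_incidental[gidx[i]]))
  }
  out <- data.frame(sample_id = topsets$sample_id, gene_id = topsets$gene_id,
                    rank = topsets$rank, score = topsets$score,
                    category = factor(category, levels = TRIAGE_CATEGORIES),
                    stringsAsFactors = FALSE)
  class(out) <- c("triage_verdicts", "data.frame")
  out
}
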