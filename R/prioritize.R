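HARD_FLAGS <- c("common_in_callset", "no_segregation", "in_cis", "no_second_hit")
ALL_FLAGS <- c("noncoding_mane", HARD_FLAGS)
PATHOGENIC_CLASSES <- c("P", "LP")

#' Priority rule table
#'
#' The Top/Middle/Low/Exclude decision table, loaded from a YAML file so it
#' can be amended without touching code. The default table (shipped in
#' `inst/extdata/priority_rules.yaml`) excludes findings carrying any hard
#' deprioritization flag, requires a homozygous or phase-confirmed in-trans
#' configuration of MANE-coding P/LP variants for Top, and tolerates unknown
#' phase or a VUS partner at Middle.
#'
#' @param path optional path to a YAML rule file; default: the packaged
#'   table.
#' @return A list of class `priority_rules`.
#' @export
priority_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "priority_rules.yaml", package = "genepyr")
  }
  r <- yaml::read_yaml(path)
  stopifnot(all(c("exclude_flags", "pathogenic_classes", "top", "middle") %in%
                  names(r)))
  class(r) <- "priority_rules"
  r
}

#' Extract a sample's candidate variants in one gene
#'
#' All variants in the gene that the sample carries (dosage >= 1) with a
#' CADD phred score of at least `min_cadd`, in genomic order. A sample
#' absent from the callset (e.g. withdrawn from the study after scoring)
#' yields a closed, empty candidate set.
#'
#' @param v `genepy_variants` (post-QC).
#' @param sample_id,gene_id the pair under review.
#' @param min_cadd CADD threshold for candidate extraction (default 15).
#' @return An object of class `candidate_set`: fields `sample_id`,
#'   `gene_id`, `closed`, `tab` (variant annotations plus the sample's
#'   `dosage`), `idx` (row indices into `v`).
#' @export
extract_candidates <- function(v, sample_id, gene_id, min_cadd = 15) {
  stopifnot(inherits(v, "genepy_variants"))
  if (!sample_id %in% v$samples) {
    return(structure(list(sample_id = sample_id, gene_id = gene_id,
                          closed = TRUE,
                          tab = v$tab[0, , drop = FALSE], idx = integer(0)),
                     class = "candidate_set"))
  }
  in_gene <- vapply(v$gene_ids, function(g) gene_id %in% g, logical(1))
  dos <- v$dosage[, sample_id]
  keep <- which(in_gene & !is.na(dos) & dos >= 1L &
                  !is.na(v$tab$cadd_phred) & v$tab$cadd_phred >= min_cadd)
  keep <- keep[order(v$tab$chrom[keep], v$tab$pos[keep])]
  tab <- v$tab[keep, , drop = FALSE]
  tab$dosage <- dos[keep]
  rownames(tab) <- NULL
  structure(list(sample_id = sample_id, gene_id = gene_id, closed = FALSE,
                 tab = tab, idx = keep),
            class = "candidate_set")
}

#' Phase a heterozygous variant pair by trio transmission
#'
#' Given the child's het/het genotype at two sites and the parental
#' dosages, enumerates which parent could have transmitted each alternate
#' allele (a parent can transmit the alternate iff their dosage is >= 1 and
#' the reference iff their dosage is <= 1). If every consistent transmission
#' puts the two alternates on opposite parental haplotypes the pair is
#' `in_trans`; if always on the same parent's haplotype, `in_cis`; if both
#' readings are possible, or a parent is missing/uncalled, `unknown`. A
#' configuration with no consistent transmission is Mendelian-inconsistent:
#' `unknown`, with a warning.
#'
#' @param child length-2 dosage vector of the child (must be c(1, 1): a
#'   homozygous variant alone is already a biallelic genotype and needs no
#'   phase).
#' @param father,mother length-2 parental dosage vectors, or NULL when the
#'   parent is unavailable.
#' @return list with `phase` in \{"in_cis", "in_trans", "unknown"\} and
#'   `mendelian_consistent` (NA when phase was not attempted).
#' @export
phase_pair <- function(child = c(1L, 1L), father = NULL, mother = NULL) {
  if (anyNA(child) || !all(child == 1L)) {
    stop("phase_pair requires a het/het child genotype")
  }
  if (is.null(father) || is.null(mother) || anyNA(father) || anyNA(mother)) {
    return(list(phase = "unknown", mendelian_consistent = NA))
  }
  can_alt <- function(d) d >= 1L
  can_ref <- function(d) d <= 1L
  poss <- character(0)
  for (gA in c("F", "M")) {
    for (gB in c("F", "M")) {
      okA <- if (gA == "F") can_alt(father[1]) && can_ref(mother[1])
             else can_alt(mother[1]) && can_ref(father[1])
      okB <- if (gB == "F") can_alt(father[2]) && can_ref(mother[2])
             else can_alt(mother[2]) && can_ref(father[2])
      if (okA && okB) poss <- c(poss, if (gA == gB) "cis" else "trans")
    }
  }
  if (length(poss) == 0L) {
    warning("Mendelian-inconsistent trio genotypes; phase set to unknown")
    return(list(phase = "unknown", mendelian_consistent = FALSE))
  }
  u <- unique(poss)
  phase <- if (length(u) == 1L) c(cis = "in_cis", trans = "in_trans")[[u]]
           else "unknown"
  list(phase = phase, mendelian_consistent = TRUE)
}

## Phase every het/het pair of a candidate set through the pedigree.
## Returns a data.frame (i, j, phase) over het candidate indices.
phase_candidates <- function(cs, v, pedigree = NULL) {
  hets <- which(cs$tab$dosage == 1L)
  if (length(hets) < 2L) {
    return(data.frame(i = integer(0), j = integer(0), phase = character(0)))
  }
  father <- mother <- NULL
  if (!is.null(pedigree)) {
    row <- pedigree[pedigree$sample_id == cs$sample_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      fid <- row$father_id; mid <- row$mother_id
      if (!is.na(fid) && fid %in% v$samples) father <- fid
      if (!is.na(mid) && mid %in% v$samples) mother <- mid
    }
  }
  combs <- utils::combn(hets, 2)
  out <- data.frame(i = combs[1, ], j = combs[2, ],
                    phase = NA_character_, stringsAsFactors = FALSE)
  for (p in seq_len(nrow(out))) {
    rows <- cs$idx[c(out$i[p], out$j[p])]
    fd <- if (!is.null(father)) v$dosage[rows, father] else NULL
    md <- if (!is.null(mother)) v$dosage[rows, mother] else NULL
    out$phase[p] <- phase_pair(c(1L, 1L), fd, md)$phase
  }
  out
}

## Biallelic configurations of a candidate set: each homozygous variant on
## its own, and each het pair that is not phased in cis.
candidate_configs <- function(cs, phases) {
  configs <- list()
  for (i in which(cs$tab$dosage == 2L)) {
    configs[[length(configs) + 1L]] <- list(idx = i, type = "hom", phase = "hom")
  }
  if (nrow(phases) > 0L) {
    for (p in seq_len(nrow(phases))) {
      configs[[length(configs) + 1L]] <-
        list(idx = c(phases$i[p], phases$j[p]), type = "pair",
             phase = phases$phase[p])
    }
  }
  configs
}

## Affected, genotyped members of the sample's family (other than the
## sample itself); empty when pedigree/participants are unavailable.
affected_relatives <- function(cs, v, pedigree, participants) {
  if (is.null(pedigree) || is.null(participants)) return(character(0))
  row <- pedigree[pedigree$sample_id == cs$sample_id, , drop = FALSE]
  if (nrow(row) != 1L) return(character(0))
  fam <- pedigree$sample_id[pedigree$family_id == row$family_id]
  fam <- setdiff(fam, cs$sample_id)
  aff <- participants$sample_id[participants$affected]
  intersect(intersect(fam, aff), v$samples)
}

## Does `rel` carry the biallelic configuration `cfg` of candidate set `cs`?
relative_carries <- function(cfg, cs, v, rel) {
  d <- v$dosage[cs$idx[cfg$idx], rel]
  if (anyNA(d)) return(TRUE)  # uncalled: cannot assert non-segregation
  if (cfg$type == "hom") d == 2L else all(d >= 1L)
}

#' Deprioritization flags for a candidate set
#'
#' The five flags under which a candidate is deprioritized:
#' `noncoding_mane` (some variant is non-coding on the MANE transcript),
#' `common_in_callset` (some variant's within-callset allele frequency
#' exceeds `callset_af_threshold`, strict), `in_cis` (the only available
#' het pairing(s) are phased in cis), `no_second_hit` (no homozygote and no
#' second heterozygous variant), and `no_segregation` (an affected,
#' genotyped relative in the same family does not carry the candidate
#' biallelic genotype; only assessable for families with at least two
#' affected genotyped members).
#'
#' @param cs a `candidate_set` from [extract_candidates()].
#' @param v the `genepy_variants` the candidates were extracted from.
#' @param pedigree optional pedigree table ([read_pedigree()]).
#' @param participants optional participant table (for affection status of
#'   relatives).
#' @param callset_af_threshold within-callset frequency above which a
#'   variant counts as common (default 0.05).
#' @return Character vector of flags (possibly empty).
#' @export
compute_flags <- function(cs, v, pedigree = NULL, participants = NULL,
                          callset_af_threshold = 0.05) {
  stopifnot(inherits(cs, "candidate_set"))
  if (cs$closed || nrow(cs$tab) == 0L) {
    return(if (cs$closed) character(0) else "no_second_hit")
  }
  flags <- character(0)
  if (any(!cs$tab$mane_coding)) flags <- c(flags, "noncoding_mane")
  if (any(cs$tab$callset_af > callset_af_threshold, na.rm = TRUE)) {
    flags <- c(flags, "common_in_callset")
  }
  n_hom <- sum(cs$tab$dosage == 2L)
  n_het <- sum(cs$tab$dosage == 1L)
  phases <- phase_candidates(cs, v, pedigree)
  if (n_hom == 0L && n_het < 2L) flags <- c(flags, "no_second_hit")
  if (n_hom == 0L && n_het >= 2L && nrow(phases) > 0L &&
      all(phases$phase == "in_cis")) {
    flags <- c(flags, "in_cis")
  }
  rels <- affected_relatives(cs, v, pedigree, participants)
  if (length(rels) > 0L) {
    configs <- candidate_configs(cs, phases)
    configs <- Filter(function(cfg) cfg$phase != "in_cis", configs)
    carries <- function(rel) {
      if (length(configs) == 0L) {
        d <- v$dosage[cs$idx, rel]
        any(is.na(d) | d >= 1L)
      } else {
        any(vapply(configs, relative_carries, logical(1), cs = cs, v = v,
                   rel = rel))
      }
    }
    if (!all(vapply(rels, carries, logical(1)))) {
      flags <- c(flags, "no_segregation")
    }
  }
  intersect(ALL_FLAGS, flags)
}

#' Assign a priority tier to one biallelic configuration
#'
#' First matching rule wins: (1) any hard deprioritization flag
#' (`common_in_callset`, `no_segregation`, `in_cis`, `no_second_hit`) gives
#' Exclude; (2) a biallelic genotype — homozygous, or an in-trans-phased
#' pair — whose contributing variants are all P/LP (ClinVar or ACMG) and
#' MANE-coding gives Top; (3) a biallelic configuration with at least one
#' P/LP variant, all MANE-coding, but phase unknown or a VUS partner gives
#' Middle; (4) anything else biallelic — including any non-MANE-coding
#' contributor — gives Low.
#'
#' @param flags character vector of flags applying to the configuration.
#' @param clinvar ClinVar classes of the contributing variants.
#' @param acmg ACMG/AMP classes of the contributing variants (consumed as
#'   annotations; `"absent"` when uncurated).
#' @param phase `"hom"`, `"in_trans"`, `"in_cis"` or `"unknown"`.
#' @param rules a [priority_rules()] table.
#' @return One of `"Top"`, `"Middle"`, `"Low"`, `"Exclude"`.
#' @export
assign_priority <- function(flags, clinvar, acmg = rep("absent", length(clinvar)),
                            phase = "unknown", rules = priority_rules()) {
  if (length(intersect(flags, rules$exclude_flags)) > 0L) return("Exclude")
  path_cls <- rules$pathogenic_classes
  is_path <- clinvar %in% path_cls | acmg %in% path_cls
  any_vus <- any(clinvar == "VUS" | acmg == "VUS")
  mane_ok <- !("noncoding_mane" %in% flags)
  if (phase %in% rules$top$phases && all(is_path) &&
      (!isTRUE(rules$top$require_mane_coding) || mane_ok)) {
    return("Top")
  }
  if ((!isTRUE(rules$middle$require_mane_coding) || mane_ok) &&
      sum(is_path) >= rules$middle$min_pathogenic &&
      (phase == "unknown" || any_vus)) {
    return("Middle")
  }
  "Low"
}

## Flags restricted to one configuration of a candidate set.
config_flags <- function(cfg, cs, v, pedigree, participants,
                         callset_af_threshold) {
  tab <- cs$tab[cfg$idx, , drop = FALSE]
  flags <- character(0)
  if (any(!tab$mane_coding)) flags <- c(flags, "noncoding_mane")
  if (any(tab$callset_af > callset_af_threshold, na.rm = TRUE)) {
    flags <- c(flags, "common_in_callset")
  }
  if (cfg$phase == "in_cis") flags <- c(flags, "in_cis")
  rels <- affected_relatives(cs, v, pedigree, participants)
  if (length(rels) > 0L &&
      !all(vapply(rels, function(r) relative_carries(cfg, cs, v, r),
                  logical(1)))) {
    flags <- c(flags, "no_segregation")
  }
  intersect(ALL_FLAGS, flags)
}

#' Prioritize phenotype-matched (sample, gene) pairs
#'
#' For each pair, extracts the candidate variants, phases het pairs through
#' the pedigree, evaluates the deprioritization flags per biallelic
#' configuration (each homozygote; each het pair), and assigns the best
#' achievable priority tier across configurations — so a benign common
#' bystander variant in the gene cannot exclude an otherwise clean
#' homozygous pathogenic finding. A pair whose sample is absent from the
#' callset is reported as Closed (participant withdrawn); a pair with no
#' biallelic configuration is Excluded with the `no_second_hit` flag.
#'
#' @param pairs data.frame with columns `sample_id`, `gene_id` (typically
#'   the `overlap` rows of a [triage()] verdict table).
#' @param v `genepy_variants` to extract candidates from (post-QC; scoring
#'   selection not required).
#' @param pedigree optional pedigree ([read_pedigree()]).
#' @param participants optional participant table.
#' @param min_cadd candidate CADD threshold (default 15).
#' @param callset_af_threshold common-variant threshold (default 0.05).
#' @param rules a [priority_rules()] table.
#' @return data.frame of class `prioritized_findings`: one row per pair
#'   with `variants` (semicolon-joined chrom:pos:ref:alt), `dosages`,
#'   `phase`, `flags`, `clinvar_summary`, `priority`.
#' @export
prioritize <- function(pairs, v, pedigree = NULL, participants = NULL,
                       min_cadd = 15, callset_af_threshold = 0.05,
                       rules = priority_rules()) {
  tiers <- c(Top = 1, Middle = 2, Low = 3, Exclude = 4)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cs <- extract_candidates(v, pairs$sample_id[i], pairs$gene_id[i],
                             min_cadd = min_cadd)
    if (cs$closed) {
      res[[i]] <- data.frame(sample_id = cs$sample_id, gene_id = cs$gene_id,
                             variants = "", dosages = "", phase = NA_character_,
                             flags = "", clinvar_summary = "",
                             priority = "Closed", stringsAsFactors = FALSE)
      next
    }
    phases <- phase_candidates(cs, v, pedigree)
    configs <- candidate_configs(cs, phases)
    if (length(configs) == 0L) {
      flags <- compute_flags(cs, v, pedigree, participants,
                             callset_af_threshold)
      best <- list(priority = "Exclude", flags = flags,
                   idx = seq_len(nrow(cs$tab)), phase = NA_character_)
    } else {
      best <- NULL
      for (cfg in configs) {
        fl <- config_flags(cfg, cs, v, pedigree, participants,
                           callset_af_threshold)
        pr <- assign_priority(fl, cs$tab$clinvar[cfg$idx],
                              cs$tab$acmg[cfg$idx], cfg$phase, rules)
        if (is.null(best) || tiers[[pr]] < tiers[[best$priority]]) {
          best <- list(priority = pr, flags = fl, idx = cfg$idx,
                       phase = cfg$phase)
        }
      }
    }
    tab <- cs$tab[best$idx, , drop = FALSE]
    res[[i]] <- data.frame(
      sample_id = cs$sample_id, gene_id = cs$gene_id,
      variants = paste(variant_key(tab), collapse = ";"),
      dosages = paste(tab$dosage, collapse = ";"),
      phase = best$phase,
      flags = paste(best$flags, collapse = ";"),
      clinvar_summary = paste(tab$clinvar, collapse = ";"),
      priority = best$priority, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(res, list(stringsAsFactors = FALSE)))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), gene_id = character(0),
                      variants = character(0), dosages = character(0),
                      phase = character(0), flags = character(0),
                      clinvar_summary = character(0), priority = character(0))
  }
  class(out) <- c("prioritized_findings", "data.frame")
  out
}

#' Write prioritized findings to TSV and JSON-lines
#'
#' @param findings a `prioritized_findings` data.frame.
#' @param tsv_path,jsonl_path output paths (either may be NULL to skip).
#' @export
write_findings <- function(findings, tsv_path = NULL, jsonl_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(findings, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(jsonl_path)) {
    con <- file(jsonl_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(findings))) {
      writeLines(jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE),
                 con)
    }
  }
  invisible(findings)
}
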