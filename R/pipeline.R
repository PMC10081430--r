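#' Run configuration for the end-to-end pipeline
#'
#' Collects every input path and tunable parameter of the workflow. The
#' object round-trips losslessly through YAML via [write_genepy_config()] /
#' [read_genepy_config()].
#'
#' @param vcf,genes_bed,ped,participants,gene_phenotypes,hpo_obo input file
#'   paths (`ped`, `overrides` optional).
#' @param vcf_extract optional VCF used for candidate extraction at the
#'   prioritization stage (e.g. a post-withdrawal callset); defaults to
#'   `vcf`.
#' @param overrides optional triage override table path.
#' @param out_dir output directory for stage outputs and manifests.
#' @param min_depth,min_gq,min_mean_gq,min_call_rate genotype/site QC
#'   thresholds.
#' @param max_coding_distance,min_cadd scoring selection thresholds.
#' @param k top-k rank cutoff (default 5).
#' @param af_floor,fallback_to_callset frequency policy.
#' @param deleteriousness_mode,deleteriousness_scale deleteriousness model.
#' @param min_hpo_terms,min_shared,use_ancestors triage parameters.
#' @param callset_af_threshold common-variant flag threshold.
#' @param priority_rules_path optional YAML rule table (default: packaged).
#' @param seed integer seed recorded in manifests.
#' @return list of class `genepy_config`.
#' @export
genepy_config <- function(vcf, genes_bed, participants, gene_phenotypes,
                          hpo_obo, ped = NULL, vcf_extract = NULL,
                          overrides = NULL, out_dir = tempfile("genepy_run"),
                          min_depth = 10, min_gq = 20, min_mean_gq = 35,
                          min_call_rate = 0.70, max_coding_distance = 8,
                          min_cadd = 15, k = 5, af_floor = 1e-5,
                          fallback_to_callset = FALSE,
                          deleteriousness_mode = "normalized_phred",
                          deleteriousness_scale = 99,
                          min_hpo_terms = 1, min_shared = 1,
                          use_ancestors = TRUE, callset_af_threshold = 0.05,
                          priority_rules_path = NULL, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "genepy_config"
  cfg
}

#' Write a run configuration to YAML
#' @param cfg a `genepy_config`.
#' @param path output YAML path.
#' @export
write_genepy_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_genepy_config()].
#' @return A `genepy_config`.
#' @export
read_genepy_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(genepy_config)))]
  do.call(genepy_config, args)
}

stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

write_manifest <- function(cfg, stage, counts, inputs = character(0)) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  params <- unclass(cfg)
  params$out_dir <- NULL
  manifest <- list(stage = stage, parameters = params,
                   input_md5 = hashes, counts = counts)
  path <- stage_file(cfg, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

read_manifest <- function(cfg, stage) {
  jsonlite::read_json(stage_file(cfg, sprintf("manifest_%s.json", stage)))
}

need_stage <- function(cfg, file, stage) {
  p <- stage_file(cfg, file)
  if (!file.exists(p)) {
    stop(sprintf("missing intermediate '%s'; run the '%s' stage first",
                 file, stage))
  }
  p
}

load_qc_variants <- function(cfg, vcf_path) {
  regions <- read_gene_regions(cfg$genes_bed)
  v <- read_cohort_vcf(vcf_path, regions)
  n_raw <- nrow(v$tab)
  v <- apply_genotype_qc(v, min_depth = cfg$min_depth, min_gq = cfg$min_gq)
  v <- apply_site_qc(v, min_mean_gq = cfg$min_mean_gq,
                     min_call_rate = cfg$min_call_rate)
  list(v = v, regions = regions, n_raw = n_raw)
}

#' Scoring stage: QC, variant selection, GenePy matrix
#'
#' Reads the cohort VCF restricted to the gene BED, applies genotype- and
#' site-level QC, selects scoring variants, fits the GenePy matrix and
#' writes `matrix.tsv` plus a JSON manifest of parameters, input hashes and
#' filter-funnel counts.
#'
#' @param cfg a [genepy_config()].
#' @return The fitted `genepy_matrix`, invisibly.
#' @export
run_score <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lq <- load_qc_variants(cfg, cfg$vcf)
  v <- lq$v
  sel <- select_scoring_variant(v, max_coding_distance = cfg$max_coding_distance,
                                min_cadd = cfg$min_cadd)
  vs <- subset_variants(v, which(sel))
  fit <- genepy(vs, genes = sort(unique(lq$regions$gene_id)),
                model = deleteriousness_model(cfg$deleteriousness_mode,
                                              cfg$deleteriousness_scale),
                policy = frequency_policy(cfg$af_floor,
                                          fallback_to_callset = cfg$fallback_to_callset))
  write_genepy_matrix(fit, stage_file(cfg, "matrix.tsv"))
  write_manifest(cfg, "score",
                 counts = list(n_samples = nrow(fit$scores),
                               n_genes = ncol(fit$scores),
                               n_variants_raw = lq$n_raw,
                               n_variants_after_site_qc = nrow(v$tab),
                               n_variants_selected = nrow(vs$tab)),
                 inputs = c(cfg$vcf, cfg$genes_bed))
  invisible(fit)
}

#' Ranking stage: per-gene competition ranks and tie-retaining top-k
#'
#' @param cfg a [genepy_config()].
#' @return The `top_set` data.frame, invisibly.
#' @export
run_rank <- function(cfg) {
  mpath <- need_stage(cfg, "matrix.tsv", "score")
  fit <- read_genepy_matrix(mpath)
  rankings <- rank_all(fit)
  ts <- top_k(rankings, k = cfg$k)
  utils::write.table(rankings, stage_file(cfg, "rankings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ts, stage_file(cfg, "topsets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "rank",
                 counts = list(n_genes = ncol(fit$scores),
                               n_pairs_topranked = nrow(ts),
                               n_unique_samples = length(unique(ts$sample_id))),
                 inputs = mpath)
  invisible(ts)
}

#' Triage stage: stratification and phenotype-overlap verdicts
#'
#' @param cfg a [genepy_config()].
#' @return The `triage_verdicts` data.frame, invisibly.
#' @export
run_triage <- function(cfg) {
  tpath <- need_stage(cfg, "topsets.tsv", "rank")
  ts <- utils::read.delim(tpath, stringsAsFactors = FALSE)
  participants <- read_participants(cfg$participants)
  gp <- read_gene_phenotypes(cfg$gene_phenotypes)
  ont <- read_hpo_obo(cfg$hpo_obo)
  ov <- if (!is.null(cfg$overrides)) read_override_table(cfg$overrides) else NULL
  verdicts <- triage(ts, participants, gp, ont,
                     min_hpo_terms = cfg$min_hpo_terms,
                     min_shared = cfg$min_shared,
                     use_ancestors = cfg$use_ancestors, overrides = ov)
  utils::write.table(verdicts, stage_file(cfg, "verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- as.list(table(verdicts$category))
  counts$n_pairs <- nrow(verdicts)
  write_manifest(cfg, "triage", counts = counts,
                 inputs = c(cfg$participants, cfg$gene_phenotypes, cfg$hpo_obo))
  invisible(verdicts)
}

#' Prioritization stage: candidate extraction, phasing, flags, tiers
#'
#' Candidates are extracted from `vcf_extract` when configured (scores are
#' computed before participants withdraw; extraction happens after), so a
#' phenotype-matched sample absent from that callset yields a Closed
#' finding.
#'
#' @param cfg a [genepy_config()].
#' @return The `prioritized_findings` data.frame, invisibly.
#' @export
run_prioritize <- function(cfg) {
  vpath <- need_stage(cfg, "verdicts.tsv", "triage")
  verdicts <- utils::read.delim(vpath, stringsAsFactors = FALSE)
  pairs <- verdicts[verdicts$category == "overlap", , drop = FALSE]
  extract_vcf <- if (!is.null(cfg$vcf_extract)) cfg$vcf_extract else cfg$vcf
  lq <- load_qc_variants(cfg, extract_vcf)
  ped <- if (!is.null(cfg$ped)) read_pedigree(cfg$ped) else NULL
  participants <- read_participants(cfg$participants)
  rules <- priority_rules(cfg$priority_rules_path)
  findings <- prioritize(pairs, lq$v, pedigree = ped,
                         participants = participants, min_cadd = cfg$min_cadd,
                         callset_af_threshold = cfg$callset_af_threshold,
                         rules = rules)
  write_findings(findings, stage_file(cfg, "findings.tsv"),
                 stage_file(cfg, "findings.jsonl"))
  counts <- as.list(table(factor(findings$priority,
                                 levels = c("Top", "Middle", "Low", "Exclude",
                                            "Closed"))))
  counts$n_findings <- nrow(findings)
  write_manifest(cfg, "prioritize", counts = counts, inputs = extract_vcf)
  invisible(findings)
}

#' Run the full workflow and summarize the funnel
#'
#' Runs score, rank, triage and prioritize in order and writes a summary
#' manifest whose counts mirror the analysis funnel: pairs top-ranked, the
#' triage partition (unaffected removed, insufficient phenotype, diagnosed
#' split, overlap split) and the priority tallies. Conservation holds at
#' every split: categorized counts sum to the count entering the stage.
#'
#' @param cfg a [genepy_config()].
#' @return list with elements `matrix`, `topsets`, `verdicts`, `findings`,
#'   `funnel`, invisibly.
#' @export
run_all <- function(cfg) {
  fit <- run_score(cfg)
  ts <- run_rank(cfg)
  verdicts <- run_triage(cfg)
  findings <- run_prioritize(cfg)
  cat_counts <- table(verdicts$category)
  funnel <- list(
    n_pairs_topranked = nrow(ts),
    triage = as.list(cat_counts),
    n_overlap = unname(cat_counts[["overlap"]]),
    priorities = as.list(table(factor(findings$priority,
                                      levels = c("Top", "Middle", "Low",
                                                 "Exclude", "Closed")))),
    n_findings = nrow(findings))
  manifest_path <- stage_file(cfg, "manifest_summary.json")
  jsonlite::write_json(list(stage = "summary", funnel = funnel), manifest_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(matrix = fit, topsets = ts, verdicts = verdicts,
                 findings = findings, funnel = funnel))
}
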