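# Fixture builders: every test input is constructed in code at run time.

# Build a genepy_variants container directly (no VCF round trip).
make_variants <- function(n_var, samples, genes, seed = 1,
                          cadd = NULL, pop_af = NULL, dosage = NULL,
                          gene_ids = NULL, mane = NULL, clinvar = NULL,
                          callset_af = NULL, depth = NULL, gq = NULL,
                          coding_distance = NULL) {
  set.seed(seed)
  ns <- length(samples)
  if (is.null(cadd)) cadd <- round(stats::runif(n_var, 0, 50), 3)
  if (is.null(pop_af)) {
    pop_af <- 10^stats::runif(n_var, -5, log10(0.5))
    pop_af[stats::runif(n_var) < 0.15] <- NA  # absent from reference panel
  }
  if (is.null(gene_ids)) {
    gene_ids <- lapply(seq_len(n_var), function(i)
      sample(genes, sample(seq_len(min(2, length(genes))), 1)))
  }
  if (is.null(dosage)) {
    dosage <- matrix(sample(c(0L, 0L, 0L, 1L, 1L, 2L, NA), n_var * ns,
                            replace = TRUE), n_var, ns)
  }
  if (is.null(depth)) depth <- matrix(30L, n_var, ns)
  if (is.null(gq)) gq <- matrix(80L, n_var, ns)
  if (is.null(mane)) mane <- rep(TRUE, n_var)
  if (is.null(clinvar)) clinvar <- rep("absent", n_var)
  if (is.null(coding_distance)) coding_distance <- rep(0L, n_var)
  tab <- data.frame(chrom = "1", pos = seq_len(n_var) * 100L,
                    ref = "A", alt = "T",
                    cadd_phred = cadd, pop_af = pop_af,
                    coding_distance = coding_distance,
                    mane_coding = mane, clinvar = clinvar,
                    acmg = rep("absent", n_var),
                    callset_af = if (is.null(callset_af))
                      genepyr:::compute_callset_af(dosage) else callset_af,
                    stringsAsFactors = FALSE)
  genepy_variants(tab, gene_ids, dosage, depth, gq, samples)
}

# A candidate_set built directly from variant properties of one gene.
make_candidates <- function(dosage, cadd = 30, clinvar = "P", mane = TRUE,
                            callset_af = 0.001, samples = "S1",
                            sample_id = "S1", gene_id = "G1") {
  n <- length(dosage)
  recycle <- function(x) rep_len(x, n)
  v <- make_variants(n, samples, gene_id,
                     cadd = recycle(cadd),
                     pop_af = rep(1e-4, n),
                     dosage = matrix(rep(dosage, length(samples)), n,
                                     length(samples)),
                     gene_ids = rep(list(gene_id), n),
                     mane = recycle(mane), clinvar = recycle(clinvar),
                     callset_af = recycle(callset_af))
  list(v = v, cs = extract_candidates(v, sample_id, gene_id))
}

# One small simulated cohort (with a withdrawn proband) shared across test
# files; built once per run.
.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_cohort(
      simulation_config(n_samples = 60, n_trios = 8, n_genes = 10,
                        n_planted_trans = 2, n_planted_cis = 1,
                        n_planted_hom = 1, n_withdrawn = 1, seed = 7),
      dir = file.path(tempdir(), "genepyr_shared_sim"))
  }
  .shared$sim
}

shared_config <- function(out_dir = file.path(tempdir(), "genepyr_shared_run")) {
  sim <- shared_sim()
  genepy_config(vcf = sim$paths$vcf, genes_bed = sim$paths$bed,
                participants = sim$paths$participants,
                gene_phenotypes = sim$paths$gene_phenotypes,
                hpo_obo = sim$paths$obo, ped = sim$paths$ped,
                vcf_extract = sim$paths$vcf_postwithdrawal,
                out_dir = out_dir, seed = 7)
}

shared_run <- function() {
  if (is.null(.shared$run)) .shared$run <- run_all(shared_config())
  .shared$run
}

# Minimal hand-written VCF (one multi-allelic record + extras) for io tests.
write_tiny_vcf <- function(path, samples = c("SA", "SB"),
                           records = NULL, format_fields = "GT:DP:GQ") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000000>",
    "##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description=\"d\">",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"d\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"d\">",
    "##INFO=<ID=CODING_DIST,Number=A,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MANE_CODING,Number=A,Type=Integer,Description=\"d\">",
    "##INFO=<ID=CLINVAR,Number=A,Type=String,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"d\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

write_tiny_bed <- function(path, lines) {
  writeLines(lines, path)
  path
}

# Three-level test ontology: root -> organ systems -> features -> subtypes.
write_test_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: root", "",
    "[Term]", "id: HP:0000010", "name: system A", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000020", "name: system B", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000100", "name: feature A1", "is_a: HP:0000010", "",
    "[Term]", "id: HP:0000101", "name: feature A2", "is_a: HP:0000010", "",
    "[Term]", "id: HP:0000200", "name: feature B1", "is_a: HP:0000020", "",
    "[Term]", "id: HP:0001000", "name: subtype of A1", "is_a: HP:0000100", "",
    "[Term]", "id: HP:0009999", "name: obsolete thing", "is_obsolete: true"),
    path)
  path
}
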