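#' Configuration for the synthetic cohort simulator
#'
#' Defines the study conditions the simulator emulates: a rare-disease
#' cohort of singletons plus parent-child trios, gene regions carrying a
#' rare-variant background with a log-uniform population allele-frequency
#' spectrum and Hardy-Weinberg genotypes, and planted ground-truth events —
#' in-trans P/LP compound-heterozygous pairs and homozygous P/LP variants
#' in affected trio probands (true missed diagnoses), plus in-cis decoy
#' pairs that trio phasing must reject.
#'
#' Planted variants are drawn deep in the rare, damaging corner of the
#' spectrum (CADD uniform on `planted_cadd`, population AF log-uniform on
#' `planted_af`), and background variants inside planted genes are capped
#' below the CADD-15 scoring threshold so each planted configuration is the
#' only qualifying variant set in its gene and its intended priority is
#' unambiguous.
#'
#' @param n_samples total cohort size (default 200).
#' @param n_trios number of father-mother-child trios (children affected,
#'   parents unaffected; default 30). Remaining samples are singletons.
#' @param n_genes number of gene regions (default 50).
#' @param variants_per_gene mean background variants per gene (Poisson;
#'   default 8).
#' @param af_spectrum length-2 range of the log-uniform background
#'   population AF spectrum (default c(1e-5, 0.5)).
#' @param cadd_shape,cadd_scale gamma parameters of the background CADD
#'   spectrum (default shape 2, scale 6: most background variants fall
#'   below the CADD-15 threshold).
#' @param n_planted_trans in-trans P/LP pairs planted in affected probands
#'   (default 6).
#' @param n_planted_cis in-cis decoy pairs (default 4).
#' @param n_planted_hom homozygous P/LP variants (default 4).
#' @param planted_cadd,planted_af CADD range and AF range of planted
#'   variants (defaults c(30, 45) and c(1e-5, 1e-4)).
#' @param hpo_noise probability of dropping a proband phenotype term and of
#'   adding a spurious one (default 0).
#' @param n_withdrawn probands planted with an in-trans event but withdrawn
#'   from the callset after scoring (default 0); when positive, a
#'   post-withdrawal VCF with their sample columns removed is also emitted.
#' @param seed integer seed; the seed fully determines every output byte.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200, n_trios = 30, n_genes = 50,
                              variants_per_gene = 8,
                              af_spectrum = c(1e-5, 0.5),
                              cadd_shape = 2, cadd_scale = 6,
                              n_planted_trans = 6, n_planted_cis = 4,
                              n_planted_hom = 4,
                              planted_cadd = c(30, 45),
                              planted_af = c(1e-5, 1e-4),
                              hpo_noise = 0, n_withdrawn = 0, seed = 1) {
  cfg <- list(n_samples = n_samples, n_trios = n_trios, n_genes = n_genes,
              variants_per_gene = variants_per_gene,
              af_spectrum = af_spectrum, cadd_shape = cadd_shape,
              cadd_scale = cadd_scale, n_planted_trans = n_planted_trans,
              n_planted_cis = n_planted_cis, n_planted_hom = n_planted_hom,
              planted_cadd = planted_cadd, planted_af = planted_af,
              hpo_noise = hpo_noise, n_withdrawn = n_withdrawn,
              seed = as.integer(seed))
  counts <- c(n_samples, n_trios, n_genes, n_planted_trans, n_planted_cis,
              n_planted_hom, n_withdrawn)
  if (any(counts < 0)) stop("all counts must be >= 0")
  n_events <- n_planted_trans + n_planted_cis + n_planted_hom + n_withdrawn
  if (n_events > n_trios) {
    stop("more planted events (", n_events, ") than trio probands (", n_trios, ")")
  }
  if (n_events > n_genes) stop("more planted events than genes")
  if (3 * n_trios > n_samples) stop("n_samples too small for n_trios trios")
  class(cfg) <- "simulation_config"
  cfg
}

fmt_num <- function(x) sub("e([+-])0*(\\d)", "e\\1\\2", sprintf("%.6g", x))

GENE_LEN <- 10000L
GENE_GAP <- 100000L

#' Simulate a self-contained cohort fixture with known ground truth
#'
#' Emits, under `dir`: a multi-sample VCF (plus a post-withdrawal VCF when
#' configured), a 4-column gene BED, a 6-column PED, the participant
#' phenotype TSV, the gene-phenotype TSV, a miniature 3-level HPO-style
#' ontology in OBO format, and a ground-truth table of the planted events
#' with their intended phase and priority. Background genotypes are drawn
#' from Hardy-Weinberg proportions at each variant's population AF for
#' founders, and trio children inherit one allele from each parent by
#' Mendelian transmission. Planted pairs are placed with the parental
#' origins that make trio phasing recover the intended phase. Per-genotype
#' DP and GQ straddle the QC thresholds so the filters are exercised (a few
#' percent of background sites are engineered to fail site QC).
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `ground_truth`
#'   (data.frame: `event`, `type`, `sample_id`, `gene_id`, `variants`,
#'   `intended_phase`, `intended_priority`) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = tempfile("cohort")) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  ## ---- samples, families ----
  n <- config$n_samples; nt <- config$n_trios
  trio_father <- sprintf("S%03dF", seq_len(nt))
  trio_mother <- sprintf("S%03dM", seq_len(nt))
  trio_child <- sprintf("S%03dC", seq_len(nt))
  n_single <- n - 3L * nt
  singles <- if (n_single > 0) sprintf("U%03d", seq_len(n_single)) else character(0)
  samples <- c(rbind(trio_father, trio_mother, trio_child), singles)
  founders <- c(trio_father, trio_mother, singles)

  n_unaff_single <- min(n_single, max(0L, round(0.45 * n) - 2L * nt))
  unaffected <- c(trio_father, trio_mother,
                  if (n_unaff_single > 0) singles[seq_len(n_unaff_single)])
  affected <- setdiff(samples, unaffected)

  ## ---- genes ----
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  gstart0 <- (seq_len(config$n_genes) - 1L) * GENE_GAP  # 0-based BED starts
  n_events <- config$n_planted_trans + config$n_planted_cis +
    config$n_planted_hom + config$n_withdrawn
  planted_genes <- if (n_events > 0) sample(genes, n_events) else character(0)
  event_types <- rep(c("trans", "cis", "hom", "withdrawn_trans"),
                     times = c(config$n_planted_trans, config$n_planted_cis,
                               config$n_planted_hom, config$n_withdrawn))
  event_children <- if (n_events > 0) sample(trio_child, n_events) else character(0)

  ## ---- variant table ----
  rows <- list()
  add_row <- function(gene, pos, cadd, paf, cdist, mane, clin) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, pos = pos, cadd = cadd, paf = paf, cdist = cdist,
      mane = mane, clinvar = clin, planted = FALSE, stringsAsFactors = FALSE)
  }
  rloguni <- function(k, lo, hi) 10^stats::runif(k, log10(lo), log10(hi))
  for (g in seq_along(genes)) {
    k <- stats::rpois(1, config$variants_per_gene)
    if (k == 0L) next
    pos <- sort(sample.int(GENE_LEN, k)) + gstart0[g]
    cadd <- if (genes[g] %in% planted_genes) {
      stats::runif(k, 0, 14.5)  # keep planted configs the only scorers
    } else pmin(stats::rgamma(k, config$cadd_shape, scale = config$cadd_scale), 99)
    paf <- rloguni(k, config$af_spectrum[1], config$af_spectrum[2])
    cdist <- ifelse(stats::runif(k) < 0.8, sample(0:8, k, replace = TRUE),
                    sample(9:200, k, replace = TRUE))
    mane <- stats::runif(k) < 0.85
    clin <- sample(c("absent", "VUS", "LB", "B", "conflicting"), k,
                   replace = TRUE, prob = c(0.8, 0.1, 0.04, 0.04, 0.02))
    for (i in seq_len(k)) {
      add_row(genes[g], pos[i], round(cadd[i], 3), paf[i], cdist[i],
              mane[i], clin[i])
    }
  }

  ## planted variants: rare, damaging, P/LP, MANE-coding
  truth <- list()
  used_pos <- function(gene) {
    d <- do.call(rbind, rows)
    d$pos[d$gene == gene]
  }
  for (e in seq_along(event_types)) {
    gene <- planted_genes[e]
    npv <- if (event_types[e] == "hom") 1L else 2L
    repeat {
      pos <- sort(sample.int(GENE_LEN, npv)) +
        gstart0[match(gene, genes)]
      if (!any(pos %in% used_pos(gene))) break
    }
    for (i in seq_len(npv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, pos = pos[i],
        cadd = round(stats::runif(1, config$planted_cadd[1],
                                  config$planted_cadd[2]), 3),
        paf = rloguni(1, config$planted_af[1], config$planted_af[2]),
        cdist = 0L, mane = TRUE, clinvar = sample(c("P", "LP"), 1),
        planted = TRUE, stringsAsFactors = FALSE)
    }
    truth[[e]] <- list(type = event_types[e], sample_id = event_children[e],
                       gene_id = gene, pos = pos)
  }

  vt <- do.call(rbind, rows)
  vt <- vt[order(vt$pos), , drop = FALSE]
  rownames(vt) <- NULL
  nv <- nrow(vt)
  bases <- c("A", "C", "G", "T")
  vt$ref <- sample(bases, nv, replace = TRUE)
  vt$alt <- vapply(vt$ref, function(r) sample(setdiff(bases, r), 1), character(1))

  ## ---- genotypes ----
  dosage <- matrix(0L, nv, n, dimnames = list(NULL, samples))
  for (i in which(!vt$planted)) {
    fd <- stats::rbinom(length(founders), 2, vt$paf[i])
    dosage[i, founders] <- fd
  }
  for (t in seq_len(nt)) {
    fa <- dosage[, trio_father[t]]; mo <- dosage[, trio_mother[t]]
    bg <- !vt$planted
    dosage[bg, trio_child[t]] <- stats::rbinom(sum(bg), 1, fa[bg] / 2) +
      stats::rbinom(sum(bg), 1, mo[bg] / 2)
  }
  for (e in seq_along(truth)) {
    ev <- truth[[e]]
    child <- ev$sample_id
    t <- match(child, trio_child)
    ridx <- match(ev$pos, vt$pos)
    if (ev$type == "hom") {
      dosage[ridx, trio_father[t]] <- 1L
      dosage[ridx, trio_mother[t]] <- 1L
      dosage[ridx, child] <- 2L
    } else if (ev$type == "cis") {
      dosage[ridx, trio_father[t]] <- 1L
      dosage[ridx, child] <- 1L
    } else {  # trans, withdrawn_trans
      dosage[ridx[1], trio_father[t]] <- 1L
      dosage[ridx[2], trio_mother[t]] <- 1L
      dosage[ridx, child] <- 1L
    }
  }

  ## ---- DP / GQ ----
  dp <- matrix(stats::rpois(nv * n, 35), nv, n)
  low_dp <- matrix(stats::runif(nv * n) < 0.06, nv, n)
  dp[low_dp] <- stats::rpois(sum(low_dp), 6)
  gq <- matrix(pmax(0L, pmin(99L, round(stats::rnorm(nv * n, 60, 15)))), nv, n)
  bad_site <- !vt$planted & stats::runif(nv) < 0.03
  gq[bad_site, ] <- pmax(0L, pmin(99L, round(stats::rnorm(sum(bad_site) * n, 28, 8))))
  missing_gt <- matrix(stats::runif(nv * n) < 0.01, nv, n)
  planted_rows <- which(vt$planted)
  dp[planted_rows, ] <- 40L + matrix(stats::rpois(length(planted_rows) * n, 10),
                                     length(planted_rows), n)
  gq[planted_rows, ] <- 75L + matrix(sample(0:24, length(planted_rows) * n,
                                            replace = TRUE),
                                     length(planted_rows), n)
  missing_gt[planted_rows, ] <- FALSE

  ## ---- ontology + gene phenotypes ----
  n_cat <- 6L; n_leaf <- 7L
  root <- "HP:0000001"
  cats <- sprintf("HP:%07d", 100 + seq_len(n_cat))
  leaves <- sprintf("HP:%07d", 1000 + seq_len(n_cat * n_leaf))
  leaf_cat <- rep(seq_len(n_cat), each = n_leaf)
  obo <- c("format-version: 1.2", "ontology: mini-hpo", "",
           "[Term]", paste0("id: ", root), "name: Phenotypic abnormality")
  for (c_i in seq_len(n_cat)) {
    obo <- c(obo, "", "[Term]", paste0("id: ", cats[c_i]),
             sprintf("name: Category %d", c_i),
             paste0("is_a: ", root, " ! Phenotypic abnormality"))
  }
  for (l_i in seq_along(leaves)) {
    obo <- c(obo, "", "[Term]", paste0("id: ", leaves[l_i]),
             sprintf("name: Feature %d", l_i),
             paste0("is_a: ", cats[leaf_cat[l_i]]))
  }

  gene_cat <- ((seq_len(config$n_genes) - 1L) %% n_cat) + 1L
  gene_hpo <- lapply(seq_len(config$n_genes), function(g) {
    sample(leaves[leaf_cat == gene_cat[g]], sample(3:5, 1))
  })
  names(gene_hpo) <- genes
  acmg_flag <- genes %in% sample(genes, min(3L, config$n_genes))

  ## ---- participant phenotypes ----
  hpo_terms <- stats::setNames(rep(list(character(0)), n), samples)
  planted_children <- vapply(truth, `[[`, character(1), "sample_id")
  for (s in affected) {
    e <- match(s, planted_children)
    if (!is.na(e)) {
      terms <- sample(gene_hpo[[truth[[e]]$gene_id]],
                      min(sample(2:3, 1), length(gene_hpo[[truth[[e]]$gene_id]])))
      if (config$hpo_noise > 0) {
        terms <- terms[stats::runif(length(terms)) >= config$hpo_noise]
        if (stats::runif(1) < config$hpo_noise) terms <- c(terms, sample(leaves, 1))
      }
      hpo_terms[[s]] <- unique(terms)
    } else if (stats::runif(1) < 0.1) {
      hpo_terms[[s]] <- character(0)  # insufficient-phenotype stratum
    } else {
      hpo_terms[[s]] <- sample(leaves, sample(1:3, 1))
    }
  }

  ## prior diagnoses for a subset of affected singletons
  aff_single <- setdiff(intersect(affected, singles), planted_children)
  n_diag <- round(0.15 * length(aff_single))
  diagnosed <- if (n_diag > 0) sample(aff_single, n_diag) else character(0)
  diag_gene <- stats::setNames(rep(NA_character_, n), samples)
  diag_gene[diagnosed] <- sample(genes, length(diagnosed), replace = TRUE)

  ## ---- write outputs ----
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                bed = file.path(dir, "genes.bed"),
                ped = file.path(dir, "cohort.ped"),
                participants = file.path(dir, "participants.tsv"),
                gene_phenotypes = file.path(dir, "gene_phenotypes.tsv"),
                obo = file.path(dir, "mini_hpo.obo"),
                ground_truth = file.path(dir, "ground_truth.tsv"))

  writeLines(c(sprintf("1\t%d\t%d\t%s", gstart0, gstart0 + GENE_LEN, genes)),
             paths$bed)

  ped <- character(0)
  for (t in seq_len(nt)) {
    fam <- sprintf("F%03d", t)
    ped <- c(ped,
             sprintf("%s\t%s\t0\t0\t1\t1", fam, trio_father[t]),
             sprintf("%s\t%s\t0\t0\t2\t1", fam, trio_mother[t]),
             sprintf("%s\t%s\t%s\t%s\t1\t2", fam, trio_child[t],
                     trio_father[t], trio_mother[t]))
  }
  for (s in singles) {
    ped <- c(ped, sprintf("FS%s\t%s\t0\t0\t1\t%d", s, s,
                          if (s %in% affected) 2L else 1L))
  }
  writeLines(ped, paths$ped)

  part <- c("sample_id\taffected\thpo_terms\tdiagnosis_gene\tdiagnosis_variants",
            vapply(samples, function(s) {
              sprintf("%s\t%d\t%s\t%s\t%s", s,
                      as.integer(s %in% affected),
                      paste(hpo_terms[[s]], collapse = ";"),
                      ifelse(is.na(diag_gene[[s]]), "", diag_gene[[s]]),
                      "")
            }, character(1)))
  writeLines(part, paths$participants)

  writeLines(c("gene_id\thpo_terms\tacmg_incidental",
               sprintf("%s\t%s\t%d", genes,
                       vapply(gene_hpo, paste, character(1), collapse = ";"),
                       as.integer(acmg_flag))),
             paths$gene_phenotypes)

  writeLines(obo, paths$obo)

  ## VCF
  gt_str <- matrix("0/0", nv, n)
  gt_str[dosage == 1L] <- "0/1"
  gt_str[dosage == 2L] <- "1/1"
  gt_str[missing_gt] <- "./."
  vcf_header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>", max(vt$pos) + GENE_LEN),
    "##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description=\"CADD phred deleteriousness score\">",
    "##INFO=<ID=POP_AF,Number=A,Type=Float,Description=\"Reference-population alternate allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Overlapping gene symbols, comma separated\">",
    "##INFO=<ID=CODING_DIST,Number=A,Type=Integer,Description=\"Distance in bp to nearest coding sequence over transcripts\">",
    "##INFO=<ID=MANE_CODING,Number=A,Type=Integer,Description=\"1 if coding on the MANE transcript\">",
    "##INFO=<ID=CLINVAR,Number=A,Type=String,Description=\"ClinVar classification\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  info <- sprintf("CADD_PHRED=%s;POP_AF=%s;GENE=%s;CODING_DIST=%d;MANE_CODING=%d;CLINVAR=%s",
                  fmt_num(vt$cadd), fmt_num(vt$paf), vt$gene, vt$cdist,
                  as.integer(vt$mane),
                  toupper(sub("conflicting", "CONFLICTING", vt$clinvar)))
  body_for <- function(cols) {
    sm <- matrix(sprintf("%s:%d:%d", gt_str[, cols, drop = FALSE],
                         dp[, cols, drop = FALSE], gq[, cols, drop = FALSE]),
                 nv, length(cols))
    paste("1", vt$pos, ".", vt$ref, vt$alt, ".", "PASS", info, "GT:DP:GQ",
          apply(sm, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(vcf_header, body_for(seq_len(n))), paths$vcf)

  withdrawn <- planted_children[event_types == "withdrawn_trans"]
  if (length(withdrawn) > 0) {
    keep <- which(!samples %in% withdrawn)
    hdr2 <- vcf_header
    hdr2[length(hdr2)] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                  "FILTER", "INFO", "FORMAT", samples[keep]),
                                collapse = "\t")
    paths$vcf_postwithdrawal <- file.path(dir, "cohort_postwithdrawal.vcf")
    writeLines(c(hdr2, body_for(keep)), paths$vcf_postwithdrawal)
  }

  gt <- data.frame(
    event = seq_along(truth),
    type = event_types,
    sample_id = planted_children,
    gene_id = vapply(truth, `[[`, character(1), "gene_id"),
    variants = vapply(seq_along(truth), function(e) {
      ridx <- match(truth[[e]]$pos, vt$pos)
      paste(sprintf("1:%d:%s:%s", vt$pos[ridx], vt$ref[ridx], vt$alt[ridx]),
            collapse = ";")
    }, character(1)),
    intended_phase = c(trans = "in_trans", cis = "in_cis", hom = "hom",
                       withdrawn_trans = "in_trans")[event_types],
    intended_priority = c(trans = "Top", cis = "Exclude", hom = "Top",
                          withdrawn_trans = "Closed")[event_types],
    stringsAsFactors = FALSE)
  if (nrow(gt) == 0) {
    gt <- data.frame(event = integer(0), type = character(0),
                     sample_id = character(0), gene_id = character(0),
                     variants = character(0), intended_phase = character(0),
                     intended_priority = character(0))
  }
  utils::write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = paths, ground_truth = gt, config = config)
}

mendelian_consistent <- function(child, father, mother) {
  if (anyNA(c(child, father, mother))) return(TRUE)
  for (a in 0:1) for (b in 0:1) {
    ok_a <- if (a == 1) father >= 1 else father <= 1
    ok_b <- if (b == 1) mother >= 1 else mother <= 1
    if (ok_a && ok_b && a + b == child) return(TRUE)
  }
  FALSE
}

#' Validate a simulated fixture against its own contracts
#'
#' Checks (1) Mendelian consistency of every trio genotype at every site,
#' (2) Hardy-Weinberg proportions of background sites (chi-square, alpha =
#' 0.001, at sites with adequate expected counts; a clean simulation may
#' show a false positive in about one site per thousand, so HWE counts as a
#' violation only if more than 1\% of testable sites fail), and (3) that
#' every planted genotype is present in the intended sample.
#'
#' @param sim the list returned by [simulate_cohort()].
#' @return list of class `fixture_report` with elements `violations`
#'   (character vector; empty for a clean fixture), `n_mendelian_checked`,
#'   `hwe` (per-site p-values).
#' @export
validate_fixture <- function(sim) {
  regions <- read_gene_regions(sim$paths$bed)
  v <- read_cohort_vcf(sim$paths$vcf, regions)
  ped <- read_pedigree(sim$paths$ped)
  violations <- character(0)

  trios <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id), , drop = FALSE]
  n_checked <- 0L
  for (t in seq_len(nrow(trios))) {
    ch <- trios$sample_id[t]; fa <- trios$father_id[t]; mo <- trios$mother_id[t]
    if (!all(c(ch, fa, mo) %in% v$samples)) next
    for (i in seq_len(nrow(v$tab))) {
      n_checked <- n_checked + 1L
      if (!mendelian_consistent(v$dosage[i, ch], v$dosage[i, fa],
                                v$dosage[i, mo])) {
        violations <- c(violations,
                        sprintf("mendelian: site %s child %s",
                                variant_key(v$tab[i, ]), ch))
      }
    }
  }

  planted_keys <- unlist(strsplit(sim$ground_truth$variants, ";"))
  keys <- variant_key(v$tab)
  for (e in seq_len(nrow(sim$ground_truth))) {
    if (sim$ground_truth$type[e] == "withdrawn_trans" &&
        !is.null(sim$paths$vcf_postwithdrawal)) {
      ## planted genotypes checked in the scoring VCF; sample later withdrawn
    }
    ev_keys <- strsplit(sim$ground_truth$variants[e], ";")[[1]]
    s <- sim$ground_truth$sample_id[e]
    want <- if (sim$ground_truth$type[e] == "hom") 2L else 1L
    for (k in ev_keys) {
      i <- match(k, keys)
      if (is.na(i) || is.na(v$dosage[i, s]) || v$dosage[i, s] != want) {
        violations <- c(violations,
                        sprintf("planted genotype missing: %s in %s", k, s))
      }
    }
  }

  bg <- !keys %in% planted_keys
  hwe_p <- rep(NA_real_, nrow(v$tab))
  for (i in which(bg)) {
    d <- v$dosage[i, ]
    d <- d[!is.na(d)]
    nn <- length(d)
    if (nn == 0L) next
    p <- sum(d) / (2 * nn)
    if (p <= 0 || p >= 1) next
    exp_counts <- nn * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (exp_counts[2] < 5) next
    obs <- tabulate(d + 1L, 3L)
    hwe_p[i] <- stats::pchisq(sum((obs - exp_counts)^2 / exp_counts),
                              df = 1, lower.tail = FALSE)
  }
  testable <- sum(!is.na(hwe_p))
  n_fail <- sum(hwe_p < 0.001, na.rm = TRUE)
  if (testable > 0 && n_fail / testable > 0.01) {
    violations <- c(violations,
                    sprintf("hwe: %d of %d testable sites fail at alpha=0.001",
                            n_fail, testable))
  }

  structure(list(violations = violations, n_mendelian_checked = n_checked,
                 hwe = hwe_p),
            class = "fixture_report")
}

#' @export
print.fixture_report <- function(x, ...) {
  cat(sprintf("<fixture_report> %d Mendelian checks, %d violation(s)\n",
              x$n_mendelian_checked, length(x$violations)))
  if (length(x$violations) > 0) {
    cat(paste0("  - ", utils::head(x$violations, 10), collapse = "\n"), "\n")
  }
  invisible(x)
}
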