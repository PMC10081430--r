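test_that("candidate extraction keeps carried CADD>=15 variants in genomic order", {
  v <- make_variants(4, c("S1", "S2"), "G1",
                     cadd = c(22, 16, 14.9, 30),
                     gene_ids = rep(list("G1"), 4),
                     dosage = matrix(c(1L, 1L, 1L, 0L,
                                       0L, 0L, 0L, 1L), 4, 2))
  cs <- extract_candidates(v, "S1", "G1")
  expect_false(cs$closed)
  expect_equal(cs$tab$cadd_phred, c(22, 16))  # 14.9 fails, 30 not carried
  expect_true(!is.unsorted(cs$tab$pos))

  closed <- extract_candidates(v, "GONE", "G1")
  expect_true(closed$closed)
  expect_equal(nrow(closed$tab), 0L)
})

test_that("trio transmission recovers phase in the canonical configurations", {
  # variant A het in father only, B het in mother only -> in trans
  expect_equal(phase_pair(c(1L, 1L), father = c(1L, 0L), mother = c(0L, 1L))$phase,
               "in_trans")
  # both variants het in father, absent in mother -> in cis
  expect_equal(phase_pair(c(1L, 1L), father = c(1L, 1L), mother = c(0L, 0L))$phase,
               "in_cis")
  # missing parents -> unknown
  expect_equal(phase_pair(c(1L, 1L))$phase, "unknown")
  expect_equal(phase_pair(c(1L, 1L), father = c(1L, 0L), mother = NULL)$phase,
               "unknown")
  # both parents het everywhere -> ambiguous
  expect_equal(phase_pair(c(1L, 1L), father = c(1L, 1L), mother = c(1L, 1L))$phase,
               "unknown")
  # Mendelian-inconsistent: neither parent carries variant A
  expect_warning(
    res <- phase_pair(c(1L, 1L), father = c(0L, 1L), mother = c(0L, 0L)),
    "inconsistent")
  expect_equal(res$phase, "unknown")
  expect_false(res$mendelian_consistent)
  expect_error(phase_pair(c(2L, 1L), c(1L, 1L), c(1L, 1L)), "het/het")
})

test_that("phase calls match the exhaustive transmission oracle on all trio configurations", {
  for (fa in 0:2) for (fb in 0:2) for (ma in 0:2) for (mb in 0:2) {
    expected <- oracle_phase(c(fa, fb), c(ma, mb))
    got <- suppressWarnings(
      phase_pair(c(1L, 1L), father = c(fa, fb), mother = c(ma, mb)))
    expect_equal(got$phase, expected$phase,
                 info = sprintf("father=(%d,%d) mother=(%d,%d)", fa, fb, ma, mb))
    expect_equal(got$mendelian_consistent, expected$consistent,
                 info = sprintf("father=(%d,%d) mother=(%d,%d)", fa, fb, ma, mb))
  }
})

test_that("deprioritization flags fire per the flag definitions", {
  # single het variant only
  single <- make_candidates(dosage = c(1L, 0L))
  expect_equal(compute_flags(single$cs, single$v), "no_second_hit")
  # homozygous variant common in the callset (strict > 5%)
  common <- make_candidates(dosage = 2L, callset_af = 0.06)
  expect_equal(compute_flags(common$cs, common$v), "common_in_callset")
  at_thr <- make_candidates(dosage = 2L, callset_af = 0.05)
  expect_equal(compute_flags(at_thr$cs, at_thr$v), character(0))
  # non-coding on MANE
  nc <- make_candidates(dosage = 2L, mane = FALSE)
  expect_equal(compute_flags(nc$cs, nc$v), "noncoding_mane")
})

test_that("an in-cis-only pairing is flagged through pedigree phasing", {
  # child het/het, both variants inherited from the father
  fx <- make_candidates(dosage = c(1L, 1L), samples = c("KID", "DAD", "MUM"),
                        sample_id = "KID")
  v <- fx$v
  v$dosage[, "DAD"] <- c(1L, 1L)
  v$dosage[, "MUM"] <- c(0L, 0L)
  ped <- data.frame(family_id = "F1", sample_id = c("KID", "DAD", "MUM"),
                    father_id = c("DAD", NA, NA), mother_id = c("MUM", NA, NA),
                    sex = c(1L, 1L, 2L), phenotype = c(2L, 1L, 1L))
  cs <- extract_candidates(v, "KID", "G1")
  expect_equal(compute_flags(cs, v, pedigree = ped), "in_cis")
  # one allele from each parent: no flag
  v$dosage[, "DAD"] <- c(1L, 0L)
  v$dosage[, "MUM"] <- c(0L, 1L)
  expect_equal(compute_flags(cs, v, pedigree = ped), character(0))
})

test_that("non-segregation in affected relatives is flagged only when assessable", {
  fx <- make_candidates(dosage = 2L, samples = c("A1", "A2", "UN"),
                        sample_id = "A1")
  v <- fx$v
  v$dosage[, "A2"] <- 0L  # affected sib does not carry the homozygote
  v$dosage[, "UN"] <- 0L
  ped <- data.frame(family_id = "F1", sample_id = c("A1", "A2", "UN"),
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = 1L, phenotype = c(2L, 2L, 1L))
  parts <- data.frame(sample_id = c("A1", "A2", "UN"),
                      affected = c(TRUE, TRUE, FALSE))
  parts$hpo_terms <- list(character(0), character(0), character(0))
  parts$diagnosis_gene <- NA_character_
  cs <- extract_candidates(v, "A1", "G1")
  expect_equal(compute_flags(cs, v, pedigree = ped, participants = parts),
               "no_segregation")
  # sib shares the homozygote: flag cannot fire
  v$dosage[, "A2"] <- 2L
  expect_equal(compute_flags(cs, v, pedigree = ped, participants = parts),
               character(0))
  # no second affected genotyped member: flag cannot fire either
  parts$affected <- c(TRUE, FALSE, FALSE)
  v$dosage[, "A2"] <- 0L
  expect_equal(compute_flags(cs, v, pedigree = ped, participants = parts),
               character(0))
})

test_that("priority tiers follow the first-match decision table", {
  # homozygous pathogenic, clean -> Top
  expect_equal(assign_priority(character(0), "P", phase = "hom"), "Top")
  # in-trans P/LP pair, MANE-coding -> Top
  expect_equal(assign_priority(character(0), c("P", "LP"), phase = "in_trans"),
               "Top")
  # LP + VUS pair, phase unknown -> Middle
  expect_equal(assign_priority(character(0), c("LP", "VUS"), phase = "unknown"),
               "Middle")
  # LP + P pair with a non-MANE-coding member -> Low
  expect_equal(assign_priority("noncoding_mane", c("LP", "P"),
                               phase = "in_trans"), "Low")
  # ACMG curation can substitute for a missing ClinVar class
  expect_equal(assign_priority(character(0), c("absent", "absent"),
                               acmg = c("P", "LP"), phase = "in_trans"), "Top")
  # any hard flag wins
  for (fl in c("common_in_callset", "no_segregation", "in_cis", "no_second_hit"))
    expect_equal(assign_priority(fl, "P", phase = "hom"), "Exclude")
  # hom VUS: biallelic but no pathogenic support -> Low
  expect_equal(assign_priority(character(0), "VUS", phase = "hom"), "Low")
})

test_that("Top findings never carry a deprioritization flag (property)", {
  hard <- c("common_in_callset", "no_segregation", "in_cis", "no_second_hit")
  set.seed(41)
  for (rep in 1:300) {
    flags <- sample(c(hard, "noncoding_mane"),
                    sample(0:3, 1))
    cls <- sample(c("P", "LP", "VUS", "LB", "B", "absent"),
                  sample(1:2, 1), replace = TRUE)
    phase <- sample(c("hom", "in_trans", "unknown"), 1)
    pr <- assign_priority(flags, cls, phase = phase)
    if (pr == "Top") expect_equal(length(intersect(flags, c(hard, "noncoding_mane"))), 0L)
    if (length(intersect(flags, hard)) > 0) expect_equal(pr, "Exclude")
  }
})

test_that("a clean biallelic configuration is not excluded by a common bystander variant", {
  # hom P plus an unrelated common benign het in the same gene
  fx <- make_candidates(dosage = c(2L, 1L),
                        cadd = c(35, 20),
                        clinvar = c("P", "B"),
                        callset_af = c(0.002, 0.2))
  pairs <- data.frame(sample_id = "S1", gene_id = "G1")
  f <- prioritize(pairs, fx$v)
  expect_equal(f$priority, "Top")
  expect_equal(f$flags, "")
  expect_equal(f$variants, genepyr:::variant_key(fx$cs$tab[1, ]))
})

test_that("prioritize reports Closed for samples withdrawn from the callset", {
  fx <- make_candidates(dosage = 2L)
  pairs <- data.frame(sample_id = "WITHDRAWN", gene_id = "G1")
  f <- prioritize(pairs, fx$v)
  expect_equal(f$priority, "Closed")
  expect_equal(f$variants, "")
})

test_that("raising the common-variant threshold never demotes a finding from Top to Exclude", {
  set.seed(43)
  for (rep in 1:40) {
    n <- sample(1:3, 1)
    fx <- make_candidates(dosage = sample(1:2, n, TRUE),
                          cadd = runif(n, 16, 45),
                          clinvar = sample(c("P", "LP", "VUS"), n, TRUE),
                          mane = runif(n) < 0.8,
                          callset_af = runif(n, 0, 0.15))
    pairs <- data.frame(sample_id = "S1", gene_id = "G1")
    lo <- prioritize(pairs, fx$v, callset_af_threshold = 0.03)$priority
    hi <- prioritize(pairs, fx$v, callset_af_threshold = 0.10)$priority
    if (lo == "Top") expect_true(hi != "Exclude")
    # and a finding passing the strict threshold cannot newly acquire the flag
    expect_false(lo != "Exclude" && hi == "Exclude")
  }
})

test_that("findings serialize to TSV and JSON-lines", {
  fx <- make_candidates(dosage = 2L)
  f <- prioritize(data.frame(sample_id = "S1", gene_id = "G1"), fx$v)
  tsv <- tempfile(fileext = ".tsv"); jsonl <- tempfile(fileext = ".jsonl")
  write_findings(f, tsv, jsonl)
  expect_equal(read.delim(tsv)$priority, f$priority)
  line <- jsonlite::fromJSON(readLines(jsonl)[1])
  expect_equal(line$priority, f$priority)
})
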