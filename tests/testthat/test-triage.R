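test_that("the OBO reader recovers terms, parents and depths", {
  ont <- read_hpo_obo(write_test_obo(tempfile(fileext = ".obo")))
  expect_equal(length(ont$ids), 7L)  # obsolete term skipped
  expect_false("HP:0009999" %in% ont$ids)
  expect_equal(unname(ont$depth[c("HP:0000001", "HP:0000010", "HP:0000100",
                                  "HP:0001000")]),
               c(0L, 1L, 2L, 3L))
})

test_that("ancestor closure keeps specific terms only and warns on unknown IDs", {
  ont <- read_hpo_obo(write_test_obo(tempfile(fileext = ".obo")))
  cl <- hpo_closure("HP:0001000", ont)
  expect_setequal(cl, c("HP:0001000", "HP:0000100"))  # root & systems removed
  expect_warning(cl2 <- hpo_closure(c("HP:0000100", "HP:9999999"), ont),
                 "not in ontology")
  expect_equal(cl2, "HP:0000100")
})

test_that("stratification drops unaffected and flags insufficient phenotype", {
  p <- tempfile()
  writeLines(c("sample_id\taffected\thpo_terms\tdiagnosis_gene\tdiagnosis_variants",
               "UND\t1\tHP:0000100;HP:0000101;HP:0000200\t\t",
               "PAR\t0\tHP:0000100\t\t",
               "EMP\t1\t\t\t",
               "DIA\t1\tHP:0000100\tG1\t"), p)
  s <- stratify(read_participants(p))
  expect_equal(as.character(s$stratum),
               c("undiagnosed", "unaffected_dropped", "insufficient_hpo",
                 "diagnosed"))
  # a stricter sufficiency threshold reclassifies sparse phenotypes
  s2 <- stratify(read_participants(p), min_hpo_terms = 2)
  expect_equal(as.character(s2$stratum[4]), "insufficient_hpo")
})

test_that("diagnosis-in-top-gene is a simple membership check", {
  expect_true(diagnosis_in_top_gene("CFTR", c("CFTR", "X")))
  expect_false(diagnosis_in_top_gene("DMD", c("CFTR", "X")))
  expect_false(diagnosis_in_top_gene("CFTR", character(0)))
})

test_that("phenotype overlap matches via ancestors and respects the ACMG incidental route", {
  ont <- read_hpo_obo(write_test_obo(tempfile(fileext = ".obo")))
  # direct match
  expect_equal(phenotype_overlap(c("HP:0000100", "HP:0000200"),
                                 c("HP:0000100", "HP:0000101"), ont),
               "overlap")
  # subtype matches its parent feature through the closure, but not without it
  expect_equal(phenotype_overlap("HP:0001000", "HP:0000100", ont), "overlap")
  expect_equal(phenotype_overlap("HP:0001000", "HP:0000100", ont,
                                 use_ancestors = FALSE), "no_overlap")
  # shared depth-1 system term is too unspecific to count
  expect_equal(phenotype_overlap("HP:0000100", "HP:0000101", ont), "no_overlap")
  # disjoint sets: incidental only when the gene is ACMG-listed
  expect_equal(phenotype_overlap("HP:0000100", "HP:0000200", ont,
                                 acmg_incidental = TRUE), "acmg_incidental")
  # overlap takes precedence over the incidental route
  expect_equal(phenotype_overlap("HP:0000100", "HP:0000100", ont,
                                 acmg_incidental = TRUE), "overlap")
})

test_that("enlarging a patient's HPO set never flips overlap to no_overlap", {
  ont <- read_hpo_obo(write_test_obo(tempfile(fileext = ".obo")))
  leaves <- ont$ids[ont$depth >= 2]
  set.seed(31)
  for (rep in 1:50) {
    patient <- sample(leaves, sample(1:2, 1))
    gene <- sample(leaves, sample(1:3, 1))
    v1 <- phenotype_overlap(patient, gene, ont)
    grown <- unique(c(patient, sample(leaves, 1)))
    v2 <- phenotype_overlap(grown, gene, ont)
    if (v1 == "overlap") expect_equal(v2, "overlap")
  }
})

test_that("triage partitions every top-ranked pair into exactly one category", {
  run <- shared_run()
  verdicts <- run$verdicts
  expect_equal(nrow(verdicts), nrow(run$topsets))
  expect_false(anyNA(verdicts$category))
  expect_equal(sum(table(verdicts$category)), nrow(verdicts))
})

test_that("the override table supersedes the automatic verdict in both directions", {
  sim <- shared_sim()
  run <- shared_run()
  verdicts <- run$verdicts
  auto_overlap <- verdicts[verdicts$category == "overlap", ][1, ]
  auto_no <- verdicts[verdicts$category == "no_overlap", ][1, ]
  ov_path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tverdict",
               sprintf("%s\t%s\tno_overlap", auto_overlap$sample_id,
                       auto_overlap$gene_id),
               sprintf("%s\t%s\toverlap", auto_no$sample_id, auto_no$gene_id)),
             ov_path)
  verdicts2 <- triage(run$topsets, read_participants(sim$paths$participants),
                      read_gene_phenotypes(sim$paths$gene_phenotypes),
                      read_hpo_obo(sim$paths$obo),
                      overrides = read_override_table(ov_path))
  pick <- function(v, s, g)
    as.character(v$category[v$sample_id == s & v$gene_id == g])
  expect_equal(pick(verdicts2, auto_overlap$sample_id, auto_overlap$gene_id),
               "no_overlap")
  expect_equal(pick(verdicts2, auto_no$sample_id, auto_no$gene_id), "overlap")
})
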