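test_that("deleteriousness normalization maps CADD phred onto [0, 1]", {
  m <- deleteriousness_model()
  expect_equal(deleteriousness(0, m), 0)
  expect_equal(deleteriousness(99, m), 1)
  expect_equal(deleteriousness(24.75, m), 0.25)
  expect_equal(deleteriousness(150, m), 1)  # capped
  expect_equal(deleteriousness(24.75, deleteriousness_model("raw_phred")), 24.75)
  expect_error(deleteriousness(-1, m), ">= 0")
})

test_that("allele frequencies follow source priority, fallback and flooring", {
  v <- make_variants(3, "S1", "G1", pop_af = c(0.01, NA, 0),
                     callset_af = c(0.2, 0.3, 0.4))
  fr <- allele_frequencies(v, frequency_policy())
  expect_equal(fr$f_alt, c(0.01, 1e-5, 1e-5))
  expect_equal(fr$f_ref, c(0.99, 1 - 1e-5, 1 - 1e-5))
  # fallback to within-callset frequency when enabled
  fr2 <- allele_frequencies(v, frequency_policy(fallback_to_callset = TRUE))
  expect_equal(fr2$f_alt[2], 0.3)
  # all outputs strictly positive: log10 can never diverge
  expect_true(all(fr$f_alt > 0 & fr$f_ref > 0))
})

test_that("per-variant score matches hand-evaluated values of the equation", {
  expect_equal(variant_score(0.5, 0.01, 0.99, 2L), 2.0)
  expect_equal(variant_score(0.5, 0.01, 0.99, 1L), 0.5 * -log10(0.0099))
  expect_equal(variant_score(0.5, 0.01, 0.99, 1L), 1.00218, tolerance = 1e-5)
  expect_equal(variant_score(0, 0.01, 0.99, 2L), 0)   # zero deleteriousness
  expect_equal(variant_score(0.7, 0.01, 0.99, 0L), 0) # hom-ref
  expect_equal(variant_score(0.7, 0.01, 0.99, NA), 0) # missing call
  expect_error(variant_score(0.5, 0, 0.99, 1L), "frequencies")
})

test_that("gene score is additive and agrees with a per-variant oracle", {
  v <- make_variants(2, "S1", "G1",
                     cadd = c(49.5, 49.5),  # D = 0.5
                     pop_af = c(0.01, 0.01),
                     dosage = matrix(c(2L, 1L), 2, 1),
                     gene_ids = list("G1", "G1"))
  expect_equal(gene_score("S1", "G1", v), 2.0 + 0.5 * -log10(0.0099))
  expect_equal(gene_score("S1", "NOPE", v), 0)

  set.seed(3)
  v2 <- make_variants(15, c("S1", "S2"), c("G1", "G2"), seed = 3)
  expect_equal(gene_score("S2", "G1", v2),
               oracle_matrix(v2, c("G1", "G2"))["S2", "G1"])
})

test_that("the fitted matrix equals the brute-force oracle cell by cell", {
  v <- make_variants(10, c("S1", "S2"), c("G1", "G2"), seed = 5)
  fit <- genepy(v)
  expect_equal(as.matrix(fit), oracle_matrix(v, colnames(fit$scores)),
               tolerance = 1e-12)

  # hom-ref-everywhere sample scores zero in every gene
  v0 <- make_variants(6, c("S1", "S2"), "G1", seed = 6,
                      dosage = rbind(matrix(sample(0:2, 6, TRUE), 3, 2),
                                     matrix(0L, 3, 2)))
  v0$dosage[, "S2"] <- 0L
  expect_true(all(as.matrix(genepy(v0))["S2", ] == 0))

  # permuting variant input order leaves the matrix unchanged
  perm <- sample(nrow(v$tab))
  expect_equal(as.matrix(genepy(subset_variants(v, perm))), as.matrix(fit))

  expect_error(genepy(v, genes = c("G1", "G1")), "duplicate")
})

test_that("score is monotone: decreasing in f_alt, increasing in D, hom >= het", {
  f_grid <- 10^seq(-5, -0.5, length.out = 30)
  for (dos in c(1L, 2L)) {
    s <- variant_score(0.5, f_grid, pmax(1 - f_grid, 1e-5), dos)
    expect_true(all(diff(s) < 0))
  }
  D_grid <- seq(0.05, 1, length.out = 20)
  s <- variant_score(D_grid, 0.01, 0.99, 1L)
  expect_true(all(diff(s) > 0))
  # with the complement rule the homozygote never scores below the het on
  # the minor-allele domain (f_alt <= 1/2, where f_alt^2 <= f_ref * f_alt)
  f <- 10^runif(50, -5, log10(0.5))
  expect_true(all(variant_score(0.4, f, pmax(1 - f, 1e-5), 2L) >=
                    variant_score(0.4, f, pmax(1 - f, 1e-5), 1L)))
})

test_that("matrix cells are nonnegative and adding a qualifying variant never decreases them", {
  v <- make_variants(12, paste0("S", 1:5), c("G1", "G2"), seed = 9)
  base <- as.matrix(genepy(v))
  expect_true(all(base >= 0))
  # append one qualifying carried variant to the same container
  extra <- v
  extra$tab <- rbind(extra$tab, transform(extra$tab[1, ], pos = 9999L,
                                          cadd_phred = 30, pop_af = 1e-4))
  extra$gene_ids <- c(extra$gene_ids, list("G1"))
  extra$dosage <- rbind(extra$dosage, rep(1L, 5))
  extra$depth <- rbind(extra$depth, rep(30L, 5))
  extra$gq <- rbind(extra$gq, rep(80L, 5))
  grown <- as.matrix(genepy(extra, genes = colnames(base)))
  expect_true(all(grown - base >= -1e-12))
})

test_that("matrix TSV output round-trips at full precision", {
  v <- make_variants(8, c("S1", "S2", "S3"), c("G1", "G2"), seed = 10)
  fit <- genepy(v)
  path <- tempfile(fileext = ".tsv")
  write_genepy_matrix(fit, path)
  back <- read_genepy_matrix(path)
  expect_equal(back$scores, fit$scores, tolerance = 1e-12)
  long <- tempfile(fileext = ".tsv")
  write_genepy_matrix(fit, long, format = "long")
  d <- read.delim(long)
  expect_equal(nrow(d), length(fit$scores))
})
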