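# Independent brute-force oracles. Each re-derives the expected result from
# first principles (explicit loops over definitions), never by calling the
# implementation under test.

# Score matrix oracle: evaluates -D * log10(f1 * f2) term by term.
oracle_matrix <- function(v, genes, scale = 99, floor = 1e-5) {
  M <- matrix(0, length(v$samples), length(genes),
              dimnames = list(v$samples, genes))
  for (s in v$samples) {
    for (gi in seq_along(genes)) {
      total <- 0
      for (i in seq_len(nrow(v$tab))) {
        if (!(genes[gi] %in% v$gene_ids[[i]])) next
        d <- v$dosage[i, s]
        if (is.na(d) || d == 0) next
        D <- min(v$tab$cadd_phred[i] / scale, 1)
        f <- v$tab$pop_af[i]
        if (is.na(f)) f <- floor
        f_alt <- min(max(f, floor), 1)
        f1 <- if (d == 2) f_alt else max(1 - f_alt, floor)
        total <- total + D * -log10(f1 * f_alt)
      }
      M[s, gi] <- total
    }
  }
  M
}

# Competition-rank oracle: rank = 1 + number of strictly higher scores.
oracle_ranks <- function(scores) {
  vapply(scores, function(s) 1L + sum(scores > s), integer(1))
}

oracle_top_members <- function(scores, k) {
  names(scores)[oracle_ranks(scores) <= k]
}

# Trio-phase oracle: exhaustive enumeration of parental haplotype
# configurations and transmissions for a het/het child at two loci.
oracle_phase <- function(father, mother) {
  haplotype_pairs <- function(g) {
    out <- list()
    for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
      if (a1 + a2 == g[1] && b1 + b2 == g[2]) {
        out[[length(out) + 1L]] <- list(c(a1, b1), c(a2, b2))
      }
    }
    out
  }
  outcomes <- character(0)
  for (fp in haplotype_pairs(father)) {
    for (mp in haplotype_pairs(mother)) {
      for (fh in fp) {
        for (mh in mp) {
          if (all(fh + mh == c(1, 1))) {
            cis <- all(fh == c(1, 1)) || all(mh == c(1, 1))
            outcomes <- c(outcomes, if (cis) "cis" else "trans")
          }
        }
      }
    }
  }
  if (length(outcomes) == 0L) {
    return(list(phase = "unknown", consistent = FALSE))
  }
  u <- unique(outcomes)
  list(phase = if (length(u) == 1L) c(cis = "in_cis", trans = "in_trans")[[u]]
       else "unknown",
       consistent = TRUE)
}
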