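---
title: "GenePy scoring and biallelic-diagnosis triage: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GenePy scoring and biallelic-diagnosis triage: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene-panel-driven analysis of rare-disease genomes misses diagnoses that lie
outside the chosen panel. Biallelic (recessive) variation is particularly
burdensome to reassess panel-agnostically: every person carries many rare
heterozygous variants, compound heterozygotes demand phase, and pathogenic
evidence is spread across frequency databases, ClinVar and ACMG/AMP
curation. `genepyr` implements a gene-level pathogenicity score — GenePy —
that collapses each individual's qualifying variants in a gene into one
number, so that a large cohort can be ranked per gene and only the handful
of extreme individuals per gene need expert review, followed by an
automated triage and prioritization cascade for those top-ranked
individuals.

# The score

For individual $h$ and gene $g$ with qualifying variants $i = 1..k$:

$$S_{gh} = -\sum_{i=1}^{k} D_i \log_{10}(f_{i1} f_{i2})$$

where $D_i \ge 0$ is the variant's deleteriousness weight and $f_{i1},
f_{i2}$ are the population frequencies of the individual's two alleles at
site $i$. A homozygous-reference genotype contributes nothing
($-D\log_{10}(f_{ref}^2) \approx 0$ for rare alternates, and is defined as
exactly 0 here); a heterozygote contributes $-D \log_{10}(f_{ref}
f_{alt})$; a homozygote $-D \log_{10}(f_{alt}^2)$ — the "one point / two
points" zygosity semantics: as $f_{ref} \to 1$ the homozygote scores
exactly twice the heterozygote. The score is additive over variants, grows
as alleles get rarer ($-\log_{10} f$) and as variants get more damaging
($D$), and is deliberately *not* comparable between genes — only between
individuals within a gene.

## Deleteriousness $D$

CADD phred scores are the input metric. How a phred score maps onto $D$ is
a modelling convention rather than part of the score's definition, so
`deleteriousness_model()` makes it explicit and swappable:

* `normalized_phred` (default): $D = \min(\mathrm{CADD}/99,\ 1)$, keeping
  $D \in [0, 1]$ so the weight acts as a fraction of the frequency
  surprisal. 99 is the ceiling of the phred scale.
* `raw_phred`: $D = \mathrm{CADD}$, for users who prefer unnormalized
  weights (scores scale linearly; rankings within a gene are unchanged
  for a fixed variant set).

This choice is flagged prominently because it changes absolute score
values (not per-gene rankings' qualitative behaviour).

## Allele frequencies and the floor

Frequencies come from a reference population database (a gnomAD-style
`POP_AF` annotation). `frequency_policy()` controls:

* `source_priority`: an ordered list of frequency fields; the first
  non-missing value wins (e.g. two gnomAD releases in order of
  preference).
* `fallback_to_callset`: optionally fall back to the within-cohort
  frequency when no reference value exists (off by default; the cohort is
  not a population reference).
* `floor` (default $10^{-5}$): every frequency is clamped to
  $[\mathrm{floor}, 1]$, and the reference-allele complement $1 -
  f_{alt}$ is floored the same way, so $\log_{10}$ can never diverge on
  variants absent from the reference panel. $10^{-5}$ is roughly one
  allele in a large reference panel; it caps the per-allele surprisal at 5
  score units.

One caveat documented here because it is occasionally surprising: the
homozygote-scores-at-least-the-heterozygote relation holds on the
minor-allele domain ($f_{alt} \le 1/2$, since $f_{alt}^2 \le f_{ref}
f_{alt}$ exactly when $f_{alt} \le f_{ref}$). For alternate alleles that
are the *major* allele the heterozygote can score slightly higher; such
variants are common and score near zero either way.

# Quality control and variant selection

All thresholds are exposed; the defaults are the ones used throughout this
package's validation:

| parameter | default | semantics |
|---|---|---|
| `min_depth` | 10 | per-genotype read depth, inclusive |
| `min_gq` | 20 | per-genotype quality, inclusive |
| `min_mean_gq` | 35 | per-site mean GQ over retained genotypes, **strict** (> 35) |
| `min_call_rate` | 0.70 | fraction of cohort genotyped, inclusive |
| `max_coding_distance` | 8 bp | distance to coding sequence on the most favorable transcript |
| `min_cadd` | 15 | CADD phred threshold for scoring and for candidate extraction |

Order matters and is fixed: genotype-level QC first (failing calls become
missing), then site-level QC computed over the *retained* genotypes.
Computing mean GQ after removing low-GQ calls is a genuine design choice —
the alternative (raw mean) admits sites whose good calls are a thin
majority; the chosen order is the stricter, and is what the per-genotype
filter semantics imply. Missing calls contribute zero to scores (a missing
genotype cannot add pathogenicity burden) but count against the call rate.
Multi-allelic records are decomposed into biallelic variants before any QC
so that per-allele frequencies are well defined; haploid calls (chrX in
males) default to homozygous-equivalent dosage 2 (`hemizygous = "hom"`),
configurable to 1.

The CADD ≥ 15 selection is noise control: without it, long genes accumulate
many small contributions from rare benign variants and their top ranks stop
being enriched for true biallelic damage.

# Ranking and top-k outlier selection

Within each gene all individuals are ranked by descending score with
**competition ("1224") ranks**: tied individuals share the minimal rank and
the next distinct score's rank counts all strictly higher individuals.
`top_k()` (default `k = 5`) retains everyone with rank ≤ k, so a tie
straddling rank k retains more than k individuals — dense ranking would
silently enlarge top sets beyond this semantics, which is why competition
ranking was chosen. k = 5 is an operating point, not an estimate; it is a
plain parameter. Ties at score zero are retained like any tie (in small
cohorts a gene with fewer than k nonzero scorers therefore top-ranks many
zero-score individuals; downstream triage absorbs them).

# Triage

Every top-ranked (sample, gene) pair receives exactly one verdict, so the
verdict counts partition the pair count (the "funnel" each run's manifest
records):

1. unaffected individuals are dropped regardless of phenotype;
2. affected individuals with fewer than `min_hpo_terms` (default 1)
   recorded HPO terms are set aside as phenotypically insufficient — the
   sufficiency threshold is a parameter because no principled universal
   value exists;
3. already-diagnosed individuals are classed by whether their diagnosis
   gene is itself top-ranked (a concordance check of the score against
   known answers);
4. undiagnosed individuals are screened for phenotype overlap between
   their HPO terms and the implicated gene's characteristic phenotype.

In the study design this package automates, phenotype matching was expert
manual review. The automated stand-in counts HPO terms shared directly or
through the ontology ancestor closure, excluding the root and all
depth < 2 terms (near-root terms like "abnormality of the nervous system"
are too unspecific to count as evidence); `min_shared` (default 1) sets
the threshold. This is a documented methodological departure, with two
escape hatches: an override table of per-(sample, gene) verdicts that
always supersedes the automatic call, and `use_ancestors = FALSE` for
exact-match-only screening. Non-overlapping pairs whose gene is on the
ACMG incidental-findings list are routed to a separate
`acmg_incidental` verdict (overlap takes precedence over the incidental
route: a phenotype match is a candidate diagnosis, not an incidental
finding).

# Prioritization

For each phenotype-matched pair, all variants the individual carries in
the gene with CADD ≥ 15 are extracted (no coding-distance requirement
here — non-coding candidates are handled by flags, not silently dropped).
A sample absent from the callset at this stage yields a **Closed** finding
(the participant withdrew after scoring; the simulator reproduces this by
emitting a post-withdrawal callset).

## Phase by trio transmission

For a het/het pair in a proband with both parents genotyped, each parent
can transmit an alternate allele iff their dosage ≥ 1 and a reference
allele iff their dosage ≤ 1. Enumerating the four possible parental
origins of the two alternates gives the set of consistent transmissions:
all-trans → `in_trans`, all-cis → `in_cis`, both possible → `unknown`,
none → Mendelian-inconsistent (`unknown` with a warning, rather than a
hard error, since genotyping error is the usual cause). Parental phase
never needs to be known: a parent het at both sites can transmit any
combination under some phase, which is exactly why double-het parents
yield `unknown`. This per-locus rule is provably equivalent to exhaustive
haplotype enumeration (the test suite checks all 81 parental genotype
configurations against an independent enumeration oracle). No
statistical or read-backed phasing is attempted.

## Flags and tiers

Five deprioritization flags: `noncoding_mane` (a variant is non-coding on
the MANE transcript), `common_in_callset` (within-callset allele frequency
strictly above 5%), `in_cis`, `no_segregation` (an affected genotyped
relative lacks the candidate genotype; only assessable in families with
≥ 2 affected genotyped members), `no_second_hit` (no homozygote and no
second het). The tier rules, first match wins:

1. any of `common_in_callset`, `no_segregation`, `in_cis`,
   `no_second_hit` → **Exclude**;
2. a biallelic genotype — homozygous or in-trans-phased pair — of
   all-P/LP (ClinVar or ACMG), all-MANE-coding variants → **Top**;
3. a biallelic configuration, all MANE-coding, with ≥ 1 P/LP variant but
   unknown phase or a VUS partner → **Middle** (an unphased pair is
   presumed-possible in trans: Middle at best, never Top);
4. anything else biallelic, including any non-MANE-coding contributor →
   **Low**.

Two deliberate design choices here. First, the exact decision table is a
reconstruction from the tier and flag descriptions, not a published
algorithm; it therefore lives in an editable YAML file
(`inst/extdata/priority_rules.yaml`, loadable via `priority_rules()`).
Second, flags are evaluated **per biallelic configuration** (each
homozygote; each non-cis het pair) and the finding reports the best
configuration — a common benign bystander variant in the gene must not
exclude an otherwise clean homozygous pathogenic finding. The exported
`compute_flags()` retains whole-candidate-set semantics for users who want
the conservative reading. ACMG/AMP classes are consumed as per-variant
annotations (`ACMG` INFO field); no classification engine is implemented.

# The synthetic cohort

Real study cohorts of this design are access-restricted, so the package
carries its own generator with known ground truth. What it emulates:

* cohort structure: father-mother-child trios (children affected, parents
  unaffected) plus singletons, with ~45% of the cohort unaffected and a
  subset of affected singletons carrying prior diagnoses;
* a log-uniform rare-variant population AF spectrum on $[10^{-5}, 0.5]$
  and gamma-distributed background CADD (most background variants below
  the CADD-15 threshold);
* Hardy-Weinberg founder genotypes and Mendelian transmission to
  children (validated by `validate_fixture()`: per-site chi-square HWE
  sanity at $\alpha = 0.001$ and exhaustive trio Mendelian checks);
* planted events in trio probands: in-trans P/LP pairs and homozygous
  P/LP variants (intended Top), in-cis decoy pairs placed on one parental
  haplotype (intended Exclude via trio phasing), and optionally a proband
  withdrawn after scoring (intended Closed). Planted variants are drawn
  from the rare damaging corner: CADD uniform on (30, 45), AF log-uniform
  on $(10^{-5}, 10^{-4})$, MANE-coding, ClinVar P/LP;
* DP/GQ distributions that straddle the QC thresholds, ~3% of background
  sites engineered to fail site QC, and ~1% missing genotypes;
* a miniature 3-level HPO-style ontology (49 terms) and per-gene
  phenotype sets; proband HPO terms are drawn from their planted gene's
  set with configurable noise.

What it does **not** emulate, hence what passing tests do not show:
linkage disequilibrium and realistic haplotype structure, sequencing-read
noise beyond DP/GQ, population stratification, CNVs/structural variation,
and real HPO semantics (the real ontology is supported as input but not
shipped). One further deliberate idealization: background variants inside
planted genes are capped below CADD 15, so each planted configuration is
the only qualifying variant set in its gene and its intended priority is
unambiguous — without this, a random rare het beside a cis decoy would
legitimately form an unphaseable pair and earn Middle. Recovery rates on
this generator are therefore an upper bound on real-data behaviour.

Everything is deterministic given `seed`: outputs are byte-identical
across runs.

# Validation problem sizes

The test suite validates scoring against an independent brute-force
evaluation of the equation on 100 random cohorts (≤ 20 samples, ≤ 5
genes, ≤ 50 variants; agreement to $10^{-9}$ per cell), ranking against a
counting oracle on 1000 random score vectors, phasing against exhaustive
enumeration on all 81 trio configurations, and end-to-end recovery on 20
simulated cohorts at the default configuration (200 samples, 30 trios, 50
genes): planted in-trans/homozygous P/LP events must rank top-5 and be
assigned Top in ≥ 95% of cases, every in-cis decoy reaching
prioritization must be Excluded, and the withdrawn-proband scenario must
yield Closed. `scripts/acceptance.R` recomputes all of these from scratch.

# Known limitations

* Scores are not comparable across genes; no cross-gene normalization is
  provided by design.
* Phase is trio-transmission only; non-trio families leave compound
  heterozygotes `unknown` (capping them at Middle), which mirrors the
  main loss mechanism of the underlying workflow.
* The Middle/Low boundary is a reconstruction; users with different
  evidence standards should edit the YAML rule table.
* The phenotype-overlap stand-in is intentionally simple (shared-term
  count with ancestor closure); no semantic-similarity scoring.
* The dominant/haploinsufficiency use case (single-hit genes, stricter
  CADD cutoffs) is out of scope.
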