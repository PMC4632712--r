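---
title: "Methods: allele-specific miRNA seed-site changes and their enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific miRNA seed-site changes and their enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnp)
```

## The model

MicroRNAs repress transcripts mainly through Watson–Crick pairing of their
seed region — nucleotides 2–8 of the mature strand — with a complementary
site on the mRNA. Such sites are functional in coding sequence as well as in
3ʹ UTRs, which means a coding-region SNP can create or destroy a seed-match
site regardless of whether it changes the encoded amino acid. A synonymous
variant, usually treated as neutral, can therefore rewire post-transcriptional
regulation: one allele is bound and repressed by a miRNA, the other is not.

`mirsnp` operationalizes that model in four stages:

1. **Window construction.** For each SNP, two windows of up to 31 nt are
   built on the mRNA sense strand — 15 nt of flank each side, with the
   respective allele as the central base. Since a seed match spans at most
   8 nt, a 15-nt flank is sufficient for every site that could possibly
   differ between alleles; any site further away is identical in both
   windows and cancels in the comparison.
2. **Seed-site scanning.** Each window is scanned for canonical site
   classes for every catalog miRNA: `6mer` (perfect match to seed 2–7),
   `7mer-m8` (2–8), `7mer-A1` (2–7 plus an `A` opposite miRNA position 1)
   and `8mer-1a` (2–8 plus the `A`). Matching is literal — no G:U wobble,
   no bulges, no context scoring — and positions containing `N` never
   match. When nested variants co-occur at one seed-complement locus, only
   the strongest class is reported (`8mer-1a` > `7mer-m8` > `7mer-A1` >
   `6mer`).
3. **Change classification.** A SNP *changes regulation* iff the set of
   binding miRNAs differs between its two windows; the difference is
   reported as *gained* (binds the b-allele window only) and *lost* (binds
   the a-allele window only). Changes are counted at the miRNA level: a
   variant that moves a site but leaves the miRNA bound in both windows is
   not a change, and variants that merely alter binding affinity are out of
   scope.
4. **Enrichment statistics.** Changed/unchanged status is crossed with
   per-SNP annotations — recent positive selection (|iHS| ≥ 2.5), disease
   association, deleteriousness labels — in 2×2 tables tested by Fisher's
   exact test with the sample odds ratio, backed by a permutation null for
   overlap counts, Wilcoxon rank-sum comparisons of score distributions,
   and a genotype→expression Spearman stage with a gene-level 2×2.

```{r example}
catalog <- seed_catalog("miR-x", "UGGAGUGUGACAAUGGUGUUUG")  # seed 2-8: GGAGUGU
snp <- snp_table(data.frame(
  snp_id = "rs_demo",
  left_flank = "GGGGGGGGGGGACAC", allele_a = "T", allele_b = "G",
  right_flank = "CCGGGGGGGGGGGGG", snp_class = "synonymous"))
classify_snp(snp, catalog)
```

## Tunable parameters

* **Counted site types** (default `8mer-1a`, `7mer-m8`, `7mer-A1`).
  Marginal `6mer` sites are excluded by default — they are weakly effective
  and the tool this scanner emulates does not count them by default — but a
  single switch (`counted_types`) includes them. Enlarging the counted set
  can only add binding miRNAs, never remove them.
* **|iHS| threshold** (default 2.5, inclusive). Scores are standardized, so
  ±2.5 marks roughly the 1.2% two-sided tail; SNPs without a score are
  excluded from the selection universe rather than imputed, because iHS
  panels cover only a fraction of coding SNPs.
* **alpha** (default 0.05) for the expression stage: a gene counts as
  *significant* if **any** of its SNP associations reaches `p ≤ alpha`.
  This mirrors the simplest published procedure and is deliberately
  anti-conservative; no false-discovery-rate adjustment is applied anywhere
  in the package, and all p-values are nominal.
* **n_perm** (default 10,000) and `seed` for the randomization test; the
  empirical p carries the +1 correction, so its floor is `1/(n_perm+1)`.

## Statistical conventions

* **Fisher's exact test** uses the probability-mass two-sided convention
  (the sum of probabilities of all margin-preserving tables no more likely
  than the observed one), which is what R's `fisher.test` computes. The
  `alternative` argument exposes one-sided versions; directional claims
  (e.g. "changing SNPs are *more* often disease-associated") are naturally
  one-sided, and some published analyses of this design report the
  one-sided value, so both are first-class.
* **Odds ratios** are the sample estimator `ad/(bc)`, not the conditional
  MLE that `fisher.test` prints; the sample estimator is what 2×2 screens
  in this literature report. Zero cells give `Inf` (or `NaN` when
  undefined); no continuity correction is applied.
* **Wilcoxon rank-sum** uses the exact distribution for tie-free samples
  up to n = 50 per group and the normal approximation with continuity and
  tie correction beyond.
* **Spearman association** uses average ranks for ties; p-values come from
  the t approximation for n ≥ 10 and from exhaustive permutation of the
  rank assignment below that. With tied dosages, a perfectly monotone
  relation yields the tie-corrected rho < 1 — this is a property of the
  average-rank convention, not an error. Monomorphic genotypes are flagged
  untestable and excluded from the gene-level tally.
* **Randomization test**: each permutation redraws `|changed|` ids without
  replacement from the universe, preserving only set sizes (no matching on
  allele frequency or gene length), so the null is exactly
  hypergeometric — which the suite uses as its closed-form oracle. The
  default tail is upper one-sided, matching the directional question
  "higher overlap than expected?"; `alternative` switches it.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised and validated
at desk scale with known ground truth; its defaults are the study
conditions the pipeline is meant for.

* **Change rate 0.459**: the planted probability that a SNP changes
  regulation, matching the genome-wide fraction reported for synonymous
  SNPs. Planting is *constructive*: for a to-change SNP, a counted
  pattern is written into one allele's window so that the central base
  falls inside the 6-nt seed-complement core, which the other allele
  destroys; for a no-change SNP, random windows are redrawn until both
  alleles bind identical miRNA sets. Every candidate is verified by the
  classifier in-loop, so truth labels agree with `classify_all()` exactly
  by construction — end-to-end tests can demand 100% agreement.
* **iHS**: baseline scores are normal with variance scaled so the
  two-sided tail beyond 2.5 equals 1.24% (a standard normal), which is the
  regime the published selection screens operate in; changing SNPs get a
  location shift (default 0.1) added to |iHS|. Coverage defaults to 15% of
  SNPs, reflecting how sparsely haplotype-based scores cover coding SNPs.
* **Disease**: GWAS-like baseline rate 0.2% with a planted odds ratio
  (default 1.6) on changing SNPs via a log-odds offset. Deleteriousness
  labels cover non-synonymous SNPs at 18% with *no* dependence on change
  status, mirroring the published null result.
* **Expression**: 60 samples; genotypes are Hardy–Weinberg
  `Binomial(2, maf)` with `maf ~ U(0.05, 0.5)`; a fraction (default 10%)
  of genes hosting changing SNPs receives `beta ~ N(0, 1)` genotype
  effects over unit normal noise.

What the generator does **not** emulate: codon structure and real base
composition, linkage disequilibrium between SNPs, population structure,
overlapping genes and splice isoforms, correlated annotation errors, and
expression normalization artifacts. Passing tests therefore demonstrate
that the pipeline's logic and statistics behave as specified under the
assumed sampling model — not that the biological effect sizes would be
recovered from any particular real data set.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only at the VCF
  boundary. Minus-strand variants are reverse-complemented during
  extraction so every downstream module sees mRNA sense.
* Flanks shorter than 15 nt (transcript ends) are scanned as-is and
  flagged (`short_flank`), not dropped; multi-allelic variants are split
  into per-alternate biallelic records.
* Site-report ordering is deterministic (`start`, then miRNA name), and
  every generator and the permutation test are pure functions of their
  seed, so reruns are byte-identical.
* Mature sequences shorter than 8 nt, or with ambiguity codes inside the
  seed, are rejected; duplicate miRNA names and duplicate SNP ids are
  errors, not warnings.
* Degenerate 2×2 tables (a zero margin) return p = 1 with a `degenerate`
  flag rather than erroring, so screens over many strata keep running.
* Catalog simulation redraws duplicated seed heptamers (bounded retries):
  distinct miRNAs sharing a seed would make gain/loss labels ambiguous.
* Test problem sizes: scanner oracle equivalence on 1,000 random
  window/catalog instances, classifier truth recovery on 5,000 planted
  SNPs, annotation-stage parameter recovery on 47,039-SNP universes (the
  synonymous-SNP count of the study design), and permutation nulls of
  2,000–20,000 draws. These sizes keep the full suite in minutes on one
  core while leaving every statistical check well-powered.

## Known limitations

* Only canonical, perfectly complementary seed sites are modeled — no
  3ʹ-supplementary pairing, bulged or wobble sites, no thermodynamic or
  conservation filtering — so the classifier describes *candidate*
  regulatory changes, not validated ones.
* The gene-level expression aggregation ("any SNP significant") inflates
  per-gene significance for genes hosting many SNPs; use the odds ratio
  comparatively, not the absolute percentages.
* Synonymous/non-synonymous class is consumed from input annotation; the
  package does not verify it from codon context.
* The randomization and Fisher tests answer the same question under
  slightly different conditioning; they agree in direction but their
  p-values need not coincide.
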