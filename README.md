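# mirsnp

Coding-region SNPs can rewire microRNA-mediated gene regulation: a single
base change inside a transcript can create or destroy a canonical miRNA
seed-match site, so one allele is bound and repressed while the other is
not. This affects synonymous variants — usually treated as neutral — just
as much as non-synonymous ones. `mirsnp` is for statistical geneticists
and regulatory genomicists who want to classify such variants and test
whether regulation-changing SNPs are preferentially under recent positive
selection, disease-associated, or coupled to expression differences.

## What it computes

For each SNP with alleles $a$ and $b$, two windows of up to 31 nt are built
on the mRNA sense strand (15-nt flanks, the allele as the central base).
Each window is scanned for canonical seed sites of every catalog miRNA —
`8mer-1a`, `7mer-m8`, `7mer-A1` and optionally `6mer`, defined by perfect
complementarity to miRNA seed positions 2–8 (or 2–7) with or without an
`A` opposite position 1. Writing $B(w)$ for the set of miRNAs with a
counted site in window $w$,

- gained $= B(w_b) \setminus B(w_a)$, lost $= B(w_a) \setminus B(w_b)$,
- the SNP **changes regulation** iff gained ∪ lost ≠ ∅.

Changed status is then crossed with per-SNP annotations in 2×2 tables:
selection (|iHS| ≥ 2.5, per population), disease flags, deleteriousness
labels. Each table gets Fisher's exact test (probability-mass two-sided
convention, one-sided available) and the sample odds ratio
$\mathrm{OR} = ad/(bc)$; overlap counts also get an empirical permutation
null (equivalently hypergeometric), score distributions a Wilcoxon
rank-sum test, and the genotype→expression stage Spearman rank
correlations with a gene-level 2×2. A synthetic-data generator with
planted effects (change rate, |iHS| shift, disease odds ratio, eQTL
effects) exercises every stage with known ground truth.

## Worked example

```r
library(mirsnp)

# one miRNA; its seed (positions 2-8) is GGAGUGU, so a 7mer-m8 site on the
# target reads ACACTCC
catalog <- seed_catalog("miR-x", "UGGAGUGUGACAAUGGUGUUUG")

# a SNP whose a-allele window carries that site across the central base
snp <- snp_table(data.frame(
  snp_id = "rs_demo",
  left_flank = "GGGGGGGGGGGACAC", allele_a = "T", allele_b = "G",
  right_flank = "CCGGGGGGGGGGGGG", snp_class = "synonymous"))
classify_snp(snp, catalog)
#> SNP rs_demo: changes miRNA regulation
#>   lost:    miR-x
```

Swapping T for G destroys the only `ACACTCC` match, so miR-x binding is
*lost*: the reference allele is repressed, the alternate is not.

Enrichment on a 2×2 table — here, changed/unchanged × selected/not
(|iHS| ≥ 2.5) counts of a selection screen:

```r
asi <- contingency_2x2(58, 3212, 44, 4972)
cat("OR =", round(odds_ratio(asi), 2), " p =", signif(fisher_exact(asi), 2), "\n")
#> OR = 2.04  p = 0.00047
```

Changed SNPs are about twice as likely to sit under strong recent positive
selection in this screen. And a fully synthetic end-to-end run:

```r
cfg <- sim_config(n_snps = 1000, n_mirnas = 50, seed = 42)
b <- simulate_bundle(cfg)
cl <- classify_all(b$snps, b$catalog)
cl
#> miRNA-regulation change classification
#>   1000 SNP(s), 494 changing regulation
#>   nonsynonymous     248 / 503    changed (49.3%)
#>   synonymous        246 / 497    changed (49.5%)
mean(cl$changes$changed == b$truth$changed)
#> [1] 1
```

The generator plants seed-site changes constructively and verifies them
with the scanner in-loop, so the classifier recovers the truth labels
exactly; the observed changed fraction fluctuates binomially around the
planted rate (0.459). `run_pipeline()` binds classification, selection,
disease, randomization and expression stages into one summary object;
`inst/scripts/mirsnp.R` wraps `simulate` / `classify` / `randomize` /
`run-all` for shell use.

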