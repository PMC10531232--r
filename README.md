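# mammolnc

Discovery, profiling and heritability enrichment of long non-coding RNAs
(lncRNAs) in bovine mammary tissue.

Bulk RNA-seq of the cow mammary gland in its two physiological states — the
dry (non-lactating) period and lactation — yields tens of thousands of
assembled transcripts per condition. A small fraction of them are lncRNAs:
transcripts longer than 200 nt with no evidence of protein-coding capacity.
`mammolnc` is an R package for the full downstream workflow once transcripts
are assembled and quantified: it identifies candidate lncRNAs, profiles
them, tests the candidates shared between conditions for differential
expression, scores sequence conservation, correlates lncRNA expression with
coding genes, and asks — with a two-component genomic REML model — whether
genetic variants near the candidates are enriched for trait heritability.
It is aimed at quantitative geneticists and transcriptomics analysts who
want each of those stages as tested, composable functions rather than a
chain of shell tools.

## The core methods

**Candidate cascade.** A transcript is a candidate lncRNA iff it is
(a) intergenic (its span overlaps no annotated gene span; with two
annotations the intergenic calls are combined by union), (b) longer than
200 nt, (c) non-coding on both strands under an ORF-fraction coding
potential score `2·O/L − 1 < 0` (O = longest ORF, L = length),
(d) free of protein-domain motifs in all six reading frames, and
(e) without homology to known genes under a k-mer-seeded, X-drop-extended
identity screen (≥ 90% identity over ≥ 50% coverage removes the
transcript). Survivors are merged by overlap into contiguous candidates per
condition.

**Differential expression.** Candidates from the two conditions covering
the same locus are paired, presence-filtered (non-zero in ≥ half the
samples per condition), then tested: an F pre-test of the variance ratio at
α = 0.05 chooses between the pooled-variance and Welch t-tests, and calls
are made at strict p < 0.05.

**Heritability enrichment.** With variants QC'd (MAF ≥ 0.005, HWE
p ≥ 1e-8) and partitioned by 10 kb-extended candidate windows, the model

    y = Xb + g1 + g2 + e,   g1 ~ N(0, G1·σ²g1),  g2 ~ N(0, G2·σ²g2),
    e ~ N(0, R·σ²e),        Gk = ZkZkᵀ/mk,       R = diag(1/ri)

is fitted by exact REML (Fisher scoring; optional Monte Carlo trace mode),
and the per-SNP enrichment

    ρ = (σ²g1/m1) / ((σ²g1+σ²g2)/(m1+m2))

is reported with a delta-method SE and a one-sided test of ρ = 1 vs ρ > 1.

Synthetic-data generators produce every input with planted ground truth
(labelled transcript classes, planted fold-changes, piecewise conservation
tracks, genotypes/phenotypes with known true ρ), so the whole pipeline is
validated end to end without downloads. See the methods vignette
(`vignettes/mammolnc-methods.Rmd`) for the modelling details and design
choices.

## Worked example

```r
library(mammolnc)

## 1. Differential expression of the bundled common-lncRNA table
tab <- common_lncrna_table()      # 53 common pairs, mean FPKM + p-value
summarize_de(tab)
#> $total
#> [1] 53
#> $significant
#> [1] 44
#> $up_dry
#> [1] 22
#> $up_lact
#> [1] 22
#> $ns
#> [1] 9
```

Of the 53 common lncRNA pairs, 44 are differentially expressed between the
dry and lactating gland at p < 0.05, split evenly — 22 higher in dry
tissue, 22 higher in lactating tissue — and 9 show no significant change.

```r
## 2. Heritability enrichment on simulated data with planted truth rho = 4
gp  <- sim_genetics(n = 800, m = 4000, m1 = 200,
                    vc = c(g1 = 0.1, g2 = 0.4, e = 0.5), seed = 11)
fit_enrichment(gp$geno, gp$pheno, gp$lnc)
#> Per-SNP heritability enrichment
#>   m1 = 200, m2 = 3800
#>   varcomp: g1 = 0.1176, g2 = 0.295, e = 0.6316
#>   rho = 5.703 (SE 2.335), one-sided p[rho > 1] = 0.022
```

200 of the 4000 variants fall in the 10 kb-extended windows of the
simulated lncRNAs; the fitted enrichment ρ̂ = 5.7 ± 2.3 covers the planted
ρ = 4 well within two standard errors, and the one-sided test correctly
flags enrichment.

```r
## 3. Candidate cascade on a generated transcriptome
gen <- sim_annotation(seed = 7)   # planted classes, one per filter
cs  <- run_cascade(gen$transcripts, gen$annotation, gen$motifs, gen$known)
cs
#> lncRNA candidate cascade
#>       stage input_count survivors
#>  intergenic         100        80
#>      length          80        70
#>   noncoding          70        50
#>      domain          50        40
#>    homology          40        30
#> merged candidates: dry=30
```

Each stage removes exactly its planted class; the 30 survivors are exactly
the transcripts planted as true lncRNAs.

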