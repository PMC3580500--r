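# cpgchrom

Comparative chromatin profiling of CpG-island and non-CpG promoter genes.

Mammalian promoters fall into two broad classes: those embedded in CpG
islands (regions of elevated CpG dinucleotide density and G+C content,
typically unmethylated) and those without. The two classes differ in
chromatin organization — CpG-island promoters tend to carry a constitutive
nucleosome-depleted region (NDR) upstream of the transcription start site
(TSS), distinctive active-mark asymmetry around the TSS, and
expression-coupled positioning of gene-body modifications. Because
CpG-island genes are also, on average, more highly expressed, naive class
comparisons confound promoter sequence class with expression level.

This package implements the complete analysis needed to make that
comparison cleanly, plus a synthetic-data generator with known ground
truth so every stage is testable without external downloads:

- **Promoter classification** — CpG-island overlap at the TSS, and an
  independent sequence-based scan: every 500-bp window in TSS −1,200 to
  +300 is scored by CpG observed/expected ratio,
  o/e = n<sub>CG</sub>·L / (n<sub>C</sub>·n<sub>G</sub>), and GC fraction;
  a promoter is **HCP** (high-CpG) if any window has o/e > 0.75 and
  GC > 55%, **LCP** if every window has o/e ≤ 0.48, **ICP** otherwise.
- **Expression-matched gene sets** — genes are ranked and cut into three
  expression tiers; within each tier, non-CpG genes are paired with CpG
  genes of near-identical expression (|Δ ln expr| ≤ 0.1), removing the
  expression confound from all class comparisons.
- **Dyad tracks** — mapped reads are deduplicated, shifted 75 bp to the
  nucleosome dyad (plus-strand reads to start + 75, minus-strand to
  end − 1 − 75), tallied per base, and depth-rescaled to 10 million
  fragments, with the scale factor carried separately so integer read
  counts are conserved exactly.
- **TSS-anchored profiles** — per-gene, strand-oriented signal matrices
  over TSS −500 to +3,000; per-position averages with loess smoothing
  (180-bp span, exact local regression, ±2 SE band);
  nucleosome-background subtraction in sliding 75-bp windows; GC and
  interval-density profiles; expression-ordered heatmap matrices.
- **Statistics** — promoter **asymmetry score** (fraction of TSS ±500 bp
  signal lying upstream), compared between classes by Wilcoxon rank-sum
  (exact enumeration for small groups, midranks under ties); per-gene
  **peak-shift** analysis (left-most argmax within 2 kb downstream,
  Spearman-correlated with expression rank); **CTCF overlap enrichment**
  across 10 expression bins with Wilson 95% confidence intervals and a
  pooled chi-squared test.

All coordinates are 0-based, half-open (BED convention); minus-strand
genes are handled so that every profile reads in the direction of
transcription. Every random step flows from an explicit seed and reruns
are byte-identical.

## Worked example

Generate a 200-gene synthetic dataset (four read tracks: nucleosome
occupancy, an expression-coupled gene-body mark, an asymmetric promoter
mark, and a control mark with a fixed peak) and run the whole pipeline:

```r
library(cpgchrom)

dir <- tempfile()
make_fixtures(dir, synth_config(n_genes = 200, read_depth = 30000, seed = 41))
cfg <- pipeline_config(
  genes = file.path(dir, "genes.tsv"),
  islands = file.path(dir, "cpg_islands.bed"),
  ctcf = file.path(dir, "ctcf_peaks.bed"),
  promoters = file.path(dir, "promoters.fa"),
  expression = file.path(dir, "expression.tsv"),
  chrom_sizes = file.path(dir, "chrom.sizes"),
  tracks = c(occupancy = file.path(dir, "reads_occupancy.bed"),
             body_mark = file.path(dir, "reads_body_mark.bed"),
             promoter_mark = file.path(dir, "reads_promoter_mark.bed"),
             fixed_mark = file.path(dir, "reads_fixed_mark.bed")),
  out_dir = tempfile(), per_tier = 20, seed = 17)
res <- run_pipeline(cfg)

res$matched
#> Expression-matched gene sets (seed 17, tolerance 0.1 ln units)
#>   high: 20 pairs
#>   low: 20 pairs
#>   medium: 20 pairs

str(res$reports$peak_shift$body_mark_CPG)
#> List of 3
#>  $ rho    : num 0.882
#>  $ p_value: num 1.31e-20
#>  $ n      : int 60

str(res$reports$asymmetry$promoter_mark[c("median_cpg", "median_noncpg", "p_value")])
#> List of 3
#>  $ median_cpg   : num 0.7
#>  $ median_noncpg: num 0.704
#>  $ p_value      : num 0.892

str(res$reports$ctcf[c("chi2_statistic", "chi2_p")])
#> List of 2
#>  $ chi2_statistic: num 19.1
#>  $ chi2_p        : num 1.24e-05
```

The reports recover the generator's design: the gene-body mark, whose peak
centre moves with expression tier (500/800/1,100 bp), shows a strong
peak-shift correlation (ρ = 0.88); the promoter mark, generated with 70%
of its mass upstream, yields median asymmetry scores of ~0.70 in both
matched classes (non-significant difference, as designed); and CTCF sites,
planted preferentially at CpG promoters, give a significant pooled 2×2
chi-squared. The output directory holds the promoter class table, matched
gene sets, per-mark heatmap matrices, average/smoothed/
background-subtracted profiles for all six class-by-tier groups,
per-gene peak tables, the JSON statistics report, and a manifest with
input checksums and the full configuration.

The numbered scripts under `analysis/` run the same workflow as a
file-based pipeline (`01_simulate.R` → `02_pipeline.R` → `03_recovery.R`
→ `04_report.R`), writing everything under `results/`.

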