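# tfdirect

Calling **direct transcription-factor target genes** by cross-referencing
ChIP-Seq binding-locus enrichment with RNA-Seq differential expression in
TF-overexpressing lines against a shared non-transgenic (NT) control.

RNA-Seq of an overexpression line mixes direct targets with downstream
responders. `tfdirect` separates them with the canonical two-assay
intersection: a gene is a direct target of a TF line when it is

1. **up-regulated** in that line — fold change
   `(mean FPKM_TF + 1)/(mean FPKM_NT + 1) ≥ 1.5` with Welch-test
   `p < 0.05` on `log2(FPKM + 1)` across replicates, after excluding
   genes with a zero-FPKM treatment condition, and
2. **bound** in its promoter or 5'UTR — a coverage window (200 bp) with
   `log2((RPM_TF + c)/(RPM_NT + c)) ≥ 1` (i.e. > 2-fold over the NT ChIP
   background, pseudocount `c = 0.5` RPM), adjacent enriched windows
   merged, and the merged locus center assigned to the nearest-TSS gene
   and classified into one of seven feature categories: intergenic,
   promoter (2 kb upstream of the TSS), 5'UTR, exon, intron, 3'UTR, TTS
   (1 kb downstream of the transcript end).

The package covers the full workflow for the four-line study design —
feature classification (`read_gff_annotation()`, `classify_loci()`),
enrichment calling (`call_enriched_loci()`), expression analysis
(`fpkm_table()`, `filter_zero_fpkm()`, `call_degs()`), integration and
multi-line Venn partitioning (`integrate_targets()`, `venn_partition()`,
`direct_target_fraction()`), hypergeometric GO singular enrichment
analysis with Benjamini–Hochberg FDR (`sea()`), and a fully seeded
synthetic-data generator with planted ground truth
(`simulate_experiment()`, `evaluate_recovery()`) so every stage is
testable offline. Everything takes and returns tibbles, chains with the
pipe, and exposes `tidy()`/`glance()`/`autoplot()` methods. See the
methods vignette (`vignettes/direct-target-calling.Rmd`) for the model,
its assumptions, and every numerical choice.

## Worked example

Simulate the default study (1000 genes on 4 chromosomes; four TF lines +
NT; two RNA replicates; planted 4-fold expression effects and 8-fold
binding enrichment), run the full pipeline, and score it against the
planted truth:

```r
library(tfdirect)

cfg <- sim_config()
sim <- simulate_experiment(cfg, seed = 101)
rep <- run_pipeline(sim, quiet = TRUE)
rep
#> tfdirect run report
#>   genes: 1000 ( 1000 retained )
#>   direct targets: 65 genes / 66 loci
#>   per-line fractions (% of up-regulated):
#>     TF1: 19.2% (19 / 99)
#>     TF2: 16.2% (16 / 99)
#>     TF3: 19.2% (19 / 99)
#>     TF4: 12.2% (12 / 98)

evaluate_recovery(rep$targets, sim$truth)
#> # A tibble: 4 × 6
#>   line  n_called n_truth n_correct precision recall
#>   <chr>    <int>   <int>     <int>     <dbl>  <dbl>
#> 1 TF1         19      19        19         1      1
#> 2 TF2         16      16        16         1      1
#> 3 TF3         19      19        19         1      1
#> 4 TF4         12      12        12         1      1

head(tidy(rep$targets), 3)
#> # A tibble: 3 × 6
#>   gene_id n_lines lines n_loci best_log2_ratio distance_to_tss
#>   <chr>     <int> <chr>  <int>           <dbl>           <int>
#> 1 G0025         1 TF3        1            2.74            -401
#> 2 G0083         1 TF3        1            3.06            -600
#> 3 G0084         1 TF3        1            2.95           -1400
```

Reading the output: 65 genes carry both an up-regulation call and a
promoter/5'UTR binding locus in at least one line (66 supporting loci —
one gene is supported twice); per line, 12–19% of the up-regulated genes
are direct targets; recovery against the planted truth is exact at these
effect sizes. `glance(rep$degs)` gives per-line up/down counts,
`rep$venn$cells` the 15-cell line-subset partition, and `rep$go` the GO
enrichment of the target set (here the two planted terms are the two
significant ones). `plot_locus_categories()`, `autoplot(rep$venn)`,
`autoplot(rep$go)` and `plot_deg_volcano()` draw the standard figures.

The same pipeline runs from files: `simulate_experiment(cfg, seed, dir =
"sim/")` writes GFF3/bedGraph/TSV inputs, and `run_pipeline("sim/",
output_dir = "out/")` reads any directory in that layout and writes
`report.json`, `direct_targets.tsv`, `degs.tsv` and `loci.tsv`.

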