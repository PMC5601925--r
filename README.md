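# combitet

Combinatorial tetramer mass-cytometry screening and phenotyping of
antigen-specific CD8+ T cells, as a tested, reusable R pipeline with a
ground-truth simulator.

## The problem

Neoantigen-specific CD8+ T cells are rare, and screening many candidate
specificities at once in limited tissue is hard. Mass cytometry (CyTOF)
with *combinatorial* peptide–MHC tetramer staining solves this: each
antigen's tetramer carries a unique unordered set of 3 of 9 metal-labelled
streptavidins, so C(9,3) = 84 specificities fit into 9 reporter channels —
a true antigen-specific cell is positive in exactly its 3 coded channels.
Combined with 2-of-6 palladium/indium sample barcoding, four tissues
(tumour, spleen, draining and non-draining lymph node) are screened against
81 candidate tumour epitopes in a single acquisition, and the surviving
antibody channels phenotype every antigen-specific cell.

`combitet` implements the full analysis chain for such screens:

1. **coding** — 3-of-9 tetramer code books (dual staining configurations as
   internal control), 2-of-6 sample barcodes, the 81-candidate panel;
2. **synthetic data** — an event-level simulator whose ground truth encodes
   the published tissue frequencies (tumour 10.2%/9.9% for the two known
   sarcoma neoantigens mLama4/mAlg8, down to 0.2% in non-draining lymph
   nodes), 10 phenotype archetype clusters C1–C10, beads, dead cells,
   doublets, drift, and checkpoint-blockade treatment effects
   (anti-CTLA-4: tumour frequencies ×2.0/×1.5, phenotype mass moving from
   C1–C5 into C7–C10; peripheral tissues unaltered);
3. **preprocess** — equilibration-bead signal normalization, zero
   randomization to Uniform(−1, 0), automated barcode deconvolution;
4. **gating** — the sequential hierarchy to live CD8+ T cells (beads out,
   cisplatin−, DNA+, CD45+, CD19−, TCRβ+ CD90+, CD8+ CD4−) with
   reproducible 1-D automatic thresholds;
5. **tetramer decode** — rank the 9 logicle-transformed reporter channels
   per cell; assign the antigen whose code equals the top-3 set iff all
   three clear positivity, the rank-3 − rank-4 gap clears a separation
   cutoff, and the set is a valid code; frequencies among CD8+ T cells;
   hits at the strict >0.15% cutoff; dual-configuration concordance;
6. **profiling** — logicle transform (Parks–Moore biexponential, w = 0.25,
   t = 16409, m = 4.5, a = 0; implemented from scratch, no flowCore
   dependency), downsampling to 10,000 cells/tissue, Barnes-Hut t-SNE (via
   Rtsne), k-means with 10 centres and 1,000 restarts, rule-based C1–C10
   annotation, χ² concordance, per-cluster marker medians/percent-positive;
7. **differential** — pooled-variance t tests with Holm–Šidák step-down,
   Benjamini–Hochberg FDR (q = 0.25), Fisher's exact test by
   hypergeometric enumeration, z-score matrices
   ((X − m)/s per marker, averaged per specificity), frequency fold
   changes;
8. **io** — FCS 3.0/3.1 read and FCS 3.1 write, CSV event tables, JSON run
   configs, a manifest with per-file hashes, and a CLI
   (`inst/cli/combitet.R`).

## Worked example

Simulate a 2-replicate, dual-configuration 81-antigen screen across four
tissues, run the whole pipeline, and call hits:

```r
library(combitet)
man <- run_pipeline(run_config(outdir = "demo", seed = 42, replicates = 2,
  n_cells = c(tumour = 4000, spleen = 5000, dLN = 8000, ndLN = 12000)))
print(man)
#> combitet run (2026-09-11T14:06:06+0000): seed 42, 5 files in demo
#> consistent hits: mAlg8, mLama4
subset(man$results$hits, consistent_hit)
#>  antigen tissue frequency(%) is_hit concordant
#>    mAlg8    dLN       0.40    TRUE       TRUE
#>   mLama4    dLN       1.04    TRUE       TRUE
#>    mAlg8   ndLN       0.23    TRUE       TRUE
#>   mLama4   ndLN       0.51    TRUE       TRUE
#>    mAlg8 spleen       0.90    TRUE       TRUE
#>   mLama4 spleen       0.90    TRUE       TRUE
#>    mAlg8 tumour       9.76    TRUE       TRUE
#>   mLama4 tumour      10.61    TRUE       TRUE
```

Of the 81 candidates only the two known neoantigens exceed 0.15% of CD8+
T cells in every tissue and in both staining configurations; the decoded
tumour frequencies (10.6%, 9.8%) recover the generator's ground truth
(10.2%, 9.9%) up to counting noise. The rule-based phenotype profile shows
what the numbers mean — e.g. PD-1 (logicle scale medians) is bright on the
dysfunctional clusters C3–C5 and absent elsewhere:

```r
subset(man$results$profile, marker == "PD1")[, c("cluster", "n", "median", "pct_positive")]
#>  cluster   n median pct_pos
#>       C1 244   0.18     0.0
#>      ...
#>       C3 110   2.46   100.0
#>       C4  59   2.45   100.0
#>       C5  52   2.47   100.0
#>      ...
```

## Vignette

`vignettes/combitet-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the simulator
does and does not emulate, and known limitations.
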