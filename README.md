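# TEactivity

Quantification of transposable-element (TE) transcriptional activity from
RNA-seq transcriptome assemblies, for researchers studying TE dynamics and
their host silencing machinery across developmental stages or treatment
contrasts (e.g. DNA-demethylation-induced derepression in zebrafish
embryos).

The package covers the full quantitative chain:

- **Annotation** — parse RepeatMasker `.out` files, map repeat labels onto
  the TE taxonomy (DNA, LINE, SINE, LTR with superfamilies Copia, DIRS,
  ERV1, ERV2, Gypsy, Pao, Ngaro, plus "Unclear"), and remove redundancy:
  drop non-TE entries, keep the highest-scoring entry of each overlap
  cluster, and drop matches not strictly longer than 80 bp.
- **Quantification** — filter read alignments at length fraction ≥ 0.80
  and similarity fraction ≥ 0.80, assign each read to the unique TE entry
  covering ≥ 50% of its aligned interval, and report per-sample profiles
  as percentages of all mapped reads, by TE class and LTR superfamily.
- **Divergence landscapes** — count transitions *p* and transversions *q*
  between each TE copy and its consensus and bin the Kimura 2-parameter
  distance

  *K* = −½ ln((1 − 2*p* − *q*) √(1 − 2*q*)),

  weighted by copy bp or by assigned reads (the expressed fraction), into
  1% divergence bins with an explicit overflow bucket.
- **Normalization** — TPM per sample, then cross-sample scaling factors
  *s*<sub>j</sub> = *R*/*C*<sub>j</sub> from the cumulative TPM
  *C*<sub>j</sub> of a single-copy orthologue set, plus per-family mean
  expression for multi-gene families (KRAB-like, FiNZ zinc fingers).
- **Statistics** — Pearson correlation panels of TE types versus silencing
  genes across stages with a seeded random-gene null control, one-way
  ANOVA with significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001)
  for treatment contrasts, and mean ± SEM replicate summaries.
- **Synthetic data** — a seed-reproducible generator emitting FASTA,
  RepeatMasker-style `.out`, aligned copy/consensus pairs, alignment
  tables, gene counts and ground truth, so the whole pipeline is testable
  end to end without any external download.

## Worked example

```r
library(TEactivity)

cfg <- simulation_config(seed = 3)        # 6 stages + DMSO/5Aza, 3 reps
res <- run_pipeline(cfg, "te_run")

res$anova[res$anova$contrast == "class_LTR", c("contrast", "F", "p_value",
                                               "stars", "mean_DMSO",
                                               "mean_5Aza")]
#>   contrast        F     p_value stars mean_DMSO mean_5Aza
#> 4 class_LTR 62.28759 0.001393922    **  2.288333  6.213333

res$null_control$summary[res$null_control$summary$te_type == "LTR", ]
#>   te_type       mean_r     sd_r fraction_significant n_random
#> 3     LTR -0.004823926 0.447533                 0.05      100
```

The LTR class rises from ~2.3% to ~6.2% of mapped reads under the
configured 3-fold derepression and is starred by the ANOVA, while the
random-gene control flags ~5% of null genes — the expected false-positive
rate at α = 0.05. `make_report("te_run")` then writes the figure-ready
tables (stacked-bar class percentages, LTR superfamily shares, divergence
landscape, family expression, correlation bars with significance colours,
ANOVA stars) under `te_run/report/`.

A thin command-line wrapper with the same defaults lives at
`inst/cli/teactivity.R` (subcommands `simulate`, `run-all`, `report`).

## Package layout

- `R/repeat_annotation.R` — `.out` parsing, TE taxonomy, redundancy filter
- `R/te_quantification.R` — alignment filters, read assignment, profiles
- `R/divergence.R` — substitution counting, K2P, landscapes
- `R/expression.R` — TPM, orthologue scaling, family means
- `R/stats.R` — correlation panel, null control, ANOVA, mean ± SEM
- `R/synthetic.R` — simulation config, TE library and expression generators
- `R/pipeline.R` — `run_pipeline()`, `make_report()`, manifest
- `vignettes/te-activity-methods.Rmd` — models, assumptions, design choices
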