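---
title: "Quantifying transposable-element transcription: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transposable-element transcription: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEactivity)
```

## The problem

Transposable elements (TEs) make up a large fraction of fish genomes and
are transcriptionally active during early embryogenesis: maternally
deposited transcripts dominate the 1-cell stage, are degraded around
zygotic genome activation (ZGA, ~128-cell stage in zebrafish), and
zygotic TE transcription — with a marked contribution of LTR
retroelements such as ERV1 — rebounds from gastrulation onwards. Host
silencing machinery (zinc-finger proteins with KRAB-like or FiNZ
N-terminal domains recruiting a TRIM corepressor, plus heterochromatin
and NuRD-complex genes) is expected to be co-expressed with the TEs it
controls, and DNA-demethylating agents such as 5-aza-2'-deoxycytidine
(5-aza-dC) derepress TEs and should amplify both signals.

`TEactivity` implements the quantitative side of such a study as a
reusable, fully testable pipeline operating on transcriptome-assembly
scale data: RepeatMasker annotation of an assembly, read alignments
against it, and per-gene counts. Because the real inputs are large
archive downloads, the package ships a first-class synthetic-data
generator that reproduces the statistical structure the analysis relies
on, with known ground truth.

## Annotation filtering

RepeatMasker `.out` files are redundant: a locus can be hit by several
library entries. `filter_redundancy()` reduces the annotation in three
steps, in this order:

1. entries whose class is not a TE class (simple repeats, low
   complexity, satellites, structural RNAs, artefacts) are removed;
2. on each contig, entries overlapping by at least one base are
   clustered by transitive closure and only the highest-scoring entry of
   each cluster is kept (ties: longer match, then smaller start, then
   input order);
3. survivors whose match length is not strictly greater than 80 bp are
   dropped.

The cluster scope (rather than best-per-contig) is deliberate: a contig
can legitimately carry several non-overlapping TE insertions, and
collapsing to one entry per contig would discard them. The overlap
definition (≥ 1 shared base) and the strict `> 80 bp` cutoff are
configurable. Internally all intervals are 0-based half-open; `.out`
files keep their native 1-based inclusive convention, and the writer
restores it so filtered annotations round-trip exactly.

Classification follows the RepeatMasker label grammar: the prefix before
`/` (case-insensitive, `?` stripped) selects the class; `RC/Helitron`
rolling-circle elements are counted with DNA transposons; labels that
are none of DNA/LINE/SINE/LTR but still repeats of unknown kind
(`Unknown`, etc.) form the `Unclear` class, which is reported in
profiles; non-TE categories are `NotTE` and never counted. For LTR
elements the suffix token selects the superfamily (Copia, DIRS, ERV1,
ERV2, Gypsy, Pao, Ngaro), anything else being pooled as `LTR_other`.

## Read quantification

Alignments are filtered with the two standard mapper cutoffs: aligned
fraction of the read ≥ 0.80 and identity over the aligned part ≥ 0.80
(both inclusive; the generating study's mapper used the same values).
Multi-mapped reads keep their single best placement (most matching
bases, first on ties). A read is then assigned to the unique filtered TE
entry covering at least half of its aligned interval; because filtered
entries never overlap within a contig, assignment is unambiguous except
exactly at the 0.5 threshold, where the larger overlap (then annotation
order) wins. Reads assigned to no entry still count toward the
mapped-read total. Per-sample profiles report, for each TE class and
each LTR superfamily, the read count as a percentage of all mapped reads
in the sample, which makes profiles comparable between samples of
different depth.

Counting TE-overlapping reads (rather than all reads of a TE-containing
transcript) is the default because an assembled transcript can contain
both TE-derived and host sequence; the interval-overlap rule confines
the signal to the annotated repeat.

## Divergence landscapes

Each TE copy is compared with its family consensus over an equal-length
alignment. Columns with a gap or `N` are excluded; among differing
columns `A↔G` and `C↔T` are transitions (proportion *p*), everything
else transversions (proportion *q*). The Kimura 2-parameter distance

&nbsp;&nbsp;&nbsp;&nbsp;*K* = −½ ln((1 − 2*p* − *q*) · √(1 − 2*q*))

corrects for multiple hits and serves as a proxy for copy age. Outside
its domain (1 − 2*p* − *q* ≤ 0 or 1 − 2*q* ≤ 0) divergence is saturated:
such copies are excluded from landscapes but counted and reported — they
are never silently dropped. The landscape bins 100·*K* into 1%-wide
intervals over [0, 50) with an explicit overflow bucket, so binned
weights always conserve the total. Two weightings are emitted: aligned
bp of the copy (the RepeatMasker convention) and assigned reads, the
latter describing the *expressed* repeat fraction, which is what a
transcriptome-based landscape measures. CpG-adjusted divergence is not
applied.

## Expression normalization

TPM is computed with effective length equal to transcript length (the
data are assembled transcripts; no fragment-length model is available or
needed). TPM equalizes within-sample composition but cross-stage
comparisons are still distorted by global composition shifts — maternal
transcript degradation changes what "per million" means. The pipeline
therefore rescales each sample by
*s*<sub>j</sub> = *R* / *C*<sub>j</sub>, where *C*<sub>j</sub> is the
cumulative TPM of a single-copy orthologue set in sample *j* and *R* is
the across-sample mean of the *C*<sub>j</sub> (a named reference sample
can be chosen instead; the mean avoids privileging one stage). After
scaling, the orthologue set has identical cumulative expression in every
sample, within-sample ratios are untouched, and the operation is
idempotent. Replicates are scaled independently and summarized (mean ±
SEM) afterwards. Multi-gene families (KRAB-like, FiNZ) are reported as
the unweighted mean of their members' scaled TPM.

## Statistics

Pearson correlations between TE-type trajectories and gene trajectories
are computed on per-stage replicate means (n = 6 stages), with the
two-sided t test on n − 2 degrees of freedom; "significant" means
p < 0.05 — two-sided, with no multiple-testing correction, matching how
such panels are conventionally drawn (a Benjamini–Hochberg flag can be
applied downstream by the user on the emitted p-values). As a
specificity control, `null_correlation_control()` repeats the panel on
genes drawn uniformly at random outside the target sets (default 100,
seeded and reproducible); under independence ~5% of null genes are
flagged, and the pipeline reports that fraction.

The DMSO vs 5-aza-dC contrast uses fixed-effects one-way ANOVA (pooled
variance) per TE class, per LTR superfamily, and per gene family, with
the conventional strict star thresholds (* < 0.05, ** < 0.01,
*** < 0.001). ANOVA is run on percentages of mapped reads (the plotted
quantity); replicate summaries are mean ± SEM. Degenerate inputs are
errors, not NAs: constant vectors for correlation, groups of fewer than
two values, or an all-identical ANOVA.

## The synthetic-data generator

`simulation_config()` fixes every study condition: six developmental
stages (zygote, blastula, gastrula, somitogenesis, pharyngula, larva)
with three replicates each, and a treatment experiment of two arms
(DMSO, 5-aza-dC) with three replicates, 100 bp reads for the
developmental series and 150 bp for the treatment series, 20,000 mapped
reads per sample by default, and a 2,111-gene single-copy orthologue set
mirroring the size used for real cross-stage scaling.

*TE library.* Each superfamily has a random consensus; copies mutate
every site independently — a transition with probability `p_true`, a
transversion (uniform over both options) with probability `q_true` — so
the expected K2P divergence is the closed form at the generating rates.
Substitutions are i.i.d. per site: no rate heterogeneity, no CpG
hypermutability, no indels. That is exactly the model under which the
K2P estimator is unbiased, so recovery tests measure estimator
implementation, not model misfit. Defaults give ERV1 the youngest copies
(p = 0.02) and DNA transposons the oldest (p = 0.14), producing the
bimodal young-LTR landscape the analysis is designed to resolve.

*Read shares.* Per-stage class weights encode the maternal peak
(zygote: 12.5% of mapped reads TE-derived), the ZGA trough (blastula:
3.6%) and the rebound (8–9%) with the LTR share dominated by ERV1 from
gastrula onwards. The numbers are configuration, not claims about any
real dataset. Reads are emitted as interval-level alignment records —
the pipeline never inspects base qualities, so sequencing-error
simulation would add nothing testable. With dispersion 0 counts are
exact largest-remainder allocations of the configured weights, giving
the noise-free identity the end-to-end test asserts; with dispersion > 0
counts are negative-binomially jittered. A configurable fraction of
deliberately under-aligned reads exercises the mapping filter, and decoy
annotation rows (overlapping lower-score duplicates, short fragments at
the 80 bp boundary, simple repeats) exercise the redundancy filter in
every end-to-end run.

*Treatment contrast.* The 5-aza-dC arm multiplies the LTR share by a
configured fold-change (default 3), taking the extra mass from the
non-TE remainder so other class shares stay fixed and the ground truth
stays interpretable; the within-LTR composition is reweighted toward
DIRS/ERV1/ERV2. Silencing-gene expression rises by a configured factor
(default 1.6).

*Genes.* Silencing genes follow a latent per-stage profile constructed
as ρ·z(LTR trajectory) + √(1 − ρ²)·noise, with ρ programmed per set
(0.9 for heterochromatin/NuRD/KRAB-like, 0.95 for trim33, 0.3 for FiNZ
— deliberately below the detection threshold at n = 6, 0 for
background); orthologues are constant up to depth. What passing tests
show is therefore that the pipeline *recovers programmed structure*;
they cannot show robustness to features the generator omits (isoform
mixtures, mappability artefacts, batch effects, assembly
fragmentation).

## Numerical and design choices

- Every stochastic output is a pure function of (config, seed); the run
  manifest carries no timestamps, so identical runs are byte-identical.
- Saturated K2P values are `NA` plus a reported count, never an
  exception mid-pipeline.
- The mapping cutoffs compare with `≥` (a read exactly at 0.80 passes);
  the length filter compares with `>` (a match of exactly 80 bp fails).
  Both follow the conventions of the tools that define the parameters.
- Ties everywhere are broken deterministically (score, length, start,
  input order) so results do not depend on storage order.
- Problem sizes in the shipped tests and acceptance script (20,000 reads
  per sample, 100 copies of 10 kb for divergence recovery, 200 seeded
  power runs, 10,000 ANOVA null simulations) were chosen as the smallest
  sizes at which the targeted effects are comfortably identifiable;
  they are package choices and scale linearly if raised.

## Known limitations

- Read assignment is unstranded; library strandedness, if known, is
  currently ignored.
- Whole-transcript counting (all reads of a TE-containing contig) is
  supported only through annotation manipulation, not as a switch.
- The K2P step assumes externally provided copy/consensus alignments
  (or the generator's); it does not reconstruct consensus sequences.
- `read_alignment_sam()` derives matches from the `NM` tag, which is
  exact only for gap-free alignments; gapped SAM input slightly
  underestimates identity.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
res <- run_pipeline(cfg, "te_run")
res$anova[res$anova$contrast == "class_LTR", ]
make_report("te_run")
```
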