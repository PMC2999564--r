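# estarray

Species-specific oligonucleotide microarray probe sets, built directly
from EST collections when no reference genome exists.

Many ecologically or toxicologically important organisms have
transcriptome-scale EST collections (Sanger reads plus 454
contigs/singletons) but no genome. `estarray` implements the workflow
that turns such a collection into a validated expression array: assembly
quality testing, deterministic 40/60-mer probe design in both
orientations (single-pass ESTs do not reveal the mRNA strand),
spike-in-calibrated hybridization calling, and a six-step reduction to
one unique, validated probe per unique target. A built-in hybridization
simulator makes the whole chain testable against known truth. The
intended users are genomics groups building custom arrays for non-model
species, and anyone who needs reproducible, auditable probe-selection
logic.

## The core methods

**Alignment statistics.** Assembly completeness (within-assembly
redundancy) and correctness (agreement with reference Sanger ESTs) are
judged with a BLASTN-like seed-and-extend local aligner: exact-word
seeding on both strands, affine-gap Smith–Waterman resolution, scoring
+1/−2 with gaps −5/−2. Significance uses ungapped Karlin–Altschul
statistics: λ solves Σᵢⱼ pᵢpⱼ e^{λsᵢⱼ} = 1 and K comes from the standard
lattice series K = δλ e^{−2σ}/(H(1 − e^{−λδ})), giving
E = K·m·n·e^{−λS}. For +1/−1 uniform composition λ = ln 3 exactly; for
the +1/−2 default the solver prints

```
KarlinAltschulParams: lambda 1.332706, K 0.620991, H 1.124092
```

**Probe design.** Targets are classed by length (40–59 → one 40-mer;
60–150 → one 60-mer, best probe; 151–300 → two 60-mers; >300 → four
60-mers, best distribution), probes are placed by a deterministic window
score (GC balance, homopolymer and self-complementarity penalties), and
the 244K layout accounting (243,504 spots − 2,105 controls = 241,399
features) places every unique probe once with duplicate fill cycling in
input order.

**Calling and selection.** Each array × PMT-gain scan is calibrated from
its spike-ins (threshold = mean + 2 SD of the pooled replicates of the
three lowest species); spots are absent/present/saturated (SI ≥ 65,000);
a probe is positive when ≥75% of its 4/8/16 measurements are present and
is discarded when flagged in >25% of them. Selection then removes
redundant probes and targets within and across orientations and filters
probe pairs sharing an ungapped window of ≥50 columns at ≥95% identity,
always keeping the brighter probe — every removal logged with its step.

## Worked example

```r
library(estarray)
targets <- simulateTranscriptome(200, c(100, 400), seed = 42)
res <- runProbePipeline(targets, truthConfig(seed = 42))

res$design
#> ArrayDesign: 1878 spots = 700 controls + 978 unique probes + 200 duplicate fill
res$calibrations[[1]]
#> Calibration A1 / PMT 400: threshold 123.22 (spikes spike01,spike02,spike03), saturation 65000
res$validated
#> ValidatedProbeSet: 88 validated probes ( 45 sense / 43 antisense ), 198 removals logged

orientationRecovery(res$validated, res$truth)
#> $n_expressed        [1] 89
#> $n_recovered        [1] 88
#> $recovery_fraction  [1] 0.988764
#> $n_from_unexpressed [1] 0
```

Of the 200 simulated targets, 89 were expressed; the pipeline designed
978 unique probes (both orientations), calibrated each of the eight
scans from its spike-in block (the A1/PMT-400 threshold of 123.22 SI
units is mean + 2 SD of the three dimmest spike species), and validated
88 probes — one per expressed target, in the true orientation for 88 of
89, with no probe from any unexpressed target. The provenance log
records why each of the 198 removed probes fell (e.g. the second probe
of a two-probe target, or the wrong-orientation twin):

```r
head(selectionLog(res$validated), 2)
#>              probe_id step                                                  reason
#> 1  t0003|antisense|19    3 additional probe on the same target within orientation
#> 2 t0008|antisense|144    3 additional probe on the same target within orientation
```

## Layout

* `R/`, `src/` — implementation (S4 classes, Rcpp alignment core)
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/probe-design-methods.Rmd` — the model, parameters and
  design decisions in detail
* `inst/scripts/estarray-cli.R` — thin shell interface
  (`qc-assembly`, `design`, `select` subcommands)
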