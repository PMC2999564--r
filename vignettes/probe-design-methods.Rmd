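---
title: "Designing and validating transcriptome-wide oligo probe sets from ESTs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating transcriptome-wide oligo probe sets from ESTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estarray)
```

## The problem

For most non-model organisms no reference genome exists, but
transcriptome-scale EST collections (Sanger reads, 454 contigs and
singletons) are comparatively cheap to obtain. A species-specific
expression microarray can be built directly from such a collection by (1)
assessing how redundant and how trustworthy the assemblies are, (2)
designing candidate oligo probes against every putative target in both
orientations (single-pass ESTs do not reveal which strand is the mRNA),
(3) hybridizing test arrays against a pooled RNA sample, and (4) keeping,
for each unique target, the one probe that reliably lights up. `estarray`
implements this workflow end to end, together with a hybridization
simulator so that every stage is testable without array data.

## Assembly quality: completeness and correctness

Two alignment-based tests inform the choice between competing assemblies.
The *completeness test* aligns every contig/singleton against all others
in the same assembly; an assembler that left merging opportunities on the
table shows many significant hits (E ≤ 10⁻⁵) and many sequences with
≥25-column ungapped overlaps at 100% or >95% identity. The two identity
columns are nested: a sequence with a perfect overlap also counts in the
>95% bin. Significant hits are tallied as hits (alignments), while the
identity bins tally sequences — only that reading keeps the magnitudes of
the two statistics coherent on real assemblies, where hit counts far
exceed sequence counts. The *correctness test* aligns each sequence
against reference Sanger sets; only the most significant reference hit
counts (ties broken by score, then subject id), and a sequence counts as
full-length identical when the shorter of query and subject is ≥100 bases
and identities over that shorter length reach the per-set threshold
(0.90 against same-species references, 0.80 against congeners, both
configurable).

### The internal aligner and its statistics

The aligner is BLASTN-like: exact-word seeding on both strands
(word size 11 by default) selects candidate query/subject/strand triples,
and each seeded triple is resolved by a full affine-gap Smith-Waterman
with traceback, so any reported hit is locally optimal. Default scoring is
+1/−2 with gaps −5 to open and −2 per base, a standard short-sequence
nucleotide scheme. E-values use the ungapped Karlin–Altschul parameters:
λ is the positive root of Σᵢⱼ pᵢpⱼ e^{λsᵢⱼ} = 1 (solved to 10⁻¹²), and K
by the standard lattice series
K = δλ e^{−2σ} / (H(1 − e^{−λδ})), with the σ-series truncated at 50
terms or a 10⁻⁹ term, whichever comes first. No edge-effect length
correction is applied (E = K·m·n·e^{−λS} on the raw pair search space):
the sequences involved are short and the tests only threshold at
E ≤ 10⁻⁵, and the raw form keeps every count bit-reproducible. For +1/−1
uniform composition λ reduces analytically to ln 3, and for the +1/−2
default the solver reproduces the standard ungapped constants
(λ ≈ 1.33, K ≈ 0.62, H ≈ 1.12).

Seeding is provably lossless in the two regimes where the package relies
on it. For short sequences compared at word size 3 and minimum score 5
under +1/−2 scoring, any alignment without an exact 3-mer scores at most
2 (each match run of ≤2 is separated by a penalty of ≥2), so a qualifying
alignment always contains a seed; the randomized suite checks equality
against an independent dynamic-programming oracle on a thousand pairs.
For the similarity filter the seed length is derived from the pigeonhole
bound min over window lengths L of ⌈(L − k_L)/(k_L + 1)⌉, where k_L is
the mismatch budget at L — at the default 95%/50-column criterion on
60-mers this gives 15 (not the 16 that holds for 50-column windows alone,
because a 60-column window tolerates three mismatches).

```{r lambda}
solveLambda(scoringParams(match = 1, mismatch = -1))
```

## Probe design

Targets are classified by length: under 40 bases no probe class exists
(rejected); 40–59 one 40-mer; 60–150 one 60-mer (best probe); 151–300 two
60-mers; above 300 four 60-mers (best distribution). The boundaries read
"longer than" strictly: a 150-base target receives a single probe, a
300-base target two. A per-source override can force a different rule
(e.g. two probes for every subtracted-library target). The window score,

score = −|GC − 0.5| − 0.05·(longest homopolymer − 4)₊
        − 0.02·(longest self-complementary stretch − 8)₊,

with windows above 10% N ineligible, is a deterministic package-defined
criterion standing where commercial design tools keep a proprietary one;
the pipeline's guarantees depend only on it being deterministic and
total, so probe placement is reproducible and the placement contract
(one probe per equal-length segment under best distribution, pairwise
distinct windows, ties to the smallest start) is exactly testable.
Antisense probes are windows of the reverse complement. Within each probe
group, duplicate probe sequences are removed with earlier groups taking
priority. Layout accounting fills a fixed-format array (243,504 spots,
2,105 controls, hence 241,399 features in the 244K format) with every
unique probe once and duplicates cycling in input order.

## The hybridization simulator

The simulator exists so that calibration, calling and selection are
testable against known truth. Its defaults describe the study conditions
the rest of the package is tested under:

* four arrays, each scanned at two PMT gains (400 and 500; gain factors
  1 and 2.5) — eight measurements per probe, sixteen for duplicate-filled
  probes;
* per target: expressed with probability 0.5, one true orientation,
  log-normal abundance (meanlog log 3000, sdlog 1);
* per probe: a log-normal affinity (sdlog 0.3) drawn once and reused
  across arrays, so probe-level consistency is realistic;
* per spot: log-normal measurement noise (sdlog 0.15) on signal spots,
  Gaussian background (mean 40, sd 25) on silent spots — negative
  background-subtracted intensities are kept, as in real GPR exports;
* ten spike-in species in a geometric concentration series (25·2⁰…2⁹;
  real spike mixes do not publish concentrations, so a documented
  geometric default is used), 60 replicate spots each, plus 100
  negative-control spots;
* probes similar to a signal-bearing probe (95%/50-column ungapped
  window) leak 5% of that signal (cross-hybridization);
* all intensities clip at the 16-bit ceiling 65,535 — deliberately
  distinct from the 65,000 saturation call level, which is a judgment
  about reliability rather than a physical limit.

The simulator reproduces the qualitative scanner behaviour that motivates
dual-gain scanning: the higher gain saturates more spots while the lower
gain leaves more spots near background. What it does not emulate:
spatial artefacts, dye chemistry, probe-position (3′-bias) effects,
partial-overlap cross-hybridization below the window criterion, and
correlated noise between gains of the same physical array. Passing tests
therefore certify the decision logic — calibration arithmetic, boundary
handling, selection order — not wet-lab performance of designed probes.

The "noiseless" regime used by the dichotomy checks sets every dispersion
parameter (abundance, affinity, spot noise, background sd) and the
cross-hybridization leak to zero: hybridization is then decided purely by
complementarity, and each probe is either positive in all measurements or
in none, because the calling threshold scales with the gain exactly as
the signal does.

## Calibration and calling

For each array × gain scan independently, the three spike species with
the lowest median replicate intensity are pooled and the threshold is
their mean + 2·SD (sample SD over pooled replicates — replicates are the
observable variance source, and selecting by observed medians rather than
nominal concentration keeps the procedure applicable when concentrations
are unknown). A spot at or above 65,000 is saturated (flagged); otherwise
at or below the threshold it is absent — the boundary goes to absent, the
conservative reading where the two natural phrasings ("smaller than" /
"no greater than") disagree; otherwise present. Negative controls must
not exceed the lowest spike median. Every spot instance is one
measurement, so the per-probe denominators are 4, 8 or 16 depending on
replication.

## The six-step selection

Starting from the call matrix: (1) remove probes flagged in strictly more
than 25% of measurements (≥2/4, 3/8, 5/16); a probe is *positive* when at
least 75% of its measurements are present (6/8 qualifies). Then
(2) within-orientation removal of duplicate probe sequences;
(3) within-orientation removal of duplicate target sequences and
reduction to one probe per target; (4) the same across orientations;
(5) removal of highly similar probes (95%/50-column window, either
strand, evaluated on probe sequences — the step exists to limit
cross-hybridization between probes). Step (6), "keep the brighter probe",
is applied as the universal tie-break inside steps 2–5, with residual
ties going to the lexicographically smaller probe id so the outcome is
deterministic. Every removal is logged with its step; the survivors
satisfy, by construction and by an exhaustive post-hoc audit, pairwise
distinctness of probes and targets and the absence of any similar pair.
Because both orientations of each target enter testing and at most one
survives, the procedure assigns each validated target an orientation call
that can be compared with the simulator's truth.

Targets that merely *overlap* (rather than duplicate) other targets are
deliberately not merged — that requires re-assembly, which is outside
sequence-level deduplication; their probes can both survive when the
shared stretch stays below the similarity criterion. This is a known
limitation of the selected set.

```{r pipeline}
targets <- simulateTranscriptome(120, c(100, 400), seed = 5)
res <- runProbePipeline(targets, truthConfig(seed = 5))
res$validated
orientationRecovery(res$validated, res$truth)[c("recovery_fraction",
                                                "n_from_unexpressed")]
```

## Numerical and design choices

* Identity comparisons use a 10⁻⁹ guard band so rational fractions (e.g.
  49/50 vs 0.95·50) never fall to floating-point noise; ">95%" in the
  completeness bins is strict.
* N scores as a mismatch everywhere, never as an identity, and a codon
  containing N translates to X without terminating an open reading frame
  run (keeping runs maximal); ORFs follow the stop-to-stop convention
  with a 5-aa default cutoff and no start-codon requirement.
* Coordinates are 0-based half-open internally and 1-based closed in all
  text reports.
* Equal-scoring alignments resolve to the smallest (q_start, s_start);
  equal-scoring design windows to the smallest start.
* Degenerate inputs are values, not crashes: sub-40-base targets are
  rejected markers, single-sequence completeness reports are zeros with a
  warning, empty control sets pass vacuously with a warning.
* Problem sizes in the randomized suites — 1,000 pairs for the aligner
  oracle, 2,000 60-mers with 50 planted near-duplicates for the
  similarity audit, 500 targets for end-to-end recovery, 200 for the
  noiseless dichotomy — are the package's chosen test scale: large enough
  that seeding bugs, boundary errors and order dependence surface, small
  enough to run routinely.
* The end-to-end suites run on a compact layout (every unique probe, a
  200-spot duplicate fill, and the 700-spot control block) rather than a
  full 244K grid; the full-format arithmetic is exercised separately,
  since layout accounting is independent of simulation size.

## Limitations

Thermodynamic melting behaviour is not modelled (the window score is a
composition heuristic, not a ΔG calculation); translated (protein-level)
alignment and external annotation databases are out of scope — the
package prepares peptides for annotation but does not annotate; and the
similarity filter guarantees non-redundancy among *probes*, not among
the targets they represent.
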