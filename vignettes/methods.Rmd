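---
title: "Mapping a bacterial transcriptional landscape: models and methods"
author: "TUscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a bacterial transcriptional landscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

TUscape reconstructs the vegetative transcriptional landscape of a
high-GC bacterial chromosome from two complementary strand-specific
expression platforms — a two-channel tiling microarray (mRNA signal
against a genomic-DNA hybridization baseline) and per-base RNA-Seq
coverage — and then annotates every transcriptional unit (TU) with its
promoter, terminator, untranslated regions and expression class.  This
vignette explains the models behind each stage, the tunable parameters
and their defaults, what the synthetic-genome generator does and does
not emulate, and the numerical choices made where the underlying
procedure left room for design.

# The data model

A TU is a promoter-driven transcript: a transcription start site (TSS),
one or more genes, a 5'-untranslated leader between the TSS and the
first start codon, a 3'-UTR, and a transcription termination site
(TTS).  Expression is summarized as the fold change (FC) of the mRNA
channel over the gDNA baseline and partitioned into three classes:
high (FC > 10), medium (3 <= FC <= 10) and low (FC < 3).  The two
printed formulations of the class rule disagree about the boundary
values; both boundaries are assigned to `medium` so that the classes
form a total partition (`classifyExpression()`).

All coordinates in the package are 1-based and inclusive:
`length = end - start + 1`.  This convention is pinned by the published
housekeeping sRNA coordinates, whose printed lengths (346, 396 and
104 bp) it reproduces exactly; a half-open convention would give
345/395/103.  bedGraph input and output is converted at the boundary by
`rtracklayer`.

# Tiling-array signal

Probes are 60-mers tiled every 22 nt on both strands
(`designProbes()`).  A probe is called transcribed when its
`log2(mRNA/gDNA)` ratio is significantly positive
(`callProbes()`).  The original two-channel analysis moderated probe
variances across replicate arrays; a single synthetic array offers no
replicate variance to moderate, so the test is a one-sided z-test
against a null whose location and scale are estimated robustly
(median/MAD) from the genome-wide log-ratio distribution — valid as
long as less than half of a strand is transcribed, which holds for the
generator's layouts (roughly 25–35% transcribed).  Benjamini–Hochberg
correction is applied and significance requires `q <= 1e-4`, the FDR
the study used.  With exactly noiseless input the MAD degenerates to
zero; it is replaced by a tiny constant so that any positive ratio is
called, which is the correct noiseless limit.

Significant probes merge into transcribed segments
(`segmentProbes()`); one interior non-significant probe is tolerated
per run (`maxGapProbes = 1`) to bridge isolated dropouts.  A segment's
`mean_fc` averages `2^log2_ratio` over its significant members only:
dropout probes are treated as failed measurements, not as zeros.

The hybridization footprint of a terminal probe overhangs the true
transcript boundary: the first significant probe can begin up to one
probe length (59 bp) upstream of the true TSS.  Array TSSs are
therefore systematically early, and array TTSs systematically late, by
up to 60 bp — which motivates the cross-platform refinement below.

# RNA-Seq coverage

Gene-level expression is quantified as RPKM
(`reads / ((length/1000) * (total/1e6))`) with a 150-RPKM expression
call (`rpkm()`, `callExpressedGenes()`).

Transcript boundaries are detected from per-base coverage as step
changes (`detectBoundaries()`): a start is the first *covered* base
(coverage at least `minCov`) whose downstream `window` (25 bp) mean is
at least `minCov` and at least `minRatio` (4) times the upstream
window mean; ends are mirrored, taken at the last base of their
candidate run so an ideal step yields its exact edges.  Requiring the
boundary base itself to carry reads implements "the first and last base
of reads" literally and guarantees that a detected start never lies
upstream of the true TSS — RNA-Seq loses 5' bases (random-hexamer
priming, fragmentation), it does not invent them.  `minCov` defaults to
`max(3, 5 * background)`, the background mean being estimated from the
lower half of the strand's coverage distribution.  Where two adjacent
step candidates compete the leftmost is taken; the original report does
not state its tie-break, so this is a package decision.  The 25-bp
window matches the 25–50 bp scale of cross-platform TSS discrepancies
the study observed.

# TU assembly and cross-platform refinement

Every array segment becomes a TU (`assembleTUs()`).  Genes join a TU
when at least half the gene lies inside the segment on the same strand
(the threshold is a package decision; the study did not state one).
The TSS is the segment 5' end, replaced by the 5' end of the matching
coverage interval when the two agree within one probe length (60 bp,
the study's own array error bound); such TUs carry
`tss_source = "both"`.  The TTS is refined symmetrically.  The
symmetric TTS refinement goes beyond the stated assembly rule (TTS =
segment end), but without it the terminal probe overhang (up to 59 bp)
would defeat the ±30 bp terminator-to-TTS matching window used in
termination classification; `refineTts = FALSE` restores the literal
rule.  UTR lengths are strand-aware distances from the refined TSS/TTS
to the first/last gene boundary, floored at zero (a weakly detected TU
whose first probes fall inside the gene would otherwise report a
negative leader).

`tssConcordance()` reports the signed strand-aware distance from the
array TSS to the RNA-Seq TSS per TU (positive = RNA-Seq downstream,
the expected direction), with the fraction falling in the 25–50 bp
band.

# The two-box promoter model

Vegetative (sigma-70-style) promoters are modelled as two hexamer
boxes — consensus TTGACA (-35) and TATAAT (-10) — separated by a
14–20 bp spacer with optimum 17 bp.  `learnPromoterModel()` fits 4x6
position-weight matrices and an empirical spacer distribution by
expectation–maximization constrained to legal two-box placements: the
E-step enumerates every placement of the two boxes inside each window,
the M-step re-estimates both matrices (pseudocount 0.5) and the spacer
probabilities, and iteration stops when placement posteriors move less
than `1e-6`.  Restarts are deterministic: the -10 matrix is seeded from
the hexamers most *enriched* over their mononucleotide-background
expectation (raw frequency would seed GC-rich junk on a 59% GC genome)
and the highest-likelihood fit wins, so a given training set always
yields the same model.

Because EM sharpens on some alignment even of pure noise, an absolute
information-content cutoff cannot distinguish motif-bearing input from
noise (a fit on uniform random windows still reaches ~6 bits).  The
low-information flag therefore applies the identical fitting procedure
to base-shuffled windows — same composition, no shared motif — and
flags the model when the achieved information content is below 1.2
times that null.  Motif-free input sits at a ratio of 1 by
construction and an exact planted consensus exceeds 3; small noisy
training sets can land near the boundary, so the flag is a
conservative diagnostic (the model is still returned and usable).

Scanning (`scanPromoter()`) scores every placement as
`logodds35 + logodds10 - 0.25 * |spacer - 17|` — the per-bp spacer
penalty is a package decision; the study gives the optimum and range
but no penalty form — and returns the maximum, breaking ties toward
the spacer closer to 17 and then toward the -10 box closer to the TSS.
No call is returned below the model threshold, set at the 5th
percentile of best training-placement scores (the original borderline
cases were resolved by manual curation, which cannot be codified; the
percentile is the reproducible proxy).  The pipeline scans a 100-bp
window ending at each TU's TSS — 62 bp would be the canonical feature
span, but the RNA-Seq 5' truncation (about 20 bp) pushes the apparent
TSS downstream, and 100 bp keeps the boxes in view; for TUs whose TSS
comes from the array alone the window is additionally extended one
probe length downstream, because the array TSS overhang places the
true promoter downstream of the reported start.  Training windows are
taken from TUs with `fc >= 3` and a coverage-refined start — the
high/medium "housekeeping" training set of the original design, 75
windows by default.

`extractPromoterFeatures()` assembles the canonical feature window —
24 bp upstream of the -35, both hexamers, the spacer, and 9 bp
downstream of the -10: exactly 24+6+17+6+9 = 62 bp at the modal
spacer.  The 24-bp extent of the "-35 upstream" block follows from
that arithmetic; the original text never states it explicitly.  Spacers
shorter than 17 are centre-padded with an explicit gap character,
longer ones centre-trimmed, so `aligned_bases` always has 62 columns.

# Rho-independent terminators

`findTerminators()` detects the canonical element — a GC-rich hairpin
followed by a polyT run — by seed-and-extend: every loop placement
(3–10 nt) whose flanking bases pair is extended outward under
Watson–Crick pairing with at most one internal mismatch, emitting a
candidate at every matching depth.  Emitting interior depths matters:
for a bidirectional element (polyA–stem–polyT) the maximal extension
pairs the polyA run against the polyT run and would swallow both
signals.  Candidates need stem >= 6 bp, stem GC >= 0.5, and (for a
full call) a run of >= 4 T's starting within 3 nt of the 3' arm; a
polyA run detected symmetrically upstream marks the call
bidirectional.  Overlapping candidates resolve preferring polyT-bearing
calls, then bidirectional ones, then the score
`stem_len + 2*(GC pairs) - 0.5*loop_len` — an ad-hoc pairing score,
deliberately not a nearest-neighbour free energy.  G·U wobble pairing
is available (`wobble = TRUE`) but off by default: detection operates
on the DNA strand and the exact-complement rule keeps the brute-force
test oracle clean.

`classifyTermination()` assigns each TU one strategy:
`rho_independent` when a full call sits within ±30 bp of the TTS;
`stem_loop_only` when only a bare hairpin does (pause-like GC-rich
stem-loops); `convergent_overlap` when there is no terminal signal but
the 3'-UTR overlaps that of an opposite-strand, tail-to-tail TU
(collision-mediated termination); `none` otherwise.  The ±30 bp window
is a package decision.  Note that in a 59% GC genome bare hairpins are
common, so `stem_loop_only` absorbs some TUs that carry no planted
signal; the full (polyT) calls are the precise ones.
`terminationSummary()` tabulates strategies per expression class and
reports the rho-independent percentage; over the published per-class
counts (70 of 83 high, 81 of 153 medium, 73 of 177 low) it returns
224 of 413, i.e. 54%.

# Random-forest feature ranking

`buildFeatureMatrix()` assembles, per called promoter, the seven scalar
classifiers (spacer length, leader length, and the AT fractions of the
five sub-regions) plus the 62 aligned base positions; `trainRank()`
fits a random forest (bootstrap rows, random feature subsets,
per-class balanced sampling) and ranks features by mean decrease in
Gini impurity with ties broken by column order.  Aligned bases enter
as factor columns with an explicit gap level rather than one-hot
dummies: the forest splits categorical columns natively and each base
position keeps a single importance value, which is what a positional
importance profile plots.  When intergenic negative windows are
included (`sampleNegatives()`), negatives take the canonical 17-bp
layout and inherit leader lengths resampled from the positives, so the
bookkeeping columns cannot trivially identify them; the
high/medium/low ranking and its out-of-bag (OOB) error are always
reported from the three-class sub-problem, with the full-model OOB
alongside.  Desk-scale defaults (500 trees, 2,000 negatives) are
configurable up to the original dimensions (5,000 trees, 270,000
negatives).

# The synthetic genome generator

`simulateGenome()` plants a complete ground truth so every stage can be
validated against known answers.  Its defaults define the study
conditions:

* **Genome**: 250 kb at 59% GC, with intergenic space 8 percentage
  points more AT-rich than coding space (the coding GC is raised so the
  genome-wide target still holds).
* **TUs**: 20 per class, FC drawn uniformly from (11, 28), (3, 10) and
  (1.5, 2.8); 1–2 genes of 400–900 bp; inter-TU gaps of 200–450 bp;
  plus two gene-free, highly transcribed (FC 50–80) sRNA-like units and
  four convergent tail-to-tail pairs, half sharing a bidirectional
  polyA–stem–polyT terminator and half overlapping 3'-UTRs with no
  terminator.
* **Promoters**: consensus boxes planted with the -10 ending 10 bp
  upstream of the TSS.  Degradation is an independent per-position
  substitution, rate 0.05/0.20/0.40 (high/medium/low) on -10 positions
  1, 2 and 6 and on the -35 (0.18/0.25/0.35); the -10 core (positions
  3–5) uses `min(0.65, 0.35 + 0.8*rate)` — a high class-independent
  floor plus a damped class effect — so the class signal concentrates
  on positions 1, 2 and 6, the positions conserved in real vegetative
  promoters.  Substituted bases drift to G/C, eroding the AT content
  of a degraded box as a GC-rich genome would.
* **Spacers**: drawn from 14–20 bp with weight `exp(-|s-17|/tau)`,
  tau = 0.5/1.2/5 per class: highly expressed units sit at the 17-bp
  optimum, weak ones spread across the range.
* **UTRs**: 5'-UTR lengths are log-normal with means 100 bp (high) and
  60 bp (medium/low) and log-sd 1.0 — real bacterial leaders are
  heavy-tailed, and this spread is what lets the forest rank the -10
  AT content above the leader length, as observed; 3'-UTRs are normal
  with mean 38 bp.
* **Terminators**: planted on 70/83, 81/153 and 73/177 of units per
  class (the published per-class fractions), stem 6–8 bp at >= 75% GC,
  loop 3–8 nt, polyT 5–7 nt ending exactly at the TTS — always
  satisfying the detector minima, so noiseless recall can be 100%.
* **Array**: gDNA baseline 1000 with multiplicative log-normal noise
  (sd 0.2 log2 units); mRNA = baseline x overlap-weighted FC x its own
  noise draw.  The noise magnitude is a free parameter — neither
  platform's noise was published.
* **Coverage**: Poisson with mean `fc * 10` per base, modulated by a
  smooth sinusoidal positional bias (period 300 bp, amplitude 0.5, a
  deliberately simple stand-in for hexamer-priming and fragmentation
  bias); each transcript loses a geometric number of 5' bases (mean
  20 bp, matching the observed promoter-to-TSS offset); background is
  Poisson(0.05).

What the generator does **not** emulate: read-level sequencing (no
FASTQ, no mapping ambiguity), rRNA depletion, replicate arrays and
dye-swap chemistry, repeat families (the repeat mask input is honoured
but no repeats are planted), operonic internal promoters, and any
rho-dependent termination signal.  Passing the recovery suite
therefore shows that the algorithms are correct under the stated
statistical structure, not that they would meet the same accuracy on
real arrays and libraries.

`simulateFeatureMatrix()` draws promoter feature rows directly from
the same class-conditional distributions at arbitrary sample size, and
adds to the leader length the TSS measurement error the assembly chain
actually produces (60% coverage-refined starts shortened by the
geometric truncation, 40% array-only starts lengthened by the probe
overhang) — the forest sees leaders as the pipeline would measure
them, not as planted.

# Problem sizes and reproducibility

Every stochastic step runs through a single seed; equal configuration
and seed reproduce every numeric output bit-for-bit (`runPipeline()`
is pure given `(config, seed)`).  The package's own validation runs at
desk scale — a 250 kb genome with about 62 TUs, 500 trees and a few
thousand negatives — which keeps the full pipeline around one to two
minutes on a single core; the `paper` profile of the command-line
wrapper scales the same code to a 2.4 Mb genome with 413 TUs, 5,000
trees and 270,000 negatives.  Genome-scale published counts (852
transcribed CDSs, 413 TUs, 84.3% platform overlap, mean TU 1636 bp)
depend on the original raw data, which were not deposited; they are
not reproduction targets at desk scale, and the validation instead
asserts recovery of planted truth plus the in-paper worked-example
arithmetic.

# Known limitations

* The robust-z probe test assumes a minority of probes are
  transcribed; a genome transcribed over most of one strand would
  inflate the null scale and cost sensitivity.
* Weakly transcribed units (FC below about 2.2 at the default noise)
  drop below the FDR threshold probe-by-probe and fragment into
  partial segments, as weak transcripts do on real arrays; downstream
  statistics over the low class describe detected fragments, not
  planted units.
* The promoter threshold (5th training percentile) trades a small
  false-negative rate for precision and cannot reproduce manual
  curation of borderline promoters.
* `stem_loop_only` classifications are frequent in GC-rich sequence
  and should be read as "hairpin present, polyT absent", not as a
  validated pause site.
* The terminator score is a pairing count, not a folding energy;
  borderline elements that fold with wobble pairs are missed unless
  `wobble = TRUE`.
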