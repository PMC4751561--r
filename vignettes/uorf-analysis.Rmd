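---
title: "Classifying upstream ORFs and estimating their translation probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying upstream ORFs and estimating their translation probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Annotated transcriptomes of GC-rich genomes are dense in ATG codons
upstream of the annotated start codon. Under the scanning model of
translation initiation — the 40S subunit walks 5'→3' from the cap and fires
at the first adequate AUG — most of these upstream ORFs (uORFs) would
abolish translation of the annotated coding sequence. Deciding which
upstream ATGs are real initiation sites is therefore both an annotation
problem (is the true protein N-terminally extended?) and a translational
one.

`uorfscan` implements a complete statistical workflow around a three-way
uORF classification relative to the reference CDS:

* **class 1** — ATG in the 5'UTR, in frame with the CDS, no intervening
  in-frame stop codon wholly within the UTR. If translated, it appends an
  N-terminal extension to the reference peptide.
* **class 2** — as class 1 but out of frame; translation would read
  through the CDS start in the wrong frame.
* **class 3** — ATG whose ORF terminates at a stop codon wholly within
  the 5'UTR.

Per transcript, at most one class-1 and one class-2 record is reported
(the 5'-most qualifying ATG of each); every class-3 ORF is an individual
record. ATGs straddling the UTR/CDS junction are not evaluated — all
three bases must lie in the UTR. Internal ATGs inside the chosen class-1/2
uORF are not reported as further class-1/2 records, but they do seed
class-3 records when their ORF stops in the UTR. The unreported
candidates are retained (`keep_candidates = TRUE`) because some null
expectations are exact only at the candidate level (below).

## Coordinates, degenerate inputs, tie-breaks

GFF3 input is 1-based inclusive; internally all transcript coordinates
are 0-based and uORF positions are reported transcript-relative in mRNA
sense. Minus-strand transcripts are reverse-complemented to mRNA sense
during assembly; a round-trip property test guarantees byte-identical
region recovery on both strands. mRNAs without a CDS are skipped with a
warning; a CDS segment outside its exons drops only that transcript;
annotation referencing a missing contig aborts. Codons containing `N`
count as neither ATG nor stop (conservative, rare); `N` at a scored
Kozak position contributes 0 bits. Class-1/2 uORF length is complete
codons from the ATG to the start of the CDS; class-3 length excludes the
stop codon.

## The two-wrong-frames null and why candidates matter

For composition-driven (neutral) 5'UTR sequence, an ATG that reaches the
CDS without stopping falls in the correct frame one time in three, so
class-2 candidates should be exactly twice class-1 candidates. This 2:1
null is *not* exact for reported records: with at most one record per
class per transcript, the probability of at least one hit in two frames
is less than twice the probability in one frame, and at realistic UTR
lengths the record-level ratio saturates near 1.8. The inventory
therefore carries both `candidate_counts` (where the binomial null is
exact) and the capped `class_sums` (which match the per-transcript
presence partition). Under the same null, class-1 and class-2 record
lengths are indistinguishable; both properties are asserted on neutral
synthetic genomes in the acceptance suite.

## Randomized controls

Four control constructions for 5'UTR sets, three replicates each by
default, with per-replicate seeds derived from a master seed by fixed
offsets:

* `scramble_each` — per-sequence permutation; preserves each sequence's
  exact composition and length.
* `random_by_dinucleotide` — new sequences from a first-order Markov
  chain matching the pooled ("5'UT-ome-wide") dinucleotide table, lengths
  copied from the source. An exact Altschul–Erickson Eulerian-walk
  shuffle (`dinucleotide_shuffle`) is available when per-sequence
  dinucleotide conservation is wanted instead.
* `mono_random` — zeroth-order analogue.
* `mutagenize` — per-position resampling at rate r ∈ {0.1, 0.2, 0.5}
  from the overall composition. Resampling may restore the original
  base, so the realized substitution fraction is ≈ r(1 − Σp²); it is
  reported as `effective_rate` alongside the nominal r.

Counts between genome and control are compared with Poisson standard
deviations (z = Δ/√(a+b)), starred at 0.05/0.01/0.001; length
distributions by two-sample KS.

## The Kozak information score

Reference initiator contexts train a position-information matrix over a
window of −10..+8 relative to the A of the ATG. Per position,
R_i = 2 − H_i bits (Shannon entropy over A/C/G/T) and the weight of base
n is w_i(n) = R_i p_i(n). A context scores K = Σ w_i(b_i) over the 16
scored positions; the three ATG anchor positions are excluded as
invariant. The window width is a package choice — the natural
asymmetric window covering the classical consensus core — and is
configurable; scores are comparable only within one window and matrix.
Contexts that would overrun the transcript 5' end are excluded and
counted, not padded. No small-sample entropy correction is applied by
default (with thousands of training contexts it is negligible); an
optional flag provides it.

## Mixture projection

The class-1 score distribution is modelled as c₁ × (reference
distribution) + c₂ × (random distribution) with the unconstrained
normal-equations solution c = (AᵀA)⁻¹Aᵀt and the proportion of variance
explained about the target mean. Weights are deliberately not confined
to the simplex (a constrained mode exists for sensitivity analysis);
weights outside [0,1] are flagged. Defaults: 40 equal-width bins over
the pooled score range.

One numerical subtlety matters at desk scale: when a basis vector is an
*empirical* histogram of a few hundred scores, its sampling noise
attenuates its fitted weight (classical errors-in-regressors shrinkage).
The pipeline therefore smooths the two bases and the target with one
identical Gaussian kernel (2 bins) before projecting. Smoothing is
linear, so the true mixture weights are preserved exactly —
blur(c₁b₁ + c₂b₂) = c₁blur(b₁) + c₂blur(b₂) — while basis noise, and
with it the attenuation, shrinks severalfold. A unit test asserts the
exact-preservation property.

The divergence point of two cumulative distributions (used to read off
the fraction of transcripts with sequence-specific conservation) is the
smallest abscissa where |CDF₁ − CDF₂| first exceeds a threshold (default
0.02), reported together with the CDF level there.

## Conservation tests

Both tests align peptide queries against an ortholog proteome and take
the maximum bit score per query. The internal backend is Smith–Waterman
(BLOSUM62, gap open 11 / extend 1) with bits via the gapped
Karlin–Altschul parameters for that matrix (λ = 0.267, K = 0.041); an
external `blastp` can be substituted for proteome-scale runs, with the
same interface. The max over subjects is taken independently per query;
a same-subject mode is available for sensitivity analysis. Scores never
go below 0 (no hit).

**Extension test.** Per class-1 uORF: s_ref (reference peptide), s_ext
(extension + reference), and two controls with the extension scrambled
at the peptide level, reference part untouched. The statistic is
`improvement = (s_ext − s_ref) − max(delta_scr, 0)` with `delta_scr` the
larger scrambled delta (the mean is also reported, since either could be
the published convention). Two positive-set rules are computed: the top
quantile (default 25%) of improvement, and the absolute rule
improvement > 4 bits. The quantile rule is the right conservative choice
on real data where the translated fraction is unknown; the absolute rule
tracks the conserved subset whatever its prevalence and is what the
pipeline trains the Bayes classifier on — on synthetic genomes the
quantile rule mislabels by construction whenever the true conserved
fraction differs from the quantile, and within the conserved set it
preferentially selects long extensions, biasing the training density.

**First-vs-second-ATG test.** For transcripts with an in-frame internal
ATG at least 25 codons before the CDS end: s0 (query from 25 aa past the
second ATG), s1 (from the second ATG), s2 (from the first). s1 > s0 is
the precondition that the region past the second ATG carries signal;
s2 > s1 then supports the reference ATG being genuinely inside the CDS.

## The Bayesian translation-probability classifier

Class-1 uORFs likely to be translated are longer and have stronger
initiation contexts. The classifier histograms positive (conserved
class-1) and negative (class-2) training points on a 30×30 grid of
u = 2^K (information is log-scaled, so u is linear in implied initiation
efficiency) and log₁₀ length (ORF lengths decay roughly exponentially),
Gaussian-smooths each surface, floors them with a pseudocount, and
reports the prior-0.5 posterior P(T|K,L) = p₊/(p₊ + p₋) cell-wise.
Numerical choices, all config keys recorded in the model object:

* **bandwidth 0.75 cells.** The u axis concentrates most mass in its
  lowest bins; wider kernels bleed the dense class-2 mass into the
  positive region and visibly miscalibrate the posterior on genomes with
  known translated fraction (mean posterior error grows with bandwidth
  beyond ~1 cell). Bandwidth 0 reproduces raw histograms for comparison.
* **common pseudocount floor** 1/((n₊+n₋)·cells), added to the
  *normalized* densities of both surfaces and renormalized, so a cell
  with no training evidence in either set returns exactly the prior 0.5.
  Per-set 1/n pseudocounts instead make empty cells report an artifact
  of the training-set size ratio.
* **clamping.** Out-of-grid points map to boundary cells, so every
  class-1 uORF receives a probability.
* **prior 0.5**, configurable; the default encodes the assumed 50:50
  split of translated and untranslated class-1 uORFs that the mixture
  projections estimate independently.

The ROC sweeps all distinct posterior values; AUC by trapezoid. On
Gaussian-separated score sets the ROC of the scores themselves matches
the closed form Φ(d′/√2); pushed through the histogram surfaces the AUC
is necessarily a little lower (binning ties), which is why the
closed-form check in the acceptance suite is made on the score ROC.

## The synthetic-data generator

`generate_genome` emits FASTA + GFF3 + ground truth for a multi-contig
genome with multi-exon transcripts on both strands; defaults: GC 0.65,
log-normal region lengths (5'UTR ~150 nt, CDS ~350 codons, 3'UTR
~400 nt), 1–4 exons per transcript. Background sequence is zeroth-order
at the spec GC (a dinucleotide mode exists for control-fidelity work).
Reference initiators receive contexts from a consensus-tilted model
whose tilt is calibrated numerically so the expected Kozak-score
separation from background equals `kozak_effect` (default 4 bits).
Implanted class-1 uORFs come in two kinds mirroring the structure the
analysis is meant to detect: *translated* implants get a strong context
and a long extension (log-normal, ~45 codons — conservation and length
covary in the motivating data), and are carried, diverged at the
configured identity (default 0.7 per residue), at the N-terminus of
their ortholog; *untranslated* implants get a neutrally placed ATG
(uniform over in-frame UTR positions, so their lengths resemble the
composition-driven class-2 population) and are absent from orthologs.
In-frame stops inside intended extensions and upstream in-frame
competitor ATGs are removed by bounded-retry resampling and minimal
single-base edits, so re-scanning recovers every implant at its recorded
position (recall 1.0 is asserted).

Two emulation caveats documented deliberately:

* with `kozak_effect > 0` the reference-context draw shapes the last
  10 nt of every 5'UTR, so those UTRs are not perfectly neutral; at a
  few thousand transcripts a scramble control can detect this footprint
  in class-1 lengths (KS D ≈ 0.12). This mirrors how a real initiator
  consensus shapes UTR tails. Analyses that need a genuinely neutral
  source (the control-behavior checks) use `kozak_effect = 0`.
* the generator does not emulate splice-signal sequence, repeats, codon
  usage beyond GC, or EST-style transcription-start uncertainty, so
  passing tests validate the statistical machinery, not annotation
  quality of any real genome.

## Problem sizes

The bundled analyses and acceptance runs use desk-scale genomes chosen
so the full workflow (including all-vs-all Smith–Waterman) completes in
minutes on one CPU: 4,000 transcripts for the neutral-genome counting
properties, 300–400 transcripts (CDS ~60 codons) for the end-to-end
split-recovery and conservation runs, 100,000 random contexts where only
context scoring is exercised. The oracle-equivalence and ROC checks run
at 1,000 UTRs and n = 5,000 scores respectively. At these sizes the
stochastic acceptance checks hold with comfortable margins across seeds;
all quantities scale to annotation-sized inputs through the same code
path with the external aligner backend.

## Known limitations

Near-cognate (non-ATG) starts are out of scope, as are overlapping-gene
resolution and transcript-model inference. The Kozak window is a package
convention, so absolute score values are not comparable across tools.
Bit scores from the internal aligner use fixed Karlin–Altschul constants
rather than per-search estimation, which is adequate for score
*differences* (the statistic used) but not for E-values, which are
deliberately not computed.
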