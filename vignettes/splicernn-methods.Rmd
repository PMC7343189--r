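---
title: "Predicting cassette-exon splicing from epigenomic context: models and methods"
author: "splicernn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cassette-exon splicing from epigenomic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most splicing in higher eukaryotes happens co-transcriptionally: the
spliceosome engages the nascent transcript while RNA polymerase II is still
elongating. The chromatin context the polymerase traverses — histone
modifications, accessibility, methylation, nucleosome density — therefore has
a natural temporal order, 5' to 3' along the direction of transcription, and
is a candidate carrier of splicing-regulatory information beyond the DNA
sequence itself. This package models the inclusion versus skipping of
cassette exons (internal exons that can be spliced into or out of the mature
transcript) from exactly this kind of input: one-hot DNA sequence plus
per-base epigenomic signal in windows around the two splice sites of each
candidate exon.

## Quantification

Exon-level expression is summarised as FPKM computed per exon,
`count / ((L / 1000) * (N / 1e6))` for exon length `L` and library size `N`,
and binarised at FPKM >= 1 to give the default inclusion label. This keeps
the label agnostic to overall transcript abundance structure.

Splicing itself is quantified by the junction-based percent-spliced-in.
Inclusion-supporting reads are length-normalised by `L_i + L_f` (an
inclusion read can start anywhere over the exon plus one fragment length)
and exclusion reads by `L_f`:

$$\tilde F^{incl} = \frac{F^{incl}}{L_i + L_f},\qquad
  \tilde F^{excl} = \frac{F^{excl}}{L_f},\qquad
  \Psi = 100\,\frac{\tilde F^{incl}}{\tilde F^{incl} + \tilde F^{excl}}.$$

PSI is undefined (class "undefined") when no junction evidence exists at
all. Class cutoffs are `<= 20` (skipped) and `>= 80` (included); the
boundary handling is closed on both cutoffs, a choice this package fixes
because open versus closed intervals are immaterial for continuous PSI but
must be deterministic for testing. Enrichment profiling uses the band
variant instead (low `<= 20`, mid `40-60`, high `>= 80`), matching how
stratified metagene figures are conventionally drawn; PSI values between the
bands are deliberately left unclassified there. The fragment length `L_f` is
a per-dataset scalar (default 100 bp) rather than something estimated from
data.

## Feature windows

For every cassette event we extract two windows, one at the 3' acceptor and
one at the 5' donor, each `2 * flank` positions long (default flank 100 bp,
hence 200 positions per site and a 400 bp total span per event — a span that
works well for this problem class; flank is a plain argument everywhere).
Windows are oriented 5' to 3' in transcription direction: on the minus
strand the per-base vectors are reversed and the DNA reverse-complemented,
so position index 1 of an acceptor window is always intronic and the last
index exonic, and conversely for the donor.

DNA is one-hot encoded in channel order A, C, G, T with ambiguity codes
mapping to all-zero rows. Epigenomic tracks are expected as enrichment
signal; the package provides the MACS-style primitive
`poisson_enrichment()`, the capped upper-tail `-log10` Poisson p-value with
cap 2 (from the p = 1e-2 ceiling used to contain the dynamic range of real
tracks), and `scale01()` clips to `[0, cap]` and rescales so every
epigenomic channel fed to the model lies in `[0, 1]`. Uncovered bases take
the track's fill value (0 by default). A deliberately small deviation from
the upstream description: the feature array for a window of `T` positions is
`T x 4` for DNA, not a fixed 1,000-row array, because the latter is
internally inconsistent with a 400 bp span.

## The two-branch recurrent model

Each window is consumed position by position, mirroring polymerase
progression. Three cell types implement the standard gate equations exactly
— simple `tanh` recurrence, LSTM (gates `f, i, o`, candidate `g`, cell state
`c_t = f \otimes c_{t-1} + i \otimes g`, output `h_t = o \otimes \tanh c_t`)
and GRU (update `z`, reset `r`, candidate with reset-gated hidden term,
`h_t = (1 - z) \otimes h_{t-1} + z \otimes` candidate). The exported step
functions (`lstm_step()` and friends) are the reference implementation of
those equations; the training path runs an exactly equivalent batched
forward/backward pass in compiled code, and the test suite holds the two
routes together to 1e-10 alongside an independently coded oracle and a
finite-difference gradient check.

The architecture is: acceptor and donor windows feed two separate branch
RNNs (size 200 in the full-scale configuration); their full hidden-state
sequences are concatenated along the position axis, acceptor first — the
merge layer thus "reads" the acceptor context then the donor context — and
consumed by a merge RNN (size 400) whose final hidden state passes through
dropout (rate 0.5 by default, inference-time identity) and a two-unit
softmax head. Training minimises binary cross-entropy with Adam
(lr 1e-3, beta1 0.9, beta2 0.999), 20 epochs by default. Branches returning
full sequences rather than final states is a considered choice: a merge
layer over a length-2 input would make its size pointless. Feature-axis
concatenation of the branch outputs would be an alternative merge; it is not
implemented.

Data are shuffled and split 80/20 into train+test, and the training part
80/20 again into fit/validation — 64/16/20 percent of the data, exact at
n = 100. Every source of randomness (partition, Glorot-uniform
initialisation, epoch shuffles, dropout masks) is drawn from the single
configured seed, so runs are bit-reproducible. There is no class
rebalancing and no stratification by default. The decision threshold on
P(inclusion) is 0.5.

Named presets fix the sizes: `main` (200/400) is the full-scale
configuration; `compact` (16/32, minibatch 64) is the configuration used by
the package's own synthetic benchmarks — on strongly separable synthetic
data the compact model is indistinguishable in accuracy from larger ones
while training in minutes on one CPU, and the vignette-stated problem sizes
below were all chosen with it; `interpret` (1 branch unit, merge 2,
400 epochs) is the simplified model used for gate-weight inspection.
Dropout is disabled in `interpret`: with a two-unit merge state, rate-0.5
dropout starves the head and the model cannot fit at all, which we verified
empirically before fixing the preset.

## Model interrogation

`extract_gate_weights()` reports, per branch and gate, the input weight
attached to every channel of the simplified model, for ranking and sign
inspection; with more than one hidden unit it falls back to mean absolute
weights per channel with a warning, since per-unit signs are then not
identifiable (hidden units can be permuted and sign-flipped jointly with
downstream weights — for the same reason even the single-unit model's
informative channel is only identified up to sign).

`leave_one_out_importance()` retrains with one channel removed at a time
(same seed, hence identical partition) and reports the drop in held-out F1
and ROC AUC against a reference-model mean; seed-to-seed variability of the
reference (3 retrainings by default) provides the band against which a null
channel's delta should be judged. Importantly, ablation deltas are only
interpretable when channels are not redundant: in the default synthetic
roster the activating, repressive and accessibility channels each suffice
for near-perfect classification, so ablating any one of them yields a
near-zero delta. That is correct behaviour, not a failure — and it is why
the dedicated `importance` generator preset with exactly one informative
channel exists for testing recovery. `feature_gain()` measures the
complementary add-one-in quantity against a DNA-only baseline, singly or in
pairs, over several seeded trials.

`cross_cell_test()` applies a trained model without retraining to another
dataset with the same channel registry; F1 is the headline metric there
because class balance need not transfer. `reversal_test()` evaluates a
forward-trained model on inputs whose epigenomic channels (not the DNA, by
default — the reversal probes the temporal claim about chromatin context)
have been flipped along the position axis.

## Metrics

Threshold metrics follow the standard confusion-matrix definitions;
F1 is the harmonic mean of precision and recall. ROC and PR curves are
built over all distinct score thresholds with ties grouped (this affects
AUC in roughly the fourth decimal relative to per-observation stepping);
ROC AUC uses the trapezoid rule, PR AUC step-wise interpolation, which is
conservative relative to linear interpolation between PR points. With
single-class labels the AUCs are reported as NA while threshold metrics
remain defined.

## Profiles and peaks

Metagene profiles average strand-oriented signal per position across events
within each PSI band, separately for the acceptor and donor; position 0 is
the first base past the boundary in transcription direction. Segment
comparisons reduce each event to mean signal per segment and compare bands
with the two-sided Mann-Whitney-Wilcoxon test — exact for combined n <= 20
without ties, normal approximation with continuity correction otherwise —
with the conventional star bins (ns, then `*` at 0.05 down to `****` at
1e-4) and no multiple-testing correction, deliberately matching common
figure annotation practice. The default segment scheme tiles [-100, 100)
around the acceptor in four 50 bp segments labelled A (distal intron),
C (proximal intron, the branch-point region), B (proximal exon), D (distal
exon); the scheme is a plain argument and any report should state it, since
segment extents are a convention, not a biological constant.

RBP peaks are filtered to score 1000 (the convention marking the strongest
peak calls), reduced to midpoints, and binned in 100 bp intervals over
+/-1 kb of each splice site, oriented 5' to 3'; frequencies are counts per
bp, with a per-site-normalised variant alongside. Midpoint reduction (rather
than interval overlap) keeps a peak in exactly one bin.

## The synthetic-data generator

The generator emulates the full input stack so every module is testable
offline: a uniform-composition toy genome with multi-exon genes on both
strands (canonical GT/AG dinucleotides written at 95% of intron boundaries
by default, the remainder non-canonical); a GENCODE-style GTF; per-base
signal tracks; binomial junction reads; and scored RBP peaks. Each internal
exon gets a ground-truth class (included/skipped, prevalence 0.5 by
default) and a true PSI drawn high (0.85-0.98) or low (0.02-0.15), with an
optional mid band. Junction totals are Poisson (mean 50 reads/event by
default — typical junction coverage for a well-expressed exon in a
moderately deep library); inclusion reads are binomial with the
length-biased success probability under which the PSI estimator is unbiased
for the true inclusion fraction.

Signal channels are specified as bumps (Gaussian, class-dependent
amplitude, anchored at transcription-direction offsets from a splice site),
ramps (monotone 5'-to-3' gradient over the anchor neighbourhood, slope set
by an asymmetry parameter; at asymmetry 0 the ramp degenerates to a
symmetric plateau, which is what makes the reversal null case well-defined),
or pure noise. White noise is added everywhere and tracks are clipped at
zero. The default roster couples an activating bump (amplitude 1 for
included events, 100 bp into the exon at the acceptor and 50 bp into the
exon at the donor — offsets chosen to echo where activating marks peak
around real exons), a repressive bump (amplitude 0.6 for skipped events), a
mild accessibility bump, and three noise channels, with noise SD 0.1-0.15:
a signal-to-noise regime of roughly 10:1, i.e. deliberately "strong-signal".

What passing tests on these data do show: the pipeline is wired correctly
end to end; the cells implement their equations exactly; the model can
extract class signal, channel identity and temporal direction when they are
present by construction; and quantification is unbiased under the stated
sampling model. What they do not show: performance on real epigenomes,
where signal is weaker, channels are correlated in complicated ways, labels
are noisy, sequence itself is informative, and class balance varies by cell
type. The synthetic genome has no motif grammar, no nucleosome phasing, no
methylation chemistry; its DNA carries no class information at all, so the
DNA channels act as a built-in negative control rather than a model of
sequence-driven splicing.

## Problem sizes and numerical choices

The package's benchmarks use the `strong-signal` preset (800 genes,
~2,000 cassette events, 6 signal channels, flank 100) with the `compact`
model for 20 epochs; leave-one-out uses the `importance` preset
(~1,000 events) at 8-10 epochs with one retraining per ablation (the
default is 3), enough for the reference models to converge so that their
seed-to-seed band does not swamp the ablation deltas; the reversal experiment uses the `direction` preset (~750 events,
flank 60, noise SD 0.35 so the margin is small enough for direction
perturbations to register) over 5 seeds at 8 epochs. These sizes were
chosen once as the smallest at which the respective effects are comfortably
resolved on a single CPU.

Other fixed numerical choices: softmax is computed with max-subtraction;
training loss clamps probabilities at 1e-12; bumps are truncated four widths
from their centre; bedGraph output rounds to 4 decimals (the tests account
for both truncations). The variability band for calling an ablation delta
"null" is floored at 0.02 F1, the resolution of a few label flips on a
~250-event test partition, because the range of three reference retrainings
can degenerate to zero when all runs are perfect.

## Known limitations

Training is CPU-only and single-threaded by design; the full-scale 200/400
configuration on ENCODE-sized inputs is out of desk-scale reach and
untested here. The GTF reader targets the GENCODE dialect (attributes
`gene_id`, `transcript_id`, optional `gene_type`, `exon_number`). Only
cassette events are modelled — no intron retention or alternative 5'/3'
splice sites — and candidate status is purely positional (any internal
exon), with inclusion labels supplied by expression or PSI downstream.
Cross-dataset transfer assumes channel registries match by name; no
attempt is made to align differently named assays.
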