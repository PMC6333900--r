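---
title: "Methods: phage-display enrichment analysis and one-site ITC fitting"
author: "ngpd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage-display enrichment analysis and one-site ITC fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngpd)
```

## Scope

Next-generation phage display (NGPD) replaces clone-by-clone immunoassay
screening of biopanning output with deep sequencing of the insert-coding
region. The experimental design this package models is a randomised
nonapeptide library fused to the N terminus of the M13 major coat protein
gpVIII, panned for three rounds against a target protein with a parallel
control-protein arm; the round-3 output of both arms is barcoded,
amplified and sequenced on an Ion Torrent-style single-end platform.
`ngpd` implements the complete desk-side analysis — demultiplexing,
three-frame translation, flank-anchored peptide extraction, enrichment
ranking by the two-proportion Z statistic, ZOOPS EM motif discovery — and
a one-site isothermal titration calorimetry (ITC) fitter for validating
candidate binders, together with generators that create every kind of
input synthetically with known ground truth.

## The synthetic-data generator

No raw sequencing accession accompanies the experiment the package
models, so all testing rests on simulation. The generator emulates, in
order:

1. **Library** (`build_library`): independent inserts uniform over the 20
   standard residues (the null model for a randomised library), each
   back-translated with synonymous codons drawn uniformly at random. The
   real library's codon scheme is unpublished; uniform synonymous choice
   is the neutral default and only the protein level matters downstream.
2. **Panning** (`simulate_panning`): per round, every clone's abundance
   is multiplied by lognormal amplification noise (mean 1, CV 0.3 by
   default) in both arms; clones designated true binders are additionally
   multiplied by the enrichment factor (default 10) in the target arm
   only. Frequencies are renormalised each round. The default factor and
   CV are illustrative: only round-3 output was sequenced in the design
   being modelled, so true per-round dynamics are unknowable; a factor of
   10 over 3 rounds (10^3 total) is in the range conventional polyclonal
   phage ELISA experiments imply, and CV 0.3 makes amplification noise
   visible without drowning the signal.
3. **Reads** (`emit_fastq`): multinomial sampling of 4 × 10^4 reads per
   arm (the reported count of meaningful reads per sample), each read
   `barcode + 0–2 nt frame-offset pad + AEGEF-flank DNA + insert DNA +
   DPAKAA-flank DNA + ~20 nt trailing context` (≈ 100 bp total, the
   reported mean read length), with i.i.d. substitution errors at 0.005
   per base. Frame offsets are uniform over {0, 1, 2} so that all three
   translation frames are exercised. Indels — the dominant Ion Torrent
   homopolymer error mode — are off by default and available through
   `indel_rate` purely to exercise the extractor's frame tolerance;
   quality strings are constant Q30 because the published workflow never
   consumes qualities.

What the generator does **not** emulate: PCR chimeras and barcode
hopping, phage propagation biology (helper-phage effects, growth-rate
selection), flow-space error structure, and library sequence biases.
Passing tests therefore demonstrate the *analysis* is correct under a
clean generative model, not that the laboratory protocol is free of
artefacts.

## Read processing

Demultiplexing assigns a read to the unique sample whose barcode exactly
matches the read's 5′ prefix and trims it; unassigned reads are counted,
never dropped silently. Exact matching (0 mismatches) is the default
because the two-step barcoding PCR leaves the barcode outside the
error-prone insert region and amplicon barcodes are short; a
`max_mismatch` knob exists.

Each read is translated in the three forward frames only (the library is
directionally cloned, so reverse-complement frames carry no signal).
Codons containing N become `X`, stops become `*`. The insert is the
substring strictly between the first `AEGEF` and the subsequent first
`DPAKAA` at the protein level; an extract is discarded if it contains
`*` or `X` (not a defined peptide) or, in the default fixed-length mode,
if it is not exactly 9 residues (the nonapeptide library). Counting
totals `n1`/`n2` are numbers of *extracted peptides* per sample, not raw
reads — "meaningful reads" in the sense of reads yielding a valid
extract.

## Enrichment ranking

For each peptide with `x1` copies among `n1` extracted target-arm
peptides and `x2` of `n2` in the control arm, the pooled two-proportion
Z statistic is

$$Z = \frac{p_1 - p_2}{\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_1} +
\tfrac1{n_2}\right)}},\qquad
p_i = x_i/n_i,\ \ \hat p = \frac{x_1+x_2}{n_1+n_2}.$$

The pooled form is the textbook default and satisfies the identity
Z² = χ²(1 df) of the corresponding 2×2 table without continuity
correction, which the test suite uses as an independent oracle; an
unpooled variant sits behind a flag. No pseudo-counts are added — a
peptide absent from the control arm legitimately earns a large finite Z
— and no multiple-testing correction is applied, because the statistic
is used as a *ranking score*, not as an inference: the top 50 peptides
go forward to motif discovery. Peptides seen only in the control arm
keep their negative Z in the ranking but are excluded from the motif
input. Ties break by target count descending, then lexicographically.

## Motif discovery

`em_fit` implements the ZOOPS (zero-or-one-occurrence-per-sequence)
mixture model: a peptide contains one motif occurrence with probability
λ at an offset uniform over admissible positions, drawn from a width-w
position weight matrix (PWM), or is pure background. EM alternates
posterior occurrence/offset computation with re-estimation of the PWM
(Dirichlet pseudo-count 0.01 spread over residues), λ, and the
background composition from the expected non-motif positions. Each of
`n_starts` initialisations seeds the PWM from one observed width-w
subsequence smoothed toward the background (weight 0.6 on the observed
residue), and the best final model is kept.

Numerical notes:

* The traced objective is the pseudo-count-regularised log likelihood;
  MAP-EM increases it monotonically (asserted to 1e-9 per iteration),
  whereas the raw likelihood can fluctuate within the pseudo-count
  magnitude. The raw log likelihood is reported at convergence.
* Convergence: relative objective change below 1e-6, cap 500 iterations.
* Membership is posterior occurrence probability > 0.5. When λ is
  estimated near 1 the prior dominates and weakly matching sequences can
  cross 0.5 — an intrinsic property of ZOOPS maximum likelihood worth
  remembering when reading membership lists from datasets without
  background sequences.
* Degenerate input (a single distinct peptide) converges to a trivial
  point-mass motif and is flagged.

`discover_motifs` finds several motifs sequentially: candidate widths
(default 6–8, bracketing the consensus widths of interest) are scanned,
the width maximising the likelihood ratio against the background-only
model is accepted, and the accepted motif's member *sequences* are
removed before the next search — the simplest faithful variant of
MEME-style probabilistic erasure. OOPS is available behind a flag.

Degenerate consensus patterns make the field's motif notation
executable: `"[YNHC]-c-L-c-h-R"` and `"L-X-L-h-X-X-S-[RP]"` encode the
two USP11-binding consensus motifs, with `c` the charged class
{D,E,K,R,H} and `h` the nonpolar class {A,V,L,I,M,F,W,P,G,C}. The
nonpolar set must be fixed for testability; G, C and P are included
(they are uncharged and apolar), a documented choice since class
definitions vary between authors. Per-position information content is
the relative entropy of each PWM row against the background (bits), the
column heights of a sequence logo.

## One-site ITC model

The cell is an overfilled perfusion cell: injecting cumulative volume
ΔV into active volume V₀ displaces liquid, giving the continuous
dilution expressions M = M₀e^(−ΔV/V₀) and X = Xₛ(1 − e^(−ΔV/V₀)) —
standard for MicroCal-style instruments; a discrete per-injection
(1 − v/V₀) mode exists as the oracle in the test suite (the two agree to
0.5% at 30 × 8 µl into 1.4 ml). The complex concentration is the
physical root of the mass-action quadratic, evaluated in the
cancellation-free form 2NMX/(b + √(b² − 4NMX)). Per-injection heats use
the displaced-volume correction
δQᵢ = Qᵢ − Qᵢ₋₁ + (vᵢ/V₀)(Qᵢ + Qᵢ₋₁)/2 with Qᵢ = V₀·ΔH·[complex]ᵢ,
normalised by moles injected, plus a constant dilution-heat offset
q_dil. Calories are used internally; enthalpies are kcal/mol at the
interface.

`fit_one_site` minimises uniform-weight squared residuals of the
normalised heats over (N, log K_a, ΔH, q_dil) with Levenberg–Marquardt,
multi-started over a log-spaced K_a grid (10³–10⁹ M⁻¹), standard errors
from the Jacobian at the optimum and the delta method for K_D. Choices:

* **First injection excluded by default** — syringe-tip diffusion during
  equilibration systematically corrupts it; standard practice.
* **N floated by default**; whether published fits fixed N = 1 is
  usually unstated, and floating N is the conservative choice.
* **c-value guard**: when c = N·M₀/K_D leaves [0.1, 1000] the isotherm
  shape no longer constrains K_D and its standard error is suppressed
  unless forced.
* Peak integration of raw power traces (baseline estimation) is out of
  scope; `integrate_power` handles synthetic traces only.

The simulation defaults used throughout testing mirror the documented
titrations of the two reported peptide ligands: 30 µM protein in a
1.4 ml cell, 300 µM peptide titrated in 30 × 8 µl injections at 25 °C,
generating K_D 8.86 µM or 6.92 µM. The generating ΔH (−8 kcal/mol) and
q_dil (−0.05 kcal/mol) are not published and were chosen once as typical
for an exothermic peptide–protein interaction of this affinity; at
c ≈ 3.4–4.3 they produce the shallow sigmoid these experiments show.
"2% noise" means Gaussian noise with σ equal to 2% of the peak model
heat. Under those conditions the median of 50 simulate-and-refit
replicates reproduces the generating K_D well within the experimentally
reported uncertainties, while the *per-replicate* scatter is ~25% — the
level the fits' own standard errors predict (1-SE coverage ≈ 75%);
claims of much tighter single-experiment K_D recovery at this noise
level and c-value are not supported.

## Pipeline and reproducibility

A single configuration (R list or YAML) drives all stages; every output
table carries a header with the stage name, seed and an MD5 hash of the
scientific configuration (paths excluded), and re-running a stage with
an identical configuration reproduces every non-log output
byte-identically. Per-stage read counts (total, assigned, extracted,
unique) are logged and conserve totals.

## Problem sizes

The test suite runs the study-scale spike-in recovery at its stated
conditions (10⁴ clones, 5 binders, 4 × 10⁴ reads per arm, 20 seeds) and
sizes pure Monte-Carlo calibrations (null Z calibration, noise-moment
checks, EM recovery) at a few thousand statistics each — sizes chosen so
the complete suite documents the claimed properties at useful power
while remaining a routine desk run.

## Known limitations

* Extraction requires both anchors intact; with ~100 bp reads the
  downstream anchor can be truncated, so real-data yields may undercount
  relative to pipelines tolerating a partial downstream anchor.
* The ZOOPS membership rule (posterior > 0.5) inherits the λ-dominance
  caveat above.
* The enrichment test treats arms as independent binomial draws; true
  multinomial correlations across peptides are negligible at these
  diversities but not modelled.
* The ITC module fits integrated heats; it does not reimplement
  baseline/peak processing of raw thermograms, two-site or competitive
  models, or global multi-experiment fits.
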