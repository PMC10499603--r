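---
title: "Methods: quantifying mitotic DSB repair from junctions, substrates, screens and isotherms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitotic DSB repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorepair)
```

`mitorepair` implements the computational side of a set of mitotic
DNA double-strand-break (DSB) repair assays: classifying Sanger-sequenced
CRISPR-cut amplicon repair products, modelling an extrachromosomal
microhomology end-joining substrate and its qPCR readout, scoring a
plate-based siRNA screen for Pol&theta; focus formation, and fitting
steady-state binding isotherms from bio-layer interferometry (BLI). This
vignette documents the models, the conventions and defaults that matter,
and the choices made where the underlying experimental description left
the design open.

## Repair-junction decomposition

A repair product (read) is compared with the reference amplicon (length
$R$) in a primer-anchored coordinate frame (0-based, half-open
coordinates; the cut position is a between-base index). Writing $p$ for
the longest common prefix and $s$ for the longest common suffix of
amplicon and read (length $S$), the decomposition is:

* $read = amplicon$: **unmodified** contamination. These products would be
  removed physically by restriction digestion before cloning; in silico
  they are excluded by the retained-site filter.
* $S < R$ and $p + s \ge S$: a **pure deletion** of $d = R - S$ bases.
  The junction **microhomology** is $m = \min(p + s - S,\, d)$: a stretch
  of $m$ identical bases flanks the deletion on both sides, so $m + 1$
  deletion placements reproduce the read exactly. The ambiguity is
  reported as the half-open interval $[p - m,\, p + 1)$ and the canonical
  placement deletes $amplicon[p,\, p + d)$, i.e. the placement that puts
  the shared bases on the left flank. The microhomology sequence is
  $amplicon[p - m,\, p)$.
* $p + s < S$ and $p + s \le R$: a **deletion with insertion**
  ($d = R - p - s$, $i = S - p - s$, inserted sequence
  $read[p,\, S - s)$), or a **pure insertion** when $d = 0$. Insertions
  carry $m = 0$ by convention; detecting templated insertions is out of
  scope.
* anything else (duplications, rearrangements): **unclassified**.

The cap $m \le d$ matters only for repeat-dense amplicons (e.g.
homopolymer runs), where flanking homology can nominally exceed the
deletion length.

### Exclusion filters

Following the experimental design, reads are excluded when they miss one
or both primer sequences or when the restriction recognition site
(default `GGTGA`, HphI) survives repair. Orientation is resolved by
searching the forward primer on both strands (both strands matching is an
error naming the read); primer matching is exact by default
(`max_primer_mismatches = 0`, matching the strict exclusion of the
assay), configurable for noisy Sanger ends. Site survival is assessed per
sequence: the site is retained iff its span lies entirely within the
read's unchanged prefix ($p \ge$ span end) or suffix. This is a statement
about the read, not about the intended lesion — a deletion whose placement
ambiguity admits a placement that misses the site genuinely retains the
site and is excluded.

### Tolerating Sanger base-call errors

Isolated substitutions break exact prefix/suffix arithmetic: one error in
the prefix of a clean deletion product turns it into an apparent
deletion-with-insertion whose "insertion" is just the reference sequence
with the error in it. Two mechanisms restore the call:

1. `align_fallback()` globally aligns read and amplicon (match +1,
   mismatch -4, gap open -8, gap extend -1), takes the largest contiguous
   gap as the deletion (more than one gap of 3+ bases is a complex,
   unclassified product) and recomputes $p$, $s$ and $m$ on the exact
   flanking sequences, so its output uses the same placement convention as
   the exact caller.
2. `call_junction_robust()` decides when to trust the fallback: a
   deletion-with-insertion call is re-examined only when its apparent
   insertion matches the reference start-aligned, end-aligned, or split
   between the two, with at most half its bases mismatching. This is the
   signature of substitution noise; a genuine junction insertion resembles
   neither flank. Interpretations are otherwise genuinely ambiguous — a
   3-base insertion next to an 8-base deletion and a 5-base deletion with
   3 substitutions can describe the same read — and the threshold
   documents which reading the pipeline prefers.

### Summaries

Deletion sizes are binned as `<10`, `10-60` and `>60` bp — the middle bin
is the signature of Pol&theta;-mediated microhomology end joining — and
"uses microhomology" means $m \ge$ `mh_min` among pure deletions.
`mh_min = 2` by default: 1-base overlaps arise by chance in a quarter of
random junctions, so counting them would overstate microhomology use. The
threshold is configurable since the experimental annotation does not state
one.

## The end-joining substrate model

The extrachromosomal substrate mimics two resected DNA ends: a 747-bp
double-stranded core carrying, at each end, an oligonucleotide duplex
whose long strand is laid out 5'&rarr;3' as a 4-nt ligation overhang
(compatible with the restriction-cut core), the double-stranded region
(17 bp on one side, 15 bp on the other), and a ~70-nt 3' single-stranded
overhang (69 and 71 nt). The printed "ss" lengths exclude the 4-nt
ligation overhang; `anneal_duplex()` encodes and checks this segmentation
(`ligation_overhang + ds + ss = long oligo length`).

In cells, two substrate fragments join head-to-tail: the two 3' overhangs
anneal through a short microhomology placed near their termini.
`find_annealing_microhomology()` searches the 3'-terminal window (default
10 nt) of each overhang for the longest k-mer (k &ge; 3) on one side whose
reverse complement occurs in the other side's window, breaking ties by the
smallest combined unannealed 3'-flap length, then leftmost. On the
published oligos this finds the designed 4-nt `GCAG` pairing with 2-nt
flaps on both sides. The window and `k_min` are design defaults — the
substrate was built around a single 4-mer and no search rule was stated;
3 is the shortest annealing length that is unlikely to occur by chance
within two 10-nt windows.

`predict_ej_product()` trims the flaps, fills the gaps and returns the
junction's top strand plus the full two-fragment product, then verifies
that a qPCR primer pair can amplify it (forward primer on the top strand
strictly upstream of the reverse primer's binding site). With the printed
primers, the end-joining pair amplifies only the junction product and the
GFP pair amplifies within a single fragment — the control/readout
structure of the assay. The 747-bp core is synthesised with the printed
primer-derived ends and GFP-qPCR site but random filler (labelled
synthetic); core-internal sequence plays no role in the junction model.

Relative repair efficiency uses
$\Delta C_t = C_t^{EJ} - C_t^{GFP}$ per sample,
$\Delta\Delta C_t$ against the mean $\Delta C_t$ of a user-chosen
reference condition, and efficiency $= 2^{-\Delta\Delta C_t}$.
Amplification efficiency is fixed at perfect doubling (configurable).
Which control condition the experiment normalised against is not stated,
so the reference condition is a required argument rather than a default.

## Screen scoring

Raw well values are % cells with &ge; 5 Pol&theta; foci
(`multi_foci_fraction()` computes this from per-cell counts; upstream
image analysis is out of scope). Each plate is corrected by Tukey's
two-way median polish (`stats::medpolish` behind `median_polish()`),
which iteratively subtracts row and column medians; corrected values are
residuals plus the overall effect. Defaults follow the common convention
(10 iterations, tolerance 1e-6 on the change in total absolute residual);
the screen driver allows more iterations since full convergence on a
16 x 24 plate is cheap. Missing wells are ignored and stay missing; fully
missing rows/columns get zero effects with a warning.

Robust Z-scores are computed per plate against the reference
(transfection-reagent-only) wells:
$RZ = (x - \mathrm{median}(ref)) / (c \cdot \mathrm{MAD}(ref))$ with the
raw MAD and $c = 1.4826$ by default — the standard normal-consistency
constant. The screen's description prints the constant as "1.14826",
which we read as a typographical variant of 1.4826; since the constant is
a plain argument, either value is reproducible exactly. Reference
statistics are computed per plate (the description is ambiguous between
per-plate and per-replicate pooling; per plate is the conservative
choice and is flagged here).

A gene is a hit when at least 2 of its siRNAs have $|RZ| > 2$ in the same
direction in at least 2 replicate experiments; single-siRNA genes are
never hits and are flagged underpowered. The hit rule is monotone:
strengthening a supporting siRNA's score can never un-call a hit.

## Steady-state binding

At equilibrium the BLI response follows the one-site isotherm
$R(C) = R_{max} C / (K_d + C)$. `fit_steady_state()` fits
$(\log K_d, \log R_{max})$ by Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`), which keeps both parameters positive without
constraints; standard errors come from the log-scale covariance by the
delta method. Defaults: $K_d$ starts at the geometric mid-range
concentration, $R_{max}$ at the maximum response; 500 iterations,
relative tolerance 1e-8. Fits require at least 5 concentrations spanning
an order of magnitude; grossly non-monotone responses warn. Fold changes
between ligands propagate first-order errors. Kinetic (association /
dissociation) fitting is out of scope — only steady-state $K_d$ values
are modelled. Unweighted least squares is the default; the titrations are
two-fold dilution series whose responses span less than an order of
magnitude, so proportional-error weighting changes little.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of their seed.

**Repair reads.** The generated locus is a 400-bp random amplicon with
unique 20-bp primer landing sites, the recognition site planted straddling
the cut (so any deletion that straddles the cut destroys it), and
direct-repeat pairs planted around the cut. Microhomology-class deletions
run between repeat copies, which is how microhomology-mediated junctions
arise in real loci; repeat lengths follow a categorical distribution over
2-6 nt (0.2/0.3/0.3/0.15/0.05) and deletion sizes are uniform on 10-60 bp.
These distributions are illustrative defaults: the experiments constrain
the ranges (a 10-60 bp deletion class present in wild type and absent in
the Pol&theta; null; microhomology use strongly reduced in the null), not
the shapes. The wild-type mixture is 10% unmodified, 15% small deletions
(1-9 bp), 55% microhomology-class deletions, 10% large deletions
(61-120 bp) and 10% junction insertions; the null profile moves the
microhomology class's weight into small (55%) and large (20%) deletions.
Truth $(d, i, m)$ is measured on the emitted read by direct placement
enumeration at generation time, so chance homology extensions are part of
the recorded truth rather than a recovery error. Substitution noise
(0.2%/base) is applied after truth is fixed, avoiding the 10 bases
flanking the junction (so truth microhomology survives) and the primer
landing sites (exact primer matching is the default filter); 5% of reads
are truncated into a primer. Junction insertions are drawn to differ from
the reference both start- and end-aligned across the deleted segment, so
insertion and substitution-noise interpretations never collide in
simulated data. Real Sanger data differ in all these respects —
chromatogram-level noise, errors near junctions, templated insertions —
so passing recovery tests demonstrate correctness of the decomposition
logic, not robustness to every chromatogram artefact.

**Screen plates.** The default library is 582 genes x 3 siRNAs laid onto
16 x 24 plates with 32 scattered reference wells per plate, three
replicates. Well values are a 20% multi-foci baseline plus additive
per-plate row and column effects (SD 3 each), Gaussian noise (SD 3), and
a shift of `effect_rz` x noise SD (default 4, negative direction) for all
siRNAs of planted hit genes (1% of genes). Values are clamped to
[0, 100]. Positional effect sizes comparable to the noise make the polish
consequential: skipping it visibly costs recall. The generator plants
whole-gene effects only — no off-target single-siRNA phenotypes, no
viability confounding, no edge evaporation patterns beyond additive
row/column terms.

**qPCR and BLI.** Ct tables follow
$C_t^{EJ} = C_t^{GFP} + \Delta C_t^{ref} - \log_2(\text{efficiency})$
plus Gaussian noise; isotherms add Gaussian noise to the closed form.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including CSV outputs.
* Ties in the annealing search: smallest combined flap, then leftmost.
* Ties between equal-score alignments: the aligner's leftmost gap, then
  recanonicalised to the deletion convention via placement shifts, so the
  fallback reproduces the exact caller's fields bit-for-bit on clean
  reads.
* `N` bases never match in prefix/suffix comparisons.
* Zero reference MAD is an error instructing the user to choose a
  fallback scale — never a silent division by zero.
* Empty call lists summarise to zero counts; an empty FASTA is an error.
* Reads shorter than the combined primers are unclassified with a
  warning; reads whose $p + s$ exceeds both lengths (duplication-like)
  are unclassified.

## Problem sizes used by the test suite

The packaged checks run the junction caller against a brute-force
placement-enumeration oracle over 200+ random amplicons (lengths 12-40)
and every single-segment deletion of each; genotype-recovery uses 500
reads per profile; the screen checks use the full 582 x 3 x 3 default
and a 200-gene variant; binding checks use 7-point two-fold dilution
series. These sizes give exact, exhaustive coverage where enumeration is
feasible and binomially tight estimates elsewhere.

## Known limitations

* Single-junction products only: multi-cut products, translocations and
  duplications are reported unclassified, not decomposed.
* The substrate model is sequence-level: no melting thermodynamics, no
  polymerase fill-in chemistry, no concatemers beyond the two-fragment
  junction.
* Screen scoring implements exactly the fixed robust-Z rule; there is no
  FDR control across genes and no viability normalisation.
* The synthetic GFP core is a labelled stand-in; only its ends and the
  qPCR primer sites are faithful.
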