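# mitorepair

Analysis toolkit for mitotic DNA double-strand-break (DSB) repair assays.
Mitotic cells repair Cas9-induced breaks through Polθ-mediated
microhomology end joining (MMEJ), which leaves a recognisable scar:
deletions concentrated in the 10–60 bp range whose junctions reuse short
direct repeats (microhomologies). `mitorepair` implements the four
computational procedures that quantify this biology:

* **Junction calling** — decompose Sanger-sequenced amplicon repair
  products into events. With `p` / `s` the longest common prefix/suffix
  between amplicon (length `R`) and read (length `S`), a pure deletion has
  `d = R − S` and microhomology `m = min(p + s − S, d)`; the `m + 1`
  equally valid deletion placements are reported as an interval. Reads
  missing a primer or retaining the HphI site (`GGTGA`) are excluded, and
  a global-alignment fallback rescues reads with isolated Sanger
  base-call errors.
* **End-joining substrate model** — segmentation of the two
  oligonucleotide duplexes that mimic resected ends (4-nt ligation
  overhang + 17/15 nt dsDNA + 69/71 nt ssDNA), the annealing
  microhomology search over the 3′ overhangs (finds the designed 4-nt
  `GCAG`), prediction of the head-to-tail end-joining product, and
  ΔΔCt repair efficiency: `efficiency = 2^−(ΔCt − mean ΔCt_ref)` with
  `ΔCt = Ct_EJ − Ct_GFP`.
* **Screen scoring** — per-plate Tukey two-way median polish to remove
  row/column artefacts, robust Z-scores
  `RZ = (x − median(ref)) / (1.4826 × MAD(ref))` against in-plate
  reference wells, and the replicate-aware hit rule (|RZ| > 2 in the
  same direction for ≥ 2 siRNAs in ≥ 2 replicates).
* **Steady-state binding** — one-site isotherm
  `R(C) = Rmax·C / (Kd + C)` fitted by Levenberg–Marquardt on log
  parameters, with affinity fold changes and propagated errors.

A fifth module generates seeded synthetic data for every assay (reads
with `(d, i, m)` truth tables, screen plates with planted hits and
positional effects, Ct tables, isotherms), so the whole pipeline is
testable without any external data. The methods vignette
(`vignettes/mitotic-dsb-repair-methods.Rmd`) documents models, defaults
and design choices.

## Worked example

The numbered scripts under `analysis/` run the full workflow on synthetic
data (`Rscript analysis/01_simulate_data.R` … `05_binding_analysis.R`,
outputs under `results/`). Stage 2 contrasts repair spectra between a
wild-type-like and a Polθ-null-like profile:

```
== wt ==
<sample_summary> 500 reads in, 431 events
  excluded: missing_fwd_primer 12, missing_rev_primer 14, missing_both_primers 0, site_retained 37
  deletion bins: <10 78, 10-60 249, >60 61
  fraction MH: 0.6907216, median deletion: 49
noise-free truth recovery: 264/264 reads exact

== polq_ko ==
<sample_summary> 500 reads in, 413 events
  excluded: missing_fwd_primer 12, missing_rev_primer 4, missing_both_primers 0, site_retained 66
  deletion bins: <10 270, 10-60 0, >60 89
  fraction MH: 0.1476323, median deletion: 6
```

Reading this: of 500 wild-type reads, 431 pass the exclusion filters and
classify as repair events; 58% of pure deletions fall in the 10–60 bp
MMEJ bin and 69% of them use ≥ 2 bp of junction microhomology (median
deletion 49 bp). The Polθ-null profile has an empty 10–60 bin, little
microhomology use and a 6-bp median deletion — the scar of MMEJ loss.
Every noise-free read's `(event, d, m)` call matches the generator's
truth table exactly.

Stage 3 validates the published substrate oligos (17/69 and 15/71 nt
segmentation; `GCAG` annealing microhomology with 2-nt flaps; the
junction qPCR primers amplify only the end-joined product) and recovers a
programmed 4-fold end-joining deficit as efficiency ≈ 0.24. Stage 4
recalls all planted screen hits with zero false positives — and shows
recall falling to 0.50 when the median polish is skipped. Stage 5 fits
Kd = 646 nM and 10.7 nM to two simulated titrations programmed 65-fold
apart (recovered fold change 60 ± 5).

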