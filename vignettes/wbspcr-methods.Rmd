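---
title: "Whole-body scanning PCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body scanning PCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbspcr)
library(dplyr)
```

Whole-body scanning PCR (WBS-PCR) turns a frozen sagittal whole-body
section of a mouse into a spatial map of a nucleic-acid analyte. The
section is laid over a pre-filled 1536-well plate, tissue is extracted
grid-wise into the wells beneath it, the lysates are transferred to a
384-well qPCR plate, and the per-well signals are reassembled into an
image of the original section. A typical section covers 363 wells of the
1536-well plate, which leaves 20 wells of the 384-well analysis plate for
reference samples and standards. This vignette explains the models behind
each stage of the package and the choices we made where the procedure left
them open.

## Plate geometry and the section matrix

Plates follow ANSI/SLAS geometry (pitch 9 / 4.5 / 2.25 mm for 96 / 384 /
1536 wells); `plate_format()` makes the pitch and A1 offset configurable
because overlay registration works in physical millimetres. Well labels
are spreadsheet-style (`A1` … `AF48` on the 1536 format) and round-trip
losslessly with 1-based row/column indices.

The original matrix was hand-drawn around the section; we package a fixed,
deterministic silhouette template with exactly 363 cells
(`build_default_section_matrix()`), built from geometric shapes (head and
trunk ellipses, ear, tail, legs) and adjusted at the boundary, cell by
cell in a fixed order, until the count is exact. Arbitrary user masks of
any size are accepted through `section_matrix()`. Section cells are
enumerated row-major; samples fill the analysis plate column-major. Both
orders are fixed so exports are reproducible bit for bit. Because
363 + 20 = 383, one analysis well remains: the default layout declares it
a blank rather than silently allocating a 21st reference well.

## Assay design rules

Small-RNA RT-qPCR assays use three oligos (`design_assay()`):

* the **RT/reverse primer** — a generic 5′ tail plus a 3′
  target-recognition sequence (TRS), the reverse complement of the
  template's 3′ terminus. The TRS defaults to 8 nt (admissible 6–12). If
  the primer would end in one of the eight self-complementary tetramers
  (`ccgg, aatt, ggcc, ttaa, atat, tata, cgcg, gcgc`) the length is
  adjusted: we try +1 nt first, then −1, then scan 6–12. The procedure
  only requires that a single-nucleotide adjustment disrupt the
  palindrome; the fixed order is ours, chosen so the same template always
  yields the same primer.
* the **forward primer** — the reverse complement of the anti-primer core
  at the 5′ end and a gene-specific 3′ region of at least 12 nt, maximal
  subject to at most 3 nt of overlap with the TRS footprint (counted in
  template coordinates) and a clean 3′ tetramer.
* the **anti-primer** — quencher-labelled
  `5'-AAATCGAGGGAGGGAG-BHQ2-3'`; in the anti-primer quenching readout it
  silences unincorporated forward primers so fluorescence tracks
  double-stranded product.

The generic RT tail is not dictated by the protocol; we ship a small tail
library and pick the first tail with no complementary run of ≥ 6 nt
against the template whose full primer reaches the minimum melting
temperature (default 50 °C). Tm uses the unified nearest-neighbor
parameters with the standard entropic salt correction (defaults 50 mM
Na⁺, 250 nM total strands); the implementation is verified against an
independent reference implementation in the test suite.

Chemical-ligation qPCR (`design_ligators()`) targets analytes that resist
reverse transcription, such as fully 2′-MOE-modified antagomirs. The
reverse complement of the analyte is split at a junction — `floor(n/2)` by
default, shiftable with `junction_offset` — into an upstream core that
receives the 3′-phosphorothioate and a downstream core that receives the
5′-biphenylsulphonyl leaving group; hybridizing side by side on the
analyte, the phosphorothioate displaces the sulphonate and forms a
carbon–sulphur-linked PCR-amplifiable product. Default tails are the
shipped PCR-primer landing sites; with `junction_offset = -1` on the
22-nt anti-miR-16 analyte the designer reproduces the shipped 10/12-nt
ligator pair exactly.

`validate_assay()` re-derives every rule from the sequences, so manually
edited designs can be audited; designer output always validates (a
closure property tested over seeded random templates).

## Quantification

Calibration (`fit_standard_curve()`) is the standard log-linear model
`Ct = intercept + slope · log10(concentration)` fitted by least squares
to per-concentration mean Cts. The protocol invokes the "linear range of
the standard curve" without defining it; our operational definition is
the longest contiguous run of at least 4 dilution points with fit
R² ≥ 0.98 and every residual within 0.5 Ct, ties resolved toward the
high-concentration end. Efficiency is `10^(-1/slope) − 1`; the limit of
detection is the lowest concentration detected in all replicates
contiguously from the top of the series (the replicate fraction is
configurable). All three thresholds are parameters, not constants.

Noise filtering follows the chemistry: TaqMan and genomic-18S records are
noise when censored or when Ct exceeds 35 — read strictly, so Ct = 35.0
is retained and the boundary is pinned by a test. Small-RNA and CL-qPCR
records are noise when censored or when the back-computed concentration
leaves the standard curve's linear range. Filtering is idempotent and
logs a reason per well.

Per-well signals are normalized against genomic 18S, which measures cell
content and extraction efficiency. The published figures do not state the
formula, so both plausible forms are exposed: the default divides
back-computed quantities; `method = "delta_ct"` uses `2^-(ΔCt)` when no
curves exist. `percent_of_max()` reproduces the figure convention of
setting the maximum averaged signal to 100%, and
`cross_reactivity_matrix()` the convention of setting each primer set's
perfectly matched target to 100% (replicate quantities are averaged
before the ratio; below-LOD entries score 0%).

## Spatial reconstruction

`grid_from_records()` inverts the plate mapping: each sample well's value
is placed at its section cell; reference and blank wells never reach the
grid; noise and missing wells become invalid cells. Rendering
(`render_grid()`) is per-image max-normalized and nearest-neighbor — each
cell becomes a square pixel block, matching the plate's true resolution;
no smoothing is applied by default. Overlay registration
(`overlay_photo()`) is per-axis scale plus translation, which suffices
for a plate photographed flat; `alpha` interpolates between photo and
rendering. Grids export as TSV (bit-exact round trip, `NA` sentinel for
invalid cells) and optionally as Analyze 7.5 `.hdr`/`.img` pairs
(32-bit little-endian float, invalid cells as NaN) for imaging viewers.

## The synthetic section simulator

Every stage is exercised without downloads by a simulator
(`make_default_section()`, `simulate_ct()`) whose defaults are the study
conditions the rest of the package assumes:

* **Geometry** — the packaged 363-cell silhouette with contiguous organ
  regions (brain, spinal cord, lung, heart, blood, liver, spleen, kidney,
  GI; remaining body cells are muscle).
* **Expression atlas** — qualitative presence/absence per tissue: a
  liver-restricted, a heart-restricted and a brain-restricted miRNA
  (1e-4 curve units where present), two ubiquitous miRNAs (5e-5) and
  genomic 18S everywhere (1e-3). Real per-organ magnitudes are not
  publicly tabulated; the atlas encodes the qualitative patterns only.
* **Response model** — `Ct = 20 + slope · log10(effective abundance)`
  with slope `-1/log10(2)` (ideal 100% efficiency, ≈ −3.32 Ct per
  decade), Gaussian noise (default 0.2 Ct), censoring at the chemistry's
  cycle maximum (40 / 50), cross-reactivity as additive effective
  abundance before the log (the simplest model consistent with a
  percentage readout), and a hard detection collapse for end truncations
  beyond 2 nt — the observed behaviour is a rapid sensitivity decrease,
  for which we substitute a sharp threshold with configurable tolerance.
* **Extraction field** — a mild brain elevation (factor 1.5) by default,
  emulating the elevated genomic-18S levels seen in dense tissue and
  demonstrating why reference normalization matters.
* **Dosing scenario** — `apply_scenario()` multiplies the targeted miRNA
  by `1 − knockdown` (default 0.9) outside spared tissues (default:
  brain, which the antagomir does not reach), leaves the control miRNA
  untouched, distributes the antagomir analyte to non-spared tissues, and
  attaches a single-exponential plasma time course whose decay constant
  is set to cross the detection limit within one hour. The exponential is
  a deliberate toy: it exists to exercise the CL-qPCR quantification
  path, not to model pharmacokinetics.

All randomness flows through explicit seeds; identical seeds give
bit-identical records.

What passing simulations show — and what they do not: the simulator has
no well-to-well diffusion, no RNase degradation, no partial-extraction
spatial gradients beyond the configured field, and its noise is Gaussian
in Ct. Pipeline properties proved on it (mapping bijectivity, filter
boundaries, curve recovery within stated tolerances, localization of
restricted targets, knockdown recovery) are necessary, not sufficient,
conditions for performance on real sections.

## Worked example

```{r example}
sec <- make_default_section()
lay <- map_to_analysis_plate(sec$matrix)
model <- assay_model(noise_sd = 0)
recs <- simulate_ct(sec, default_expression_atlas(), model, lay, seed = 1)

curve <- fit_standard_curve(simulate_dilution_series(model, seed = 1))
glance(curve)

curves <- list(mir122 = curve, mir208a = curve, mir124 = curve,
               mir191 = curve, mir16 = curve)
recs <- recs |> apply_noise_filters(curves) |> quantify_records(curves)
norm <- normalize_to_reference(recs[recs$assay_id == "mir122", ],
                               recs[recs$assay_id == "genomic_18s", ])
grid <- grid_from_records(norm, sec$matrix, lay, value = "ratio",
                          valid = "valid", assay_id = "mir122")
grid
autoplot(grid)
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full 363-well
section, 14-point dilution series with 3 replicates, 100-template design
panels and 50-repetition curve-recovery studies; these sizes match the
protocol's own scale, and the whole suite completes in well under a
minute. Degenerate inputs are defined rather than accidental: a
single-concentration series is legal for `make_dilution_series()` but not
fittable; an all-invalid profile is an error for `percent_of_max()`; a
self-reverse-complementary ligation analyte designs with a warning (its
cores are each other's reverse complements, which a practitioner should
see). Concentrations are canonicalized to ng/µl (1 zg/µl = 1e-12 ng/µl
exactly); Ct comparisons use the raw floating-point values with the
boundary semantics stated above.

## Known limitations

Ct values are inputs: there is no baseline correction or Ct calling from
raw fluorescence. Group statistics on organ panels are left to standard
R facilities. Registration is scale + translation only. The silhouette
and atlas are stylized; they support method validation, not biological
inference.
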