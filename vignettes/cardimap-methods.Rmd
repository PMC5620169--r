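---
title: "Mapping left-ventricular gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping left-ventricular gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardimap)
```

## The problem

Catheter-based electroanatomical mapping systems (such as NOGA) build 3D
maps of the ventricle from point-wise voltage measurements and project them
onto a 2D "bulls-eye" polar display, apex at the center and base at the rim.
cardimap repurposes that display idea for molecular data: qPCR-derived
relative expression values measured at dozens of biopsy locations across the
left ventricle (LV) replace the voltages, yielding per-gene 2D and 3D maps
of spatial expression, followed by two quantification procedures — ischemic
versus remote zone statistics and an AHA 17-segment descriptive analysis.
The intended scenario is a porcine repetitive ischemia/reperfusion (r-I/R)
study with three groups (sham control, 5 h and 24 h after r-I/R of the mid
LAD territory) and 52 biopsies spread evenly over the LV of each heart.

## LV surface model and polar coordinates

The LV epicardial surface is modeled as a prolate hemiellipsoid with apex at
`(0, 0, -L)` (semi-axes: apex–base length `L`, default 80 mm; basal radius,
default 30 mm), optionally truncated at a fraction of the meridian. A
parametric surface rather than a reconstructed mesh keeps the synthetic
study, the coordinate transforms and the 3D rendering free of any mesh
estimation step.

The bulls-eye radial coordinate `rho` in `[0, 1]` is the *arc-length*
fraction of the apex-to-base meridian (0 = apex, 1 = basal rim). Arc-length
normalization was chosen over alternatives (chord fraction, z-fraction)
because it makes `rho` uniform in geodesic distance along the wall, which is
the natural reading of "equal distribution" of biopsy sites; this is a
package design choice, as polar-projection conventions differ between
mapping consoles. The angular coordinate `theta` is measured
counterclockwise on the displayed disk with the anterior wall centered at
90° (12 o'clock) and the septum at 9 o'clock — the conventional orientation
of AHA bulls-eye displays. The apex is angularly degenerate; its `theta` is
reported as 0 by convention. Both conversion directions share one tabulated
arc-length spline, so round trips agree to better than 1e-9.

## AHA 17-segment scheme

Ring boundaries at `rho` = 0.25, 0.5, 0.75 delimit the apical cap
(segment 17), an apical ring of four 90° sectors (13–16), a mid ring of six
60° sectors (7–12) and a basal ring of six 60° sectors (1–6), numbered
counterclockwise from the anterior wall. Intervals are half-open in both
coordinates (with `rho = 1` owned by the basal ring), so every boundary
point has exactly one deterministic owner and the 17 segments partition the
disk without gaps or overlaps.

The default 52-location sampling layout is deterministic: concentric rings
of 4/12/16/20 locations at `rho` = 0.125/0.375/0.625/0.875, each ring
starting at 90°. This reproducible layout places at least one location in
every segment; optional seeded jitter emulates hand-placed biopsies.

## Relative quantification (ΔΔCt)

Technical replicates are averaged per well; wells with replicate SD above
0.5 cycles (a common laboratory convention) are QC-flagged but not removed.
For each sample, `ΔCt = Ct(target) − mean(Ct(references))`; the arithmetic
mean of reference Cts is exactly the geometric mean of reference quantities
in linear space, which is the intended multi-reference normalization. The
calibrator defaults to the gene-wise mean ΔCt over all control-group
samples (no single calibrator sample is canonical in this design; a named
sample, e.g. a basal posterior reference location, can be supplied
instead). Fold change is `E^(−ΔΔCt)` with `E = 2` exactly by default; when
a standard curve (Ct vs log10 quantity over five 1:8 dilutions) is
attached, its fitted efficiency `E = 10^(−1/slope)` replaces 2 for the whole
run — run-level efficiency correction rather than per-well quantity
rescaling, the more conservative of the two readings of curve-based
normalization.

## Display scale, interpolation and color

Because voltage maps cannot show negative values, fold changes are mapped
to a 0–100 display scale: minimum to 0, maximum to 100. With an anchor (the
reference location's fold change) the map is piecewise linear with the
anchor pinned exactly at 20, so the reference lands at the same display
value for every gene; plain min–max is the non-anchored default.

Scattered display values are interpolated onto the disk by inverse-distance
weighting (power 2). IDW was chosen because it is exact at the sample
points, bounded by the input range (no overshoot into impossible display
values), deterministic and parameter-light; the interpolation used by
clinical consoles is unpublished, so no attempt is made to imitate one.
Interpolation is performed on display-scaled values (convert, then map);
interpolating raw fold changes first is available behind a flag. The color
scale runs red (0, strongest down-regulation) through yellow (10) to green
at the anchor (20), then blue (60) and pink/magenta (100); green is placed
at the anchor to reconcile "yellow near the reference" text conventions
with "green = baseline" figure conventions in this display family.

## Zone statistics

The ischemic zone is a manually delineated polygon on the 5 h map,
transposed verbatim onto the control and 24 h maps (all maps share the
same 52 locations, so transposition is an exact set identity, and this is
verified at run time). Point-in-polygon classification uses the even-odd
rule with boundary points counted inside — some fixed rule is required for
samples exactly on the contour, and "inside" keeps the delineated samples
with the zone they were drawn around. The remote zone is the complement of
the polygon within the disk. A contour-based helper can *suggest* a polygon
at display ≥ anchor + 30, but the manual polygon remains the interface.

The unit of analysis is the animal: per animal × gene, fold changes are
averaged inside and outside the zone before any inference, avoiding
pseudo-replication of the 52 within-heart samples. Groups are compared by
one-way fixed-effects ANOVA, with all three pairwise pooled-variance t
tests adjusted by the Holm–Šidák step-down procedure
(`adj_(i) = max_{j≤i} [1 − (1 − p_(j))^(m−j+1)]`, clipped to 1). The fully
degenerate ANOVA case (zero between- and within-group variance) is defined
as `F = 0, p = 1`.

## 17-segment relevance criterion

Per gene × group × segment, fold changes are summarized by mean and SD,
pooling locations across the group's animals (about three locations per
segment per heart is too few for formal per-segment inference). A segment
difference between control and a treatment group is called *biologically
relevant* when `|mean_control − mean_treatment| > 2 × SD`, strictly. The
variability term is read as the two-sample pooled SD of the two segments'
location values — the most defensible interpretation; two alternatives
(2 × SD of the two means, 2 × the sum of the two SDs) are implemented
behind a `rule` switch since the phrase is genuinely ambiguous. Segments
where either group has fewer than two values are *undetermined* and
rendered grey, never red; flagged segments are rendered red on a schematic
17-segment polar display.

## Synthetic study generator

The generator emulates the study conditions end to end: 52 locations,
groups control n = 8, 5 h n = 6, 24 h n = 6, 7 target genes (CASP3, CLU,
ERCC4, GATA4, HK2, MEF2C, HIF1A) and 3 references (GAPDH, HPRT1, PPIA),
two technical replicates, Ct noise SD 0.25 cycles, and an animal-level
effect (SD 0.15 cycles) additive in Ct and shared across all genes of an
animal — it mimics loading/RNA-quality variation and cancels in ΔCt by
design, which the tests exploit.

The spatial effect field on the bulls-eye plane is
`log2FC(d) = core_amp · w(d) + remote_amp · (1 − w(d))` with
`w(d) = min(1, k(d)/0.5)` and `k(d) = exp(−d²/(2σ²))`, where `d` is the
distance to the ischemic core center (default `rho` 0.35 at 90°,
apical-anterior mid-LAD territory; σ = 0.25). Ground-truth zone membership
is `k ≥ 0.5`. The plateau weight — full core amplitude throughout the
membership region, Gaussian shoulders outside — was chosen deliberately
over a pure Gaussian mix: it makes the configured core amplitude equal to
the actual inside-zone effect, so parameter recovery ("a configured
log2FC of 2 must come back as a zone fold-change ratio of 4") is
well-defined rather than diluted by the kernel's within-zone decay.
Per-gene amplitudes encode the qualitative spatiotemporal patterns the
panel is known for (e.g. HK2 core-up/remote-down at 5 h and globally down
at 24 h; GATA4 and ERCC4 persistently core-up; MEF2C flat); control
amplitudes are zero.

What the generator does *not* emulate: spatial autocorrelation of noise,
infarct border-zone histology, fibrotic basal tissue composition, animal ×
gene interactions, or pipetting/plate effects beyond the shared animal
term. Passing tests therefore demonstrate correctness of the computational
pipeline under a plausible noise model, not robustness to every artifact of
real tissue qPCR.

## Numerical choices and problem sizes

Round trips of the coordinate transforms are tested at 1e-9; ΔΔCt is
checked against an independent linear-quantity-space oracle at 1e-12
relative; the partition of the disk is validated on 1e5 uniform points
against analytic sector areas (1% absolute). The validation suite runs a
1000-replicate null simulation (all amplitudes zero) for the familywise
type-I error of the zone analysis (observed ≈ 4%, bound 6%) and a
200-replicate recovery experiment for the segmental 2×SD criterion; the
bundled acceptance script uses 300 and 50 replicates respectively, sizes
chosen to keep a full from-scratch rerun around a minute on one core while
leaving Monte-Carlo error well inside the asserted margins.

## Known limitations

No spatial autocorrelation correction and no mixed-effects modeling (the
per-animal averaging sidesteps, but does not model, within-heart
correlation); the 9-segment display variant of mapping consoles is not
implemented (non-standardized); proprietary console export formats are not
read — locations and Ct values enter as plain CSV.
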