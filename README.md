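# cardimap

Spatial "image-omics" mapping of left-ventricular (LV) gene expression in
R. cardimap projects per-location qPCR fold changes of the LV onto the 2D
bulls-eye polar maps and 3D surface renderings familiar from
electroanatomical (NOGA-style) voltage mapping — expression values take
the place of voltages — and runs the two quantification procedures that go
with such maps:

- **Ischemic / remote zone statistics.** A polygon delineated on the 5 h
  post-ischemia map is transposed verbatim onto the control and 24 h maps;
  per-animal mean fold changes inside and outside the zone are compared by
  one-way ANOVA with Holm–Šidák step-down post-hoc adjustment.
- **AHA 17-segment analysis.** Per-segment means/SDs of fold changes with a
  descriptive 2×SD relevance criterion: a control-vs-treatment segment
  difference larger than twice the pooled SD of the two segments is flagged
  and drawn red on a schematic 17-segment polar display.

The quantification core is the ΔΔCt method: for each sample,
ΔCt = Ct(target) − mean(Ct of the reference genes GAPDH, HPRT1, PPIA)
(arithmetic mean in Ct space ≡ geometric-mean normalization in quantity
space), ΔΔCt subtracts the calibrator's gene-wise ΔCt (default: the
control-group mean), and fold change = E^(−ΔΔCt) with E = 2 or the
efficiency E = 10^(−1/slope) fitted from a five-point 1:8 dilution
standard curve. Display maps use a 0–100 scale (min → 0, max → 100,
optional reference anchor pinned at 20) interpolated by inverse-distance
weighting, which is exact at the sample points and bounded by the input
range.

A fully parameterized synthetic-study generator (52 locations; groups
control n = 8, 5 h n = 6, 24 h n = 6; 7 target + 3 reference genes;
replicate-level Ct noise; animal random effects; a localized
apical-anterior ischemic effect field with ground-truth zone membership)
makes the entire pipeline testable without any external data.

## Worked example

```r
library(cardimap)

st <- simulate_study(seed = 1)
st
#> Synthetic LV study: 20 animals (control n=8, ir5h n=6, ir24h n=6),
#>   52 locations, 10 genes, 20800 Ct records (seed 1)

expr <- delta_delta_ct(collapse_replicates(st$ct))
zone <- ground_truth_zone_polygon(st$config)   # or read_zone_json("zone.json")
zs   <- zone_summaries(expr, transpose_zone(zone, st$locations))
comp <- compare_zone_groups(zs)
subset(comp, gene == "HK2" & zone == "ischemic")
#>    gene     zone         contrast    f  anova_p    p_raw    p_adj significant
#> 31  HK2 ischemic control vs ir24h 1180 5.81e-19 1.69e-11 1.69e-11        TRUE
#> 32  HK2 ischemic  control vs ir5h 1180 5.81e-19 3.75e-13 1.13e-12        TRUE
#> 33  HK2 ischemic    ir24h vs ir5h 1180 5.81e-19 5.75e-12 1.15e-11        TRUE
```

Hexokinase-2 behaves as configured in the generator: strong ischemic-zone
up-regulation at 5 h (zone mean fold-change ratio vs control 3.79, true
value 4), severe global down-regulation at 24 h (ischemic ratio 0.36,
remote ratio at 5 h 0.80), and every pairwise contrast significant after
Holm–Šidák adjustment. The standard curve on an ideal 1:8 dilution series
returns the textbook values:

```r
fit_calibration_curve(8^-(0:4), c(20, 23, 26, 29, 32))
#> Calibration curve: slope -3.3219 cycles/log10, E = 2.0000, R^2 = 1.0000
```

Rendering, per gene × group:

```r
loc  <- st$locations
uv   <- cbind(loc$rho * cospi(loc$theta_deg / 180),
              loc$rho * sinpi(loc$theta_deg / 180))
hk   <- subset(expr, gene == "HK2" & group == "ir5h")
fc   <- tapply(hk$fold_change, hk$sample_id, mean)[loc$location_id]
disp <- rescale_display(fc)
render_bullseye(idw_interpolate(uv[, 1], uv[, 2], disp),
                file = "hk2_5h.png", title = "HK2 (5h)", zones = zone)
write_mesh_ply(render_3d_surface(uv[, 1], uv[, 2], disp), "hk2_5h.ply")
```

`run_pipeline()` chains all stages (quantification → maps → zone statistics
→ segment flags) into a result bundle with a JSON manifest; the same
workflow is scriptable via `exec/cardimap` with subcommands `simulate`,
`quantify`, `map`, `zones`, `segments` and `run`.

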