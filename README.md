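# ssaxs — scanning SAXS analysis of soft tissue

`ssaxs` is an R package for analyzing scanning small-angle X-ray
scattering (sSAXS) raster maps of soft tissue — the kind of data used to
judge how fixation, embedding and cryopreservation protocols alter the
nanostructure of muscle and its collagenous connective tissue. It is aimed
at beamline users and tissue scientists who have per-point azimuthally
segmented scattering curves I(q, φ) and want per-pixel structural indices
and defensible cross-sample statistics.

## What it computes

Each scan point holds a 16-sector × ~1200-bin intensity slab. The pipeline
derives, per point:

* **Region label** (collagen / muscle / other / background) from the
  intensity exponent α — the log–log slope of I(q) over
  q = 0.085–0.095 nm⁻¹, positive on the rising edge of the first-order
  collagen peak — with a sixth-order-reflection fallback for processed
  samples that lost the first order.
* **Orientation** from the π-periodic cosine model
  I(φ) = a_sym + a_asym·cos 2(φ − θ_s), computed as the discrete 2φ
  Fourier component (equivalently, the least-squares cosine fit); the
  degree of orientation is a_asym/a_sym.
* **Collagen axial structure** from Gaussian fits of the meridional Bragg
  orders at q_n = 2πn/D: the D-period D = 2πn/q_n (orders 5 and 6), peak
  FWHM, the dehydration index I₆/I₅ (integrated intensities), and the
  overlap/D-period fraction x = O/D by inverting the two-phase step-density
  ratio r(x) = [n/(n+1)]²·sin²((n+1)πx)/sin²(nπx) toward the intact-fibril
  reference x = 0.46.
* **Myofilament lattice** from the equatorial (1,0)/(1,1) doublet:
  d = 2π/q spacings, lattice constant a = 2·d₁₀/√3, widths, and the
  rigor-sensitive intensity ratio I₁,₁/I₁,₀.

Across samples it summarizes per-region distributions box-plot style and
compares them against a declared reference with the two-sided Wilcoxon
rank-sum test (exact for small n, kurtosis-corrected normal approximation
otherwise), reporting medians, percent changes and significance stars.

A built-in simulator forward-models all of this — power-law background,
step-density order weights, von-Mises-style azimuthal kernels, Poisson
noise, preservation-method presets (`unprocessed`, `dehydrated`,
`tough_resin`, `paraffin`, `cryo`) — and provides the ground truth that
the test suite checks recovery against. See the methods vignette
(`vignettes/ssaxs-methods.Rmd`) for the full model and its assumptions.

## Worked example

```r
library(ssaxs)

gt   <- make_ground_truth("unprocessed", 20, 20, seed = 1)
scan <- simulate_reduced_scan(gt, seed = 2)
res  <- run_pipeline(scan)       # segment, orient, fit peaks, summarize

res$region
#> <region_map> background: 76, collagen: 139, muscle: 115, other: 70

tab <- res$table                 # one row per scan point
median(tab$D5, na.rm = TRUE)               # 66.740  (nm, collagen D-period)
median(tab$overlap_fraction, na.rm = TRUE) # 0.460   (O/D, hydrated reference)
median(tab$i6_over_i5, na.rm = TRUE)       # 0.502   (dehydration index)
median(tab$d10, na.rm = TRUE)              # 37.99   (nm, muscle lattice)
median(tab$i11_over_i10, na.rm = TRUE)     # 0.403   (resting-state ratio)
```

The fresh-tissue medians sit at the simulator's ground truth: a ~66.7 nm
D-period with the overlap fraction at the intact-fibril value 0.46, and a
resting muscle lattice (d₁₀ ≈ 38 nm, I₁,₁/I₁,₀ ≈ 0.4). Comparing against a
dehydration-type preparation:

```r
scan_d <- simulate_reduced_scan(make_ground_truth("dehydrated", 20, 20, seed = 3), seed = 4)
cmp <- compare_samples(list(unprocessed = res, dehydrated = run_pipeline(scan_d)),
                       reference = "unprocessed")
cmp[cmp$parameter %in% c("D5", "overlap_fraction"), ]
#>          parameter      sample   n  median median_pct_change p_value stars
#>                 D5 unprocessed 138 66.7403                NA      NA  <NA>
#>                 D5  dehydrated 160 65.4112            -1.991       0   ***
#>   overlap_fraction unprocessed 138  0.4599                NA      NA  <NA>
#>   overlap_fraction  dehydrated 160  0.4199            -8.693       0   ***
```

Dehydration shows up exactly as expected: the D-period median shrinks by
~2% and the overlap fraction drops to ~0.42, both highly significant.

`run_pipeline(scan, out_dir = "out/")` additionally writes the per-point
CSV, the region / orientation / ratio PNG maps, the distribution summaries
and the configuration used. A thin command-line front end with verbs
`simulate`, `analyze` and `compare` is installed at
`inst/scripts/ssaxs.R`.

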