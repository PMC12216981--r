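# topotrace

Automated tracing and topological classification of DNA molecules in atomic
force microscopy (AFM) height maps.

High-resolution AFM resolves single DNA molecules on mica as ~2 nm ridges in
a calibrated height grid. For entangled molecules — knots, catenanes,
supercoiled plasmids, replication intermediates — topology is decided at the
crossings: at each one, a duplex passes over or under its neighbour, and the
set of these *crossing orders* distinguishes, say, a 5-node torus knot (5_1)
from a twist knot (5_2) or from unlinked circles. Because AFM records true
height, the over-passing duplex bridges a crossing in a wide "humpback"
profile while the under-passing one shows only a narrow spike; `topotrace`
turns that signal into an explicit topological classification.

The pipeline: flatten the topograph → mask molecules → reduce each to a
single-pixel skeleton with height-biased Zhang–Suen thinning (the surviving
line follows the height crest, not just the mask centre) → detect and merge
crossing nodes (7 nm merge radius) → pair emanating branches by
maximum-weight anti-parallel matching → call the crossing order from the
full width at half maximum (FWHM) of the height profile through each
crossing, with a per-crossing reliability

    COR = (1/N) * sum over FWHM pairs of ( 1 - min(FWHM)/max(FWHM) )

→ order the skeleton into continuous molecule traces, separating entangled
molecules → convert each closed trace to a planar crossing diagram and
classify it via the Kauffman bracket / Jones polynomial
`V = (-A)^(-3w) <D>`, `t = A^-4`, against a verified table of torus and
twist knots and 2-component links in Rolfsen notation → report
morphometrics (contour lengths, replication-fork geometry, deposition
conformation classes) with standard data-cleanup filters. Discrete
Gauss-integral writhe, linking number and ribbon twist calculators are
included, as is a seeded pseudo-AFM generator that renders ground-truthed
synthetic images (tip-convolved, noisy, optionally crossing-compressed) of
every supported topology.

## Worked example

```r
library(topotrace)

# a ground-truthed synthetic 4-node catenane, 561 nm total contour
sp <- synth_spec("catenane_4node", length_nm = 561, seed = 3)
gt <- make_curve(sp)
img <- render_pseudo_afm(gt, sp)$heightmap

res <- run_pipeline(img, pipeline_config())
res$results[, c("rolfsen", "n_molecules", "n_crossings",
                "contour_length_nm", "min_cor")]
#> # A tibble: 1 × 5
#>   rolfsen n_molecules n_crossings contour_length_nm min_cor
#>   <chr>         <int>       <int>             <dbl>   <dbl>
#> 1 4^2_1             2           4              556.   0.255
```

The object is classified `4^2_1` — the 4-node catenane, two circles crossing
four times — after separating the two entangled molecules; the summed
contour length lands within 1 % of the 561 nm ground truth, and the least
reliable crossing scores COR 0.26, right at the 0.263 reporting threshold.
Inverting single crossings of that diagram reclassifies it as a 2-node
catenane (`2^2_1`) and inverting two as unlinked circles (`0^2_1`):

```r
d <- diagram_from_curves3d(gt$curves)
classification_probability(d, p = 0.82)
#> # A tibble: 3 × 3
#>   topology n_assignments probability
#>   <chr>            <int>       <dbl>
#> 1 4^2_1                2       0.453
#> 2 2^2_1                8       0.416
#> 3 0^2_1                6       0.131
```

which is the combinatorial model of misclassification risk at the
benchmarked 82 % per-crossing accuracy.

A command-line wrapper for shell use lives at `inst/cli/topotrace.R`
(subcommands `trace`, `classify`, `synth`, `prob`, `geometry`).

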