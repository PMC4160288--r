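# spinemorph

Rapid, objective dendritic-spine morphometry from serial-section trace
exports.

Dendritic spines — the small protrusions that receive most excitatory
synaptic input — change shape as circuits mature: long, thin filopodia
give way to stable, wide-headed mushroom spines, and aberrant spine
phenotypes accompany many neurological disorders. Classifying spines by
eye from Golgi-Cox stained material is slow and poorly reproducible
between analysts. `spinemorph` implements a geometric alternative: each
spine is reduced to two calibrated measurements — head width `w` (a 2D
line on the section where the head is in focus) and length `l` (a 3D
Z-trace from neck base to tip through 0.5 µm optical sections) — plus the
length-to-width ratio `LWR = l / w`, and is assigned exactly one of six
types by a hierarchical rule evaluated in order (first match wins):

1. **branch** — the analyst flagged a multi-headed spine in the trace name;
2. **filo** — `l > 2` µm (filopodium);
3. **mush** — `w > 0.6` µm (mushroom);
4. **long_thin** — `l > 1` µm;
5. **thin** — `LWR > 1`;
6. **stub** — `LWR ≤ 1` (stubby).

The package reads the two CSV exports a RECONSTRUCT tracing session
produces (the Trace List with head widths, "Export List A", and the
Z-Trace List with 3D lengths, "Export List B"), decodes the trace-name
conventions (`d1_slen`, `d1_zlen`, `d1_spine1`, `d1_spine1branch`,
`d1spineZlen1`, …), pairs widths with lengths, classifies every spine,
and computes per-dendrite summaries — protrusion density (spines per µm
of dendrite contour length), mean width/length/LWR and type fractions —
plus two-group pooled-variance Student's t comparisons. A seeded
synthetic generator emits the same file formats with known ground truth
so the whole pipeline can be validated without tissue.

## Worked example

```r
library(spinemorph)

# simulate a tracing session: 10 dendrites, ~1 protrusion/µm
dir <- tempfile()
res <- run_simulate(dir, seed = 42)

# read the exports back, pair widths with lengths, classify
ds <- run_classify(res$trace_files, res$ztrace_file)
print(ds)
#> <dendrite_set> 10 dendrite(s), 104 spine(s)
#>   total Z-length 105.39 um, overall density 0.987 /um
#>   types: branch=3 filo=12 mush=22 long_thin=13 thin=26 stub=28

s <- summarize_dendrites(ds)
s[1, c("den_id", "n_spines", "protrusion_density_per_um", "mean_lwr")]
#> # A tibble: 1 × 4
#>   den_id n_spines protrusion_density_per_um mean_lwr
#>   <chr>     <int>                     <dbl>    <dbl>
#> 1 1            10                     0.978     1.55
```

The printed density is the spine count divided by the dendrite's 3D
contour (Z-trace) length, the classifier recovered every generated
spine's true type (the generator's sampling regions keep a margin from
each threshold), and `mean_lwr` ≈ 1.6 says the average protrusion on
that segment is about one-and-a-half times longer than its head is
wide — a mixed, mature-leaning segment.

Two groups are compared dendrite-by-dendrite:

```r
sc <- maturation_scenario(seed = 7)      # immature-like vs mature-like
generate_dataset(sc$immature, "groupA"); generate_dataset(sc$mature, "groupB")
run_compare("groupA", "groupB", metric = "protrusion_density_per_um",
            labels = c("immature", "mature"))
#> Two-sample Student's t-test (pooled variance) on protrusion_density_per_um
#>   immature: mean 0.5841 +/- 0.0069 SEM (n = 15 dendrites)
#>   mature: mean 1.016 +/- 0.00705 SEM (n = 15 dendrites)
#>   t = -43.74, df = 28, p = 2.542e-27
```

The same four operations are available from a shell via
`Rscript inst/cli/spinemorph.R <simulate|classify|summarize|compare> …`.

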