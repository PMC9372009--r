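# gcscreen

Suspect screening for GC-EI-HRMS with accurate-mass spectral libraries.

## What problem it solves, and for whom

Gas chromatography coupled to electron-ionization high-resolution mass
spectrometry (GC-EI-HRMS) is the workhorse for screening semi-volatile
organic contaminants — pesticides, personal-care products, plasticizers,
PAHs — in environmental matrices such as biota extracts and passive
samplers. At 70 eV every compound fragments into a reproducible pattern of
accurate-mass ions, but co-eluting compounds superimpose, so identification
requires (1) *deconvoluting* the chromatogram into components, (2) scoring
each component spectrum against an accurate-mass EI library, and (3)
corroborating the match with Kovats retention indices (RI). `gcscreen`
implements that workflow and, just as importantly, the machinery used to
*optimize* it: false-positive/false-negative scoring against spike truth
tables, match-factor cutoff calibration at target false-negative rates,
accurate-mass-tolerance and pure-weight-factor sweeps, and
screening-detection-limit estimation. A synthetic GC-EI-HRMS generator
makes the whole pipeline testable without instrument data.

It is aimed at analytical chemists and computational method developers who
want an open, scriptable counterpart to vendor deconvolution/search tools,
with every knob exposed.

## The core model

**Deconvolution.** Profile spectra are centroided (intensity-weighted mean
per resolved region), centroids are clustered into extracted-ion
chromatograms (full extraction window Δm/z = 0.05 Da), chromatographic
peaks are found by Savitzky–Golay smoothing plus valley-to-valley
trapezoidal integration (absolute area ≥ 10,000 counts), and peaks whose
apexes co-occur within `Δt = factor × scan_period / 100` and whose shapes
correlate at Pearson r ≥ 0.9 are grouped into components (minimum 3 ions).

**Matching.** With ions below m/z 30 removed and library ions paired
one-to-one to the nearest query ion within the accurate mass tolerance
(AMT, 50 ppm default), both search directions use the Stein–Scott weighted
cosine, w = I^0.5 · (m/z)^1.3:

    R = cos over the library's ions          (reverse: query extras ignored)
    F = cos over the union of both ion sets  (forward: extras penalized)

    match factor = 100 · (pwf · F + (1 − pwf) · R)

where the pure weight factor pwf ∈ [0, 1] interpolates from a pure reverse
(0) to a pure forward (1) search. Retention evidence multiplies the score
by a trapezoidal penalty in seconds — free within 20 s, ramping to a
maximum penalty at the search-window edge, rejected beyond it — with the
expected retention time obtained from the entry's Kovats RI through the
batch's own C7–C40 n-alkane calibration (linear van den Dool–Kratz form).
Hits below the minimum match factor (75) are dropped and one best hit is
kept per component.

**Evaluation.** TP/FP/FN against spike truth tables; the largest integer
cutoff keeping the false-negative fraction at a target (e.g. 5%); full
AMT × PWF sweeps computed from cached forward/reverse cosines; and the
screening detection limit (SDL) as the lowest level with ≥ 95% detection
across replicates, holding at all higher levels.

## A worked example

Simulate a noiseless run directly from a simulated 26-compound library and
screen it at the default parameters:

```r
library(gcscreen)

cfg <- sim_config(seed = 1, ppm_sigma = 0, ion_cv = 0, intensity_cv = 0,
                  noise_floor = 0, bleed_intensity = 0)
lib <- simulate_library(26, seed = 1, richness_range = c(4, 20),
                        ri_spacing = "even")
alk <- simulate_alkane_run(c(7, 30), config = cfg)   # C7-C30 calibration run
sim <- simulate_run(lib, levels = 500, calib = alk$calibration, config = cfg)

res <- screen_sample(sim$run, screen_config(lib, calib = alk$calibration))
res$log
#>            scans             eics components_found  components_kept
#>             3625              287               26               26
#>             hits
#>               26
head(as.data.frame(res$identifications)[, c("entry_name", "component_rt",
     "component_ri", "raw_match", "final_score", "matched_ions")], 5)
#>     entry_name component_rt component_ri raw_match final_score matched_ions
#> 1 Compound_001        115.0          950       100         100            7
#> 2 Compound_002        137.8         1026       100         100            8
#> 3 Compound_003        160.6         1102       100         100           13
#> 4 Compound_004        183.4         1178       100         100           19
#> 5 Compound_005        206.2         1254       100         100           19
```

Reading the output: all 26 planted compounds come back as exactly one
component each; `raw_match` is the weighted forward/reverse match factor
(100 = perfect), `final_score` is the same after the retention penalty
(no penalty here — each component elutes at its library RI), and
`component_ri` is the component's own Kovats index from the alkane
calibration. With noise, mass errors and a matrix background switched on
(the `sim_config()` defaults), scores spread downward and matrix features
begin to claim library names — the false-positive/false-negative trade-off
that `run_experiment()` and `sweep_parameters()` quantify.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/gcscreen simulate --seed 1 --n 26 --out-dir demo
Rscript inst/scripts/gcscreen screen --run demo/sample.gcrun \
    --library demo/library.msp --crt demo/alkanes.csv --out ids.csv
```

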