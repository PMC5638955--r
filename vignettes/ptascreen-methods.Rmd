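---
title: "ptascreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptascreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ptascreen` implements the two computational stages of a synthetic
incompatibility screen: estimating colony growth rates from scanner
time-lapses of petri dishes, and quantifying SNP-free conserved regions
(CRs) in promoter windows as candidate programmable-transcriptional-
activator (PTA) target space. This vignette records the underlying
models, the parameters that matter, and the design decisions taken where
the procedure left choices open.

## 1. Plate imaging pipeline

### Model and assumptions

A plate time-lapse is an ordered stack of RGB frames at strictly
increasing times, the first of which is acquired before any colony is
visible. Colonies are assumed brighter than the agar in the HSV value
channel (V = max(R, G, B)); scans where colonies are darker are handled
by the `invert` flag. The pipeline assumes a static camera (no
registration is performed) and a temporally stable background, so the
first frame is a valid background estimate for the whole series.

The stages, in order:

1. **Value channel.** Per pixel, V = max(R, G, B), rescaled to [0, 1]
   from 8- or 16-bit integer coding when necessary.
2. **Background subtraction.** `frame - frame0`, clipped to [0, 1].
3. **Smoothing.** Two passes of a truncated, renormalised Gaussian
   (sd 1 px, 7 px support). The kernel factors exactly into its 1-D
   profile, so each pass is implemented as two clamped (replicate-
   boundary) 1-D convolutions; the unit test checks the impulse response
   against the 2-D kernel and the two-pass response against the kernel's
   self-convolution.
4. **Thresholding.** One scalar threshold for all frames, for
   consistency across the series. `"auto"` takes Otsu's threshold on the
   *final* smoothed frame, which has the best-separated bimodal
   histogram of the series. The automatic value is accepted only if it
   separates two classes whose means differ by at least 0.1 V units;
   otherwise (e.g. a colony-free series, where Otsu would split noise) a
   warning is raised and the configured fallback (default 0.25) is used.
5. **Seed detection.** The z-projection is the per-pixel *sum* of the
   binary masks over time (a maximum projection of binary masks is
   uninformative); it is smoothed once with the preprocessing kernel.
   Seeds are prominent regional peaks: watershed-based object detection
   with tolerance `min_peak_prominence` (default 2 frames of coverage)
   and neighbourhood `min_seed_separation_px` (default 10 px, roughly a
   small colony diameter at first detection). Plain regional maxima are
   not usable here: a colony that saturates early leaves wide flat
   annular steps in the projection whose interiors are all local maxima;
   prominence merges these shoulders into the dominant peak while
   keeping genuinely distinct colonies (whose peaks are separated by a
   deep ridge, since each colony was small once) apart. Seeds are
   retained only on the final frame's foreground; ties and plateaus
   collapse to the plateau centroid.
6. **Splitting merged colonies.** Per frame, each connected foreground
   component containing one seed is that seed's region; components with
   two or more seeds are partitioned by seeded propagation on the
   (negated) Euclidean distance transform restricted to the component's
   bounding box, which for overlapping disks splits along the
   perpendicular bisector. Every foreground pixel receives exactly one
   label (partition conservation is asserted exactly in the tests).
   Components containing no seed stay background — they cannot be
   attributed to any colony.
7. **Tracking.** The same global seed set labels every frame; a
   colony's area at a frame is its label's pixel count, zero before it
   appears. Relabelling every frame from global seeds keeps identities
   stable by construction, at the cost of assuming colonies do not move.
8. **Exclusions.** On the final frame: `edge` if any pixel of the
   colony's region lies within `edge_margin_px` (default 5 px) of the
   image border; `merged_with_edge` if the colony shares a connected
   component with an edge colony; `ambiguous_merge` if its component
   contains more than `max_seeds_per_component` (default 5) seeds. The
   ambiguity rule is a stand-in for a qualitative criterion ("an
   ambiguous number of peaks in a large merged region") that has no
   published quantitative form; the cap is configurable. The border
   margin treats the image edge as the plate edge, which is exact for
   the rectangular synthetic fixtures; a circular plate mask can be
   supplied for real scans by pre-masking the frames.

### Growth-rate estimator

Areas are natural-log-transformed (rates are e-folds per hour; a
different log base only rescales) and an OLS line is fitted in a 12-h
moving window anchored at every observed frame time whose full window
fits inside the observed range; the maximum slope over windows is the
colony's rate, ties going to the earliest window. Zero areas are
dropped within windows rather than pseudo-counted (any additive offset
would bias the log slope); windows retaining fewer than `min_points`
(default 3) frames are skipped. A track with no valid window returns an
explicit `no_estimate` status — distinct from an estimated slope of
zero, which is a biological no-growth readout. Restricting to full
windows is deliberate: truncated tail windows of three noisy points
would inflate the maximum-slope statistic for flat colonies.

For plate-reader curves, the rate is the OLS slope of
ln(OD - background) between 210 and 330 minutes (readings every
10 min), with the well's first reading as the default background and a
blank-derived value as an alternative; non-positive background-
subtracted readings are dropped and fewer than three remaining points
is an error. Group comparisons use `stats::aov` followed by
`stats::TukeyHSD`; the worked two-group example (0.9/1.0/1.1 vs
1.9/2.0/2.1, F = 150) is checked against definitional sums of squares.

## 2. Promoter conserved-region analysis

For each annotated gene the promoter window is the `window_bp`
(default 1000) bases immediately upstream of the annotated gene start:
`[start - 1000, start - 1]` on the plus strand, `[end + 1, end + 1000]`
on the minus strand, truncated at chromosome ends; windows are anchored
at the *annotated gene start*, not a predicted TSS (TSS prediction is
out of scope; the site-enumeration subcommand defaults to a 400-bp
window instead, the scale used when designing guides against predicted
start sites). Windows overlapping neighbouring genes are not trimmed —
no such rule is part of the procedure — and zero-length windows (gene
at the chromosome edge) are warned about and skipped.

CRs are the maximal runs of window positions carrying no segregating
variant, computed by interval arithmetic over the sorted variant
positions; a variant-free window yields one full-length CR, adjacent
variants yield no zero-length CR, and variants at the window boundary
count as inside. Only single-nucleotide records are used; multi-allelic
SNVs count as one disqualified position and indels are excluded with a
reported count. Every simulated genome carries truth CRs computed by an
independent per-base scan, and the tests assert exact equivalence of
the two routes, exact length conservation
(sum of CR lengths + in-window variants = window length), strand
symmetry under genome reverse-complementation, and the closed-form
expectation for run counts (below).

A CR is *targetable* when strictly longer than 30 bp (length >= 31; the
threshold is configurable). The mean targetable count per promoter
divides by all analysed promoters, including those with zero CRs. CR
positions are summarised as the signed offset of the CR midpoint from
the gene start (0 at the start, negative upstream; even-length
midpoints round toward the gene); the offset histogram uses 50-bp bins
over [-1000, 0] and covers targetable CRs only, while the size
histogram covers all CRs. The midpoint anchor is a choice — the
position summary could equally anchor at CR ends — and is recorded in
the output metadata.

PAM sites are 20-nt protospacers immediately 5' of an NGG on either
strand. The scan extends the window by 3 bp of genomic context on each
side so a PAM may straddle the window edge, but the protospacer itself
must lie inside the window. `inside_cr` requires containment in a
single targetable CR; `unique_in_genome` is an exact-match count
(forward plus reverse-complement) equal to one — no mismatch-tolerant
off-target scoring is attempted, matching a plain "unique sequence"
requirement. Sites touching non-ACGT symbols are skipped with a
warning.

## 3. Synthetic data: what it emulates, and what it does not

**Plates.** Colonies are disks with capped exponential area,
A(t) = min(A0 e^(r (t - lag)), Amax) for t >= lag, rendered at a
constant value level on a constant background with i.i.d. Gaussian
pixel noise, and emitted as RGB with equal channels so the V-channel
conversion is exercised but analytically predictable. Area-driven
rendering (radius derived from area) was chosen over a radial-velocity
model so the ground-truth log-area slope *is* the specified rate — the
estimand of the pipeline. A pixel belongs to a disk if its centre lies
within it, so rasterised areas differ from analytic areas by at most
the perimeter. The model deliberately omits colony morphology, optics
(vignetting, illumination drift), subpixel edges and plate texture:
passing tests demonstrate the pipeline's correctness on its own model,
not robustness to every real-scanner artefact. Colony appearance lags
are a free parameter (uniform 2-10 h in the benchmarks) since no lag
distribution is part of the protocol.

**Benchmark conditions** (`random_plate_spec` / `growth_rate_recovery`
defaults): 2-h frames for 256 h; initial area 100 px (about a 1-mm
colony at typical flatbed resolution); saturation 20,000 px; background
0.2 and colony 0.7 V units with noise sd 0.05 (SNR 10); colonies on a
jittered grid spaced so fully grown disks neither merge nor touch the
border; rates uniform on [0.1, 0.6]/h, plus dedicated zero-rate
colonies for the no-growth readout. The recovery benchmark runs 100
growing and 8 no-growth colonies in 27 plates of 4 and asserts a median
relative rate error of at most 5%, every no-growth estimate at most
0.02/h, and strict separation between the two groups.

**OD curves.** Logistic wells,
OD(t) = K / (1 + ((K - O0)/O0) e^(-r t)) + b + noise. Benchmark
defaults: O0 = 0.003 (dilute inoculum), K = 2, rates 0.006-0.009/min
(doubling times of roughly 75-115 min), background 0.08, read noise
sd 1e-4 (kinetic-mode reader repeatability). These keep the well below
3% of capacity at 330 min, so the 210-330 min fit interval genuinely
sits in the semilog-linear phase the estimator assumes; the benchmark
asserts recovery within 5% per well.

**Genomes.** Uniform-random ACGT sequence; genes placed uniformly
without overlap (bounded retries, explicit failure) on random strands;
each base is a SNP independently with probability p (ALT uniform over
the three non-reference bases). The Bernoulli placement gives the
closed form used as an analytic oracle: the expected number of maximal
SNP-free runs of length >= L in a window of W bases is

E[N_L] = (1 - p)^L (1 + (W - L) p),

checked against 10,000 simulated windows (W = 1000, L = 31, p = 0.02)
within three standard errors. No linkage structure, indels or
structural variants are simulated, and SNP density is uniform — real
promoter SNP panels are clustered and ascertainment-biased, so
population-scale conclusions require real VCFs via `find-crs`.

## 4. Numerical and interface choices

- All genomic coordinates are 1-based closed in memory and in CSV
  reports; BED exports are 0-based half-open.
- Determinism: every stochastic function takes an integer seed and
  restores the RNG state (`withr::with_seed`); identical spec + seed
  give bit-identical outputs, which the CLI extends to byte-identical
  files (provenance headers hash analysis parameters, not paths).
- Degenerate inputs are explicit: empty plates yield empty seed lists
  (not errors), flat OD curves and all-constant ANOVA groups are
  errors, zero-length promoter windows are warned and skipped,
  placement failure after bounded retries is an error.
- The problem sizes in the test-suite and acceptance script (1,000
  oracle windows, 10,000 run-count windows, 108 benchmark colonies,
  12 OD wells) were chosen as the smallest sizes at which the asserted
  statistical bounds are stable across seeds.

## 5. Known limitations

- Colonies are assumed stationary and the background static; there is
  no registration, illumination correction or plate-circle fitting.
- The ambiguous-merge rule is a configurable seed-count cap standing in
  for a qualitative criterion.
- Protospacer uniqueness is exact-match only; near-matches that a
  mismatch-tolerant activator might still bind are not scored.
- Promoter windows anchor at annotated gene starts; results on real
  annotations are annotation-release sensitive.
- CR statistics treat any segregating SNP as disqualifying, with no
  allele-frequency weighting — by design, since the target must be
  absolutely conserved across the panel for the incompatibility barrier
  to be escape-proof.
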