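---
title: "Quantifying scar remodelling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scar remodelling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`scarmorph` turns multi-channel histology of human scars and the
accompanying expression data into a reproducible set of numbers. This
vignette is the package's account of the science behind each measurement:
the model or procedure, its assumptions, the tunable parameters and their
defaults, the numerical choices, and what validation on synthetic
sections does and does not establish about real data.

## Coordinate and angle conventions

Images are numeric matrices indexed `[row, col]` with row 1 at the
epidermal surface and depth increasing downwards; the pixel at
`[r, c]` has its centre at `((c - 0.5) p, (r - 0.5) p)` µm for pixel
size `p`. Orientation angles live in `[0°, 180°)` and are measured from
the x axis, so 0° means "parallel to the epidermis". All physical
quantities are micrometres, cells/mm², or dimensionless fractions.

## The synthetic section and what it emulates

`generate_section_image()` renders a layered skin section with complete
ground truth. From top to bottom: a 20 µm mounting margin; the viable
epidermis (DAPI nuclei as non-overlapping disks, a controllable fraction
rendered Ki67-positive); a sinusoidal epidermal–dermal junction
`y(x) = top + T + A sin(2πx/L)` carrying a collagen-IV basement membrane
with a Gaussian cross-profile; and the dermis (DAPI nuclei, COLIV vessel
rings, and an SHG collagen-fibre field confined to a rectangle below the
deepest EDJ excursion).

Key parameter defaults and why:

* `pixel_size_um = 0.5`. Confocal acquisition settings differ between
  rigs; 0.5 µm/px resolves the thinnest default fibre (6 µm = 12 px)
  comfortably and is recorded in the image metadata. Everything accepts
  other pixel sizes.
* `epidermal_thickness_um = 60`, `edj_amplitude_um = 15`,
  `edj_period_um = 100`: representative of scalp skin with moderate rete
  ridges; a mature scar is emulated by lowering the amplitude.
* `nuclei_density_per_mm2 = 800`: between a mature scar and the
  ~1000 cells/mm² of healthy scalp dermis.
* `fibre_widths_um = c(6, 14)`: one class on each side of the 10 µm
  thin/thick boundary. `fibre_area_fraction = 0.25` is the packing the
  non-overlapping stroke model reaches reliably (see Limitations).
* `shg_fibre_intensity = 150`, `shg_background_intensity = 50`: a 3:1
  normalized SHG ratio, typical of well-tuned SHG acquisition.
* Intensities are noiseless by default so analytic examples stay exact;
  Gaussian noise is opt-in through `noise_sd`.

The EDJ is a sinusoid rather than a free-form curve because its
arc–chord ratio is then computable by dense numeric integration at
generation time, giving an independent truth value; free-form boundaries
are still accepted everywhere via `boundary_curve()` CSV input.

Nuclei are placed by dart-throwing with a minimum separation of one
nucleus diameter plus 1 µm, so counts are unambiguous and detection can
be validated exactly. The fibre field draws constant-width capsule
strokes with a 1.5-pixel clearance; the clearance exceeds √2 pixels, so
two strokes can never become 8-connected and every connected component
of the rendered field is a single fibre. That makes the per-class
painted-area bookkeeping exact, at the price that the achievable area
fraction saturates near 0.25–0.30 (rejection packing); overlap can be
re-enabled with `allow_overlap = TRUE` for stress tests. Orientation
follows an axial von Mises model: the doubled angle 2θ is von
Mises-distributed with concentration κ, which ties the generator
directly to the closed-form mean resultant length I₁(κ)/I₀(κ) used in
validation.

Because the stroke class is drawn once per fibre (not once per placement
attempt) the width-class mix is not biased by the higher rejection rate
of large strokes; with area-type weights a greedy largest-deficit rule
is used instead, which pins realized class areas to their targets up to
the granularity of one stroke (~0.03 in the thick proportion on a
300 × 300 µm field).

## Fibre segmentation and the thin/thick rule

`segment_fibres()` reconstructs the three-class fibre classification as
a deterministic pipeline: intensity threshold (Otsu within the analysed
ROI by default, fixed value optionally) → Zhang–Suen skeletonization →
per-fibre width = mean of twice the Euclidean distance transform sampled
along the skeleton ("average width along its length") → thin if
≤ 10 µm, thick if > 10 µm, with every foreground pixel inheriting the
class of its nearest skeleton segment (multi-source BFS). Skeleton
junction pixels (more than two skeleton neighbours) split the skeleton
into per-fibre segments before averaging; spur branches shorter than
5 µm are pruned first because Zhang–Suen thinning grows short spurs at
stroke ends and crossings, and an unpruned spur can carry a whole
segment across the class boundary.

Numerical notes. The distance transform measures to background pixel
*centres*, so on diagonal fibres the width estimate can exceed the
nominal width by up to ~0.7 px; at 0.5 µm/px this is well under the 4 µm
separation between the default classes, but a fibre genuinely at the
10 µm boundary is only classified reliably when it is resolved by ≥ 2 px
per micron or rendered axis-aligned. `local_thickness_map()` implements
the largest-inscribed-disk definition directly (each foreground pixel
paints a disk of its distance-transform radius; the map is the pixelwise
maximum diameter) and is validated against an exhaustive per-pixel
search.

Segmentation should be run on the dermal ROI, not the whole section:
the epidermis carries no SHG signal, and a large zero-intensity region
can capture Otsu's threshold on its side of the histogram.

## Orientation and the alignment coefficient

The orientation field comes from the structure tensor: the image is
pre-smoothed (default σ = 1.5 µm) before central-difference gradients —
without pre-smoothing, the stair-step edges of rasterized fibres bias
angles by several degrees — and the tensor components are integrated at
a 6 µm Gaussian scale, roughly the fibre half-width, so the dominant
eigenvector is stable across the fibre cross-section. The fibre angle is
the direction perpendicular to the dominant gradient; coherence is the
normalized eigenvalue anisotropy.

The alignment coefficient is the circular-statistics mean resultant
length of doubled angles, `R = |Σ w e^{2iθ}|/Σ w`, with one vote per
fibre pixel (coherence weighting is available as an option). Doubling
handles the 180° ambiguity of undirected fibres. R is exactly 1 for
identical angles, 0 for balanced orthogonal pairs, and I₁(κ)/I₀(κ) in
expectation under the axial von Mises model — the three anchors the test
suite checks. On rendered fields with zero angular spread the measured
coefficient lands near 0.99 rather than 1.0: stroke end-caps and edge
pixels contribute slightly off-axis estimates. This is a property of
estimating orientation from pixels, not of the coefficient.

## Epidermis and EDJ measurements

*Thickness*: vertical rays at 10 positions 150 µm apart (both
configurable), centred in the common lateral span of the two boundaries;
probing normal to the EDJ exists as an option but is off by default,
consistent with reading the thickness as "top to bottom" distance.

*Arc–chord ratio*: the boundary is cut into consecutive sections of
equal arc length (default 100 µm — shorter than an ROI, long against
pixel noise; the trailing remainder is discarded) and each section's arc
length is divided by its chord. The per-section mean is reported, and the
whole-boundary ratio is emitted alongside since either reading of a
single summary number is defensible. The ratio is dimensionless and
invariant under rigid motions and uniform scaling, which the suite
verifies, and increases monotonically with sinusoid amplitude.

*Ki67 fraction*: a nucleus is positive when its mean Ki67 intensity over
a 2 µm disk exceeds a threshold (Otsu over the per-nucleus means by
default). Fractions are reported per 250 µm lateral window and pooled;
a window with no nuclei is missing, never zero.

*Basement membrane*: COLIV is sampled along 25 µm trajectories normal to
the EDJ at pixel resolution. The profile baseline is the mean of the
outer 20% of samples at each end; the peak is the baseline-subtracted
maximum; the width is the full width at half maximum with linear
interpolation between samples. FWHM is one concrete reading of "profile
width" — on a Gaussian membrane it equals 2.355σ, which is what the
tests pin. On a strongly undulating EDJ the rendered-band width reads
up to ~5% high because the band distance is computed against the
rasterized curve; flat-EDJ fixtures are used wherever 2% accuracy is
asserted.

## Dermis measurements

Cell density is a count of detected nucleus centres in a 300 × 300 µm
ROI divided by the ROI area in mm². Nucleus detection is Gaussian
smoothing + thresholding + connected components with an
equivalent-diameter gate — deterministic and exact on the
non-overlapping disks the generator draws, which is why the generator
places them that way; heavily overlapping nuclei in real tissue will be
under-counted and are outside what the tests establish. Vessel density
is the percentage of a dermal ROI covered by the thresholded COLIV mask
(threshold recorded in the output). Normalized SHG intensity divides the
mean over fibre pixels by the mean over background pixels so fibre
density does not confound the intensity readout.

## Transcriptomics

The expression stage consumes a genes × samples log2 matrix (plain TSV
or a GEO series-matrix block; array preprocessing such as RMA is
upstream of this package). `baseline_transform()` subtracts each gene's
median across samples (idempotent). The DE filter runs a per-gene
one-way ANOVA across the four timepoints with Benjamini–Hochberg FDR
over all genes, and gates on |FC| > 1.5, P < 0.01 and FDR < 0.01; the
reported fold change is the largest-magnitude linear fold change of any
post-transplant timepoint mean against the 0-month mean, with the sign
convention positive = up. Zero within-group variance gets the degenerate
rule (p = 0 if means differ, else 1) and is logged. Pairwise comparisons
use Welch's t-test on log2 values with the same gates; the FDR gate can
be disabled (`use_fdr = FALSE`) because published gene counts from
console software do not always state whether pairwise lists were
FDR-gated, and both configurations should be reproducible. The
unique/core partition is plain set algebra over the three pairwise sets;
direction consistency across timepoints is an optional stricter reading
and is off by default. Clustering uses 1 − Pearson distance with average
linkage, recorded in the result. ΔΔCt relative quantification follows
`RQ = 2^(−ΔΔCt)` against a reference gene with the pre-treatment
condition fixed at RQ = 1.

At zero noise the filter has sensitivity and specificity exactly 1 for
planted effects above the FC gate — a sanity anchor, not a power claim.
At realistic small n (3 samples per timepoint) the FDR gate costs
sensitivity; the pipeline tests assert majority recovery and zero null
contamination rather than perfection, because that is what the
statistics deliver at that design size.

## The statistical decision tree

`select_and_run_test()` reproduces the assumption-driven test selection:
D'Agostino–Pearson normality per group at α = 0.05, then variance
homogeneity (F test for two groups, Bartlett above that), then Student's
t / one-way ANOVA + Tukey / two-way ANOVA + Tukey on the parametric
branch or Mann–Whitney / Kruskal–Wallis + Dunn (Bonferroni-adjusted) on
the nonparametric branch. The full decision trace (per-group normality
p-values, variance test, chosen branch) is recorded on every result, and
the whole tree is a pure function of its input. The D'Agostino–Pearson
K² statistic is implemented from the standard skewness and kurtosis
transforms and matches the reference implementation to 10 decimals; its
kurtosis component is undefined below n = 8, so groups of 3–7
observations fall back to Shapiro–Wilk, noted in the trace. The two-way
design models timepoint + subject, matching a few-subjects,
four-timepoints study with ROI replicates; the factor choice is recorded
in provenance. Grubbs' outlier test (two-sided, α = 0.05, at most one
flag per call) is applied once per metric × timepoint group before
testing.

Calibration is checked by simulation: the type-I error of the *selected*
pipeline on four null normal groups stays within [0.03, 0.07] at
α = 0.05 over 1000 replicates, and the Grubbs false-flag rate sits near
0.05 over 2000 replicates.

## The pipeline and problem sizes

`run_pipeline()` chains simulate → morphometry → statistics →
transcriptomics over subjects × timepoints × ROI replicates, applies
per-timepoint effect multipliers to selected section parameters (e.g.
a 1.6× epidermal thickening from 2 months on), adds lognormal
between-section biological variability (`section_cv = 0.08` — without
it, replicate sections would be geometrically identical and
within-group variances degenerate), and writes tidy CSVs, per-metric
decision-tree results, metric-versus-timepoint figures with grand-mean
lines, and a provenance JSON. Reruns with the same configuration and
seed are byte-identical.

The shipped configurations use compact sections (hundreds of µm at
1 µm/px) and ~10³-gene matrices: large enough that every estimator
operates in its intended regime, small enough that the entire validation
suite regenerates its data from scratch in about a minute. The same code
paths handle full-size 600 × 450 µm ROIs at 0.5 µm/px unchanged.

## Known limitations

* The stroke-packing model cannot reach the fibre densities of dense
  scar tissue (realized fractions saturate near 0.3); recovery of
  *fractions* is validated, extrapolation to near-confluent collagen is
  not.
* Fibres are straight, constant-width and non-overlapping by default;
  junction splitting is exercised by the skeleton logic but true
  interwoven networks are not emulated.
* Nucleus detection assumes separable nuclei; clumped nuclei in real
  sections need a different detector.
* Orientation estimates inherit a ≤ 1° rasterization bias and the
  alignment coefficient of a perfectly aligned rendered field reads
  ~0.99, not 1.0.
* The expression generator plants mean shifts with homoscedastic
  Gaussian noise; array-specific mean–variance structure is not
  emulated, so FDR behaviour on real arrays may differ from the null
  simulations.
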