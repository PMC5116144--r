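---
title: "From line scans to elemental maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From line scans to elemental maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemaps)
```

## The measurement and its geometry

LA–ICP–MS imaging rasterizes a sample with parallel laser passes. Each pass
("line") produces one time series of ion intensities per monitored isotope.
Because the laser moves at a constant `ablation_speed` (µm/s) and the
spectrometer delivers one reading every `acquisition_time` (s), time maps
linearly onto position: consecutive readings are
`ablation_speed * acquisition_time` µm apart along the scan. Across lines,
the pitch is the centre-to-centre `space_interval` (µm) chosen when
programming the stage. These two products are the pixel size of every map
this package builds — nothing else about the image geometry is estimated
from the data.

`acquisition_time` is itself determined by the spectrometer configuration:
`dwell × sweeps × n_isotopes × replicates` (`estimate_acquisition_time()`).
Times above 1.0 s smear each reading over more than the laser spot travels,
losing spatial information, so the package warns (but does not refuse) when
it sees one.

Two conventions had to be fixed where the physics does not dictate them:

* **Cell coordinates are start offsets from 0**, not cell centres. The
  spacing definitions involve distances between readings and between line
  centres; the absolute origin is arbitrary, and a 0-based corner origin
  makes axes easy to reason about.
* **Orientation** is read from the stage positions: lines with one constant
  X coordinate and varying Y are vertical, the converse horizontal, with an
  absolute tolerance of 0.001 µm (stage readouts are reported far above
  nanometre precision, so any genuine scan axis exceeds this by orders of
  magnitude). Lines extending along both axes are rejected rather than
  projected. Without a positions file the scan is assumed horizontal and
  positions are generated from the parameters.

## Assembly decisions

The matrix layout is "image orientation": rows follow the y axis, columns
the x axis, so a vertical scan yields the transpose of the same data
assembled horizontally. Several situations the file format allows but does
not define are handled as follows:

* **Row order.** With positions, rows sort by cross-axis start coordinate
  (ties broken by acquisition order); without, by the order number embedded
  in each file name. The *last* digit run of the base name is used so
  prefixes like `sample7_line 3.xl` order by 3, not 7.
* **Serpentine scans.** A record whose end coordinate precedes its start
  along the scan axis is taken to have been ablated in reverse, and its
  samples are flipped before assembly.
* **Ragged lines.** Acquisitions occasionally cut a line short. The default
  policy truncates all lines to the shortest length with a warning naming
  the longer files; `ragged = "error"` refuses instead. Truncation is the
  default because it never invents data, only discards the unmatched tail.
* **Negative intensities** are detector artifacts; they are clamped to 0
  with a warning so maps stay renderable and ratios stay non-negative.

## Normalization

Each analyte matrix is divided cell-wise by the internal standard's matrix.
The standard is assumed approximately uniform in the sample (matrix carbon
in tissue is the usual choice), so the ratio cancels ablation-yield
variation from thickness and coupling differences. Cells where the standard
intensity is exactly 0 have an undefined ratio: they become missing, are
counted in a message, render as the colour-map minimum and export as empty
CSV fields. Normalization always happens on the acquired grid, *before*
any interpolation — interpolation is a display operation and must not feed
back into the data it displays.

## Interpolation

Display upsampling uses bilinear interpolation on the uniform grid
(`pracma::interp2`). The levels none/low/medium/high map to per-axis
densification factors 1/2/4/8; the output grid has `(n − 1) × factor + 1`
nodes per axis, so every original node lies on the refined grid. Powers of
two give visibly distinct refinements at modest cost; the factors are a
documented package default, not a claim about any other tool's internals.

Numerical guarantees, enforced explicitly against ulp-level floating-point
rounding in the interpolator: original nodes keep their exact values and
coordinates, and outputs are clamped to the input's min/max (bilinear
values are convex combinations of the four surrounding nodes, so this
clamping can only remove rounding noise). On analytically bilinear fields
`a + bx + cy + dxy` the interpolator agrees with the closed form to well
below 1e-10 relative error (verified in the test suite). Maps with a single
row or column fall back to 1D linear interpolation along the valid axis,
with a warning. Missing cells are filled with 0 — the natural background —
for interpolation and restored as missing for CSV export.

## Colour mapping and rendering

Values map affinely onto a palette over a range that is either the
displayed map's own min/max (`"data"`) or a user-fixed `[v_min, v_max]`
(`"custom"`); out-of-range values clip to the end colours. A fixed custom
range is what makes maps of different elements directly comparable. A
constant map in data mode has a degenerate range; it is widened to
`[v, v + 1]` so the affine map is defined, rendering the constant as the
palette minimum. The default palette is `hcl.colors`' "viridis", a
perceptually ordered multi-hue gradient; any palette name the function
accepts can be used.

2D renders draw the matrix as a raster with µm axes; when all decorations
are disabled the PNG is written directly from the colour array, so each
cell maps to an equal pixel block of the requested image size. 3D renders
draw a static surface whose height is the normalized intensity — it
reflects signal only, not sample topology — at a configurable azimuth and
elevation (defaults 45°/30°). Rotation is restricted to 90° steps, which
are exact on a raster. Panel placement uses device fractions rather than
fixed margins so even very small pixel sizes render without error.

## File formats

Line files are delimited text; the delimiter is auto-detected among tab,
comma and semicolon by majority vote on the header row, and banner lines
before the header are skipped. This covers the instrument-exported text
variants without committing to any vendor's binary format. `parameters.conf`
is key–value text (`standard`, `ablation.speed`, `acquisition.time`,
`space.interval`, case- and separator-insensitive); `positions.txt` is
whitespace-delimited `name x_start y_start x_end y_end` with an optional
header.

CSV export offers an Excel dialect (comma fields, `.` decimals, CRLF), a
LibreOffice dialect (same with LF) and custom separators; values are
written with 17 significant digits by default, which round-trips doubles
exactly. Session archives (`.lai`) are POSIX tar containers — written with
R's built-in tar implementation, so no external tool is needed — holding
one full-precision CSV per isotope plus a versioned JSON metadata document
(parameters, axes, normalization state, render settings). Loading checks
the format version and refuses unknown ones by name.

## The synthetic generator

`phantom_spec()`/`make_phantom()`/`write_dataset()` produce complete
datasets from known ground truth so the whole pipeline is testable without
instrument data. The default fixture mirrors a seed-scale scan campaign:
23 lines, isotopes C12/Cu63/P31 with C12 as standard, 10 µm/s, 0.270 s,
15 µm spacing. 120 points per line were chosen to give a field of view
(~321 × 330 µm) proportioned like a small seed section. Spatial generators
(constant, gradient, Gaussian blob, disc) are evaluated on unit
coordinates; the standard's default is a bright 900–1100 cps gradient —
strictly positive, as normalization requires — and analytes get localized
features. Optional Gaussian noise (SD in counts, clamped at 0) emulates
counting noise.

What the phantom does *not* emulate: ablation-plasma physics, washout
tails between readings, isotopic interferences, drift, or correlated
noise. Passing round-trip tests therefore demonstrates that the software
chain (write → parse → assemble → normalize) is lossless and geometrically
correct, not that any instrument artifact is corrected.

## Problem sizes and determinism

The test suite runs entirely on generated fixtures: round-trip properties
use 20 random shapes between 2×2 and 8×9 in both orientations, and the
reference fixture is the full 23×120 grid — sizes chosen so the whole
suite completes in seconds while still exercising every code path. All
randomness is seeded; `scripts/acceptance.R` threads its `--seed` argument
through every stochastic step and recomputes each reported quantity from
scratch at run time.

## Known limitations

* No quantitative calibration (counts → concentration), drift correction,
  or multi-sample registration.
* Binary vendor formats are out of scope; the documented text dialect is
  the supported input.
* Interpolation factors and the palette are package defaults: images are
  not bit-compatible with other tools' renderings of the same data.
* The session format is this package's own; it does not read archives
  written by other software.
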