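---
title: "Methods: survey geometry, reflectance calibration and index computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey geometry, reflectance calibration and index computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrisurvey)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical conventions it commits to, and the choices that
were genuinely open.

## Geodesy: a sphere, two conversion modes

All distances are great-circle distances on a sphere of radius
R = 6,371,000 m (the mean earth radius; configurable through
`earth_model()`). Survey fields are hundreds of meters across, where the
difference to full ellipsoidal geodesy is far below a pixel, so WGS-84
Vincenty-style computations are deliberately out of scope.

Metric offsets convert to angular increments linearly:
dlat = (180 / πR) · dy. For longitude there are two modes:

* `"literal"` applies the same factor to dx. This is exact only on the
  equator; at latitude φ it compresses east–west spacing by cos φ
  (about 23% at 40°).
* `"corrected"` (the default) divides the longitude increment by cos φ of
  the reference point, so a 100 m eastward offset stays 100 m on the
  ground at any survey latitude. It is refused within 0.1° of the poles,
  where the conversion degenerates.

Both modes are linear in the offset, which is why accumulating many small
steps equals one large step, and why the tessellation can work in a single
local plane anchored at the polygon bounding box's bottom-left corner. The
small-offset approximation holds to better than 0.1% for offsets up to
about 1 km below 60° latitude (property-tested); inputs are expected to
stay well under 50 km.

## Camera model and the GSD identity

The camera is a nadir pinhole: focal length F_l (mm), pixel pitch P_s
(mm/px), resolution n_x × n_y. Configurations may instead give sensor
width/height in mm, from which the pitch is derived (non-square pixels are
rejected). Flight altitude for a target ground sampling distance is
H_f = GSD · F_l / P_s. Treating P_s as a *pitch* (mm per pixel) is the only
dimensionally consistent reading — it makes the footprint at H_f equal
GSD × pixel counts exactly, an identity the suite checks to double
precision for random cameras. Lens distortion, gimbal tilt and
rolling-shutter effects are not modeled.

Overlap is expressed as step fractions O_x, O_y in (0, 1]: the grid step is
footprint × O, so O = 1 means adjacent tiles touch and the familiar "80%
overlap" corresponds to O = 0.2. The CLI logs the image-overlap reading
(1 − O) alongside to avoid confusion.

## Tessellation and the boundary convention

The tile grid anchors the *first tile's lower-left corner* at the reference
point, which makes an axis-aligned w × h rectangle with an a × b footprint
tessellate into exactly ⌈w/a⌉ × ⌈h/b⌉ interior tiles (the reference
100 m × 120 m / 20 m × 12 m case gives 5 × 10 = 50).

Point-in-polygon is ray casting with *half-open* edges (lower-inclusive):
points on the bottom/left boundary are inside, top/right outside. This
makes every boundary point's classification deterministic, lets the tile
inclusion rule (`keep center or any of the 4 corners`) work without an
epsilon, and guarantees two adjacent tiles never both claim a shared edge
point. Polygon vertices are snapped to the micrometer in the local plane
before testing: the degrees→meters round trip carries ~1e-8 m of floating
noise that would otherwise flip the half-open rule on exact-boundary
fixtures. A degenerate (zero-area) ring and self-intersecting rings are
rejected up front.

Tiles are ordered in a boustrophedon zigzag: columns left to right, odd
visited columns bottom→top, alternating. On full rectangular grids,
consecutive tiles then differ in exactly one grid coordinate. On ragged
(concave-polygon) grids a column transition can also change the row — no
ordering can avoid that without inserting transit waypoints — so the
guaranteed invariants are: column index non-decreasing and row index
monotone within each column. The grid is axis-aligned to local east/north;
rotating the sweep to the polygon's principal axis is a known optimization
and a non-goal here.

Waypoint headings are the bearing of the incoming leg (0° for the first
waypoint); altitude and per-waypoint wait time are constant across the
mission.

## Go-home sub-routes

Battery budgeting uses a distance proxy: `d_max` defaults to endurance ×
cruise speed (20 min × 5 m/s = 6 km, both configurable). Scanning waypoints
in order, the risk at w_i is d(w_i, w_{i+1}) + d(w_{i+1}, home) — reach the
next waypoint, keep enough to return home in a straight line. When it
exceeds `d_max` a go-home waypoint (located at home) is inserted and the
next leg is flown from home. Any waypoint with 2·d(home, w) > d_max is
unreachable under this scheme and raises an error naming it.

Two consequences are worth spelling out. First, the rule is *myopic*, not
cumulative: it bounds each leg-plus-return, not total distance flown since
the last charge; as a result it only ever triggers on legs longer than
d_max − d(home, next) ≥ d_max/2, i.e. on routes with long jumps (scattered
parcels around a central launch point), never on a compact grid whose
every waypoint is reachable. Second, distances are 2-D ground distances;
the altitude component (tens of meters against a multi-km budget) is
ignored. Both choices follow the splitting procedure's definition; the
post-condition the tests enforce is exactly "every flown survey leg
satisfies leg + return ≤ d_max", verified against an independent
linear-scan oracle using a second haversine implementation.

## Mission formats

The JSON dialect is a versioned object `{schema, home, metadata,
waypoints}`; waypoints are records `{lat, lon, alt_m, wait_s, heading_deg,
kind}`. A bare waypoint array could not round-trip the home position and
mission metadata, so the wrapper object is the unit of exchange. Numbers
are written with 17 significant digits, making export → import the
identity.

The WPL dialect is `QGC WPL 110` text: one `NAV_WAYPOINT` row (command 16,
param1 = hold seconds, param4 = yaw) per survey waypoint and one
`RETURN_TO_LAUNCH` row (command 20) per go-home waypoint, so an n-waypoint
mission is exactly n rows plus the header. The format has no home record
under this layout; home coordinates ride on the return rows, and a file
with no return row imports with home defaulted to the first waypoint.
Mission metadata does not survive WPL. A `QGC WPL 109` header parses with a
warning.

## Cube I/O

Cubes are rows × cols × bands arrays with strictly increasing band-center
wavelengths in nm (bands are re-sorted ascending on construction so index
arithmetic is deterministic). Missing pixels are `NA` in memory; files
carry a sentinel (`nodata`, default −9999). `band_at()` resolves a
wavelength to the nearest band, erring beyond a tolerance (default 15 nm, a
typical multispectral band half-width) and breaking ties toward the lower
wavelength.

ENVI (.hdr text + BSQ binary) is the primary format: integer DN cubes are
stored as int32 and round-trip bitwise; other data as float32 (or float64
on request, which round-trips exactly). Multiband TIFF is supported through
baseline TIFF samples in [0, 1]: values are linearly rescaled (scale/offset
recorded in a JSON sidecar along with wavelengths and units), integer DN up
to 65535 uses 16-bit samples and round-trips exactly, continuous data uses
32-bit samples (~1e-7 of the range). Nodata travels as a trailing 0/1 mask
plane so the sentinel never contaminates the value scaling. Only BSQ
interleave is read; processing is band-at-a-time, so peak memory is a few
bands rather than twice the cube.

## Empirical-line calibration

Per band, ordinary least squares of panel reflectance on mean panel DN
(`stats::lm.fit`): reflectance = gain·DN + offset. Regressing in this
direction means application is one multiply-add per pixel. At least two
panels with distinct mean DN are required; two panels interpolate exactly,
three or more report r² per band. Panel regions are user-supplied
rectangles — automatic panel detection is out of scope.

Two reflectance presets ship: `"mosaicmill"` (black 10%, gray 30%, white
57%, the default) and `"binary"` (0%/100%). Both conventions appear in the
field's practice for gray-scale fabric targets; neither is silently
preferred beyond the documented default, and per-wavelength panel curves
can be supplied instead of flat spectra.

Corrected output is clipped to [0, 1.5] by default: genuine reflectance
lies in [0, 1], but specular glints and panel overshoot are better bounded
than collapsed to 1; the clip is configurable (including off). Nodata
propagates; correcting an already-reflectance cube is refused.

## The index registry

All 18 indices live in one declarative registry: each entry names its
required bands (target nm + tolerance + role), its coefficients with
defaults, its formula over roles, an expected output range and an optional
classification. Fifteen are closed-form literature definitions (NDVI, RVI,
EVI, SAVI, CCI, ARVI, GCI, MCARI, DCNI, SIPI, NBR, DNBR, NDWI, PRI, PSRI —
citations in `?index_registry`); since only NDVI's formula is fixed by the
application this package reimplements, keeping the rest as data means a
disagreement with any particular legacy implementation is a configuration
change, not a code change.

Choices made where definitions collide with a finite band set
(450, 531, 560, 570, 640, 680, 705, 750, 800, 860, 1240, 2200 nm):

* DCNI's canonical 720/700/670 nm red-edge triplet collapses onto a single
  band of this set (both 720 and 700 resolve to 705), so its default
  targets are 750/705/680 with the canonical formula; the original bands
  remain reachable on richer cubes via per-band configuration.
* PSRI's 500 nm band carries a 35 nm tolerance so it resolves to 531.
* SSC, TA and PLS are chemometric regression quantities with no universal
  closed form; they are user-parameterized linear combinations
  (`c(intercept = ..., w860 = ..., ...)`) and refuse to run without
  coefficients rather than guess.
* DNBR is a two-epoch difference (pre minus post NBR) and takes two cubes.

Per-pixel evaluation turns zero denominators and nodata inputs into nodata
(histograms stay finite). DN cubes are refused with a calibration hint.
Classification rules are half-open intervals (lower, upper]; the default
NDVI rule labels (−∞, 0.3] `not_healthy` and (0.3, ∞) `healthy`, so a pixel
at exactly 0.3 is not healthy. Histograms use fixed [−1, 1] edges for
normalized-difference indices and the observed range otherwise; counts
always sum to the valid-pixel count.

## Rendering and reports

Pseudo-color maps are written directly as RGBA PNGs (`png::writePNG`):
linear value→color over [vmin, vmax] (defaults to the index's expected
range), out-of-range values clamped to endpoint colors, nodata fully
transparent. The default `"vegetation"` colormap ramps red→yellow→green,
the conventional low-to-high vigor rendering. Rendering is pure: identical
inputs give identical bytes, asserted in the suite. PDF reports are one
metadata page plus one page per index (pseudo-color, histogram, class
counts); embedded images are decimated above 2048 px per side.
Regeneration is idempotent on content — the PDF container's
creation/modification timestamps are the only difference between runs.

## The synthetic scene generator

`make_scene()` builds: a dry-soil background spectrum; rectangular
vegetation regions whose 640/860 nm reflectances are solved so NDVI hits
each region's target exactly (red + NIR fixed at 0.5, other bands
vegetation-plausible); flat-spectrum calibration panels (10/30/57% by
default); then inverts a per-band linear sensor (DN = (ρ − offset)/gain,
gains 8e-4–1.2e-3 reflectance/DN across bands) and adds optional gaussian
DN noise. The default scene is 64 × 64 px × 12 bands with three vegetation
regions (NDVI 0.60, 0.20, 0.45) giving a constructed healthy fraction of
0.625. Everything is seed-deterministic and the truth record carries the
full reflectance field, sensor parameters and healthy fraction, so every
downstream module is verifiable without re-derivation.

What it emulates: a linear sensor with additive noise, known flat panels,
piecewise-constant vegetation. What it does not: atmospheric effects
(negligible at UAV altitudes, and out of scope), illumination gradients,
BRDF, geometric distortion, registration error, spatially correlated
noise, mixed pixels. Passing tests therefore demonstrate the *algorithms*
(calibration inverts a linear sensor; indices evaluate their formulas;
classification counts are exact), not robustness to real-sensor artifacts.

## Problem sizes and runtime choices

The suite runs at desk scale by design: 10⁴ random point-in-polygon pairs,
100 random camera models, 200 replicate calibration fits at 1% DN noise on
a 24 × 32 × 3 scene, 64 × 64 × 12 end-to-end scenes, and dozens of random
routes. The full test suite completes in well under a minute on one core;
the acceptance script in a few seconds. Fixtures are generated in code at
run time — the repository carries only two small camera configs and a demo
GeoJSON.

## Known limitations

* Spherical geodesy only; no projected CRS input/output.
* The go-home rule is myopic (see above) and uses 2-D distances.
* No orthomosaicking, stitching or registration: one cube in, one map out.
* WPL files cannot carry mission metadata or (without a return row) the
  home position.
* SSC/TA/PLS produce numbers only as good as the user-supplied regression
  coefficients; there is no built-in calibration set for them.
* The boundary rule makes tessellation exactly reproducible, but tiles
  whose only polygon contact is the top/right boundary line are excluded
  by convention.
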