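---
title: "Gaze metadata in multimedia containers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze metadata in multimedia containers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemux)
```

## The problem

A gaze dataset is inherently multimodal: per-subject point-of-regard time
series, annotated objects of interest, sometimes EEG, all referenced to one
stimulus video. `gazemux` treats the multimedia container as the exchange
unit. Subtitle tracks are repurposed as shape carriers — a media player then
*is* the visualization tool — while attachments keep the raw data intact for
expert analysis. Two encodings coexist deliberately:

* **USF (lossless).** An XML subtitle dialect extended with geometric shape
  elements. XML can hold arbitrary extra payload, so every sample's raw
  timestamp, pupil size and label are preserved and decoding is exact.
* **ASS (lossy, universal).** A plain-text subtitle format with vector
  drawing commands that stock players render without modification. It
  cannot carry non-visual payload; the conversion keeps geometry and timing
  (at centisecond grain) and drops the rest.

## Coordinate and time conventions

All geometry lives in video pixel space: origin top-left, x rightward, y
downward, 0-based, at the stimulus resolution (ASS `PlayResX/PlayResY` are
set to the video resolution so drawing coordinates equal video pixels).
Time is seconds from video start, held as doubles. A sample at time $t$ is
displayed during the half-open frame interval

$$\left[\frac{\lfloor t \cdot \mathrm{fps}\rfloor}{\mathrm{fps}},\;
\frac{\lfloor t \cdot \mathrm{fps}\rfloor + 1}{\mathrm{fps}}\right)$$

Half-open intervals tile time, so boundary samples belong unambiguously to
the frame that starts there (a `1e-9`-relative guard absorbs floating-point
droop in `t * fps` at exact boundaries). Eye trackers commonly sample
faster than the video frame rate; all samples of a frame are emitted as
co-timed events and are shown together, which is the intended behavior, not
aliasing. Off-screen samples are retained and flagged, never dropped — the
carrier is lossless by mandate.

Timestamp dialects (seconds, milliseconds, microseconds, sample index)
differ by vendor, so `column_spec` makes the unit explicit; sample indices
are divided by the declared sampling rate.

## Fixation/saccade detection

`classify_events` implements dispersion-threshold identification (I-DT): a
window is grown while $(\max x - \min x) + (\max y - \min y) \le D$; if it
reaches the minimum duration $T_{\min}$ it is extended maximally and
labeled *fixation*, otherwise its start sample is a *saccade* sample and
the window advances by one. Every sample ends up with exactly one label.
Defaults are $D = 0.02\cdot\max(\text{width},\text{height})$ pixels and
$T_{\min} = 0.1$ s. These are package defaults chosen to be reasonable for
screen-resolution stimuli, not calibrated constants; both are exposed, and
any serious use should match $D$ to the tracker's noise. Velocity-based
(I-VT) detection is out of scope.

## The USF shape dialect

The upstream USF draft leaves its shape grammar incomplete, so the XML
attribute set written by `write_usf` is normative *for this package*:

```
<shape type="point|rectangle|polygon"
       x= y= radius= | x= y= width= height= | points="x1,y1 x2,y2 ..."
       outline="#RRGGBB" fill="yes|no" fillcolor="#RRGGBB"/>
```

Non-visual payload is stored as per-event `<comment key value>` children
rather than a sidecar file, preserving the single-file property. Numbers
are fixed 6-decimal, `.`-separated, locale-independent; this makes
serialization idempotent (`write(read(write(doc)))` is byte-identical) and
defines the round-trip precision (1e-6). Point radius encodes relative
pupil size, $r = r_0\, p/\tilde p$ with $\tilde p$ the trajectory median
pupil and $r_0 = 8$ px by default; fixation samples are drawn as squares of
side $2r$, saccade samples as circles, so the two event classes are
distinguishable at a glance. For fixation rectangles the raw center also
rides in the payload, since the corner coordinates are rounded text.

## The ASS mapping

Each shape becomes one `Dialogue` line whose text is a drawing block
`{\an7\pos(0,0)\p1}…{\p0}` (top-left anchored at the origin, so drawing
coordinates are absolute):

* rectangle → `m x y l x+w y l x+w y+h l x y+h`
* polygon → `m v0 l v1 … l vn`
* circle of radius $r$ → four cubic Bézier quadrants with control-point
  distance $k = 0.5523\,r$; the analytic radial error of this classic
  approximation is below $0.03\,r$, and integer coordinate rounding
  (half-up; renderers disagree on fractional coordinates) adds at most
  about 1 px.

Times are rounded to the ASS centisecond grid with a minimum duration of
1 cs so no event vanishes. Only `m`, `l`, `b` are emitted — B-spline
commands exist in the grammar but are less widely rendered. One style per
source; `merge_ass_tracks` restyles each input with a distinct color from a
fixed 8-color palette (overridable), renames styles with a per-input
prefix to avoid collisions, and orders events by (start time, input index),
stable within each input. Merging exists because players display a single
subtitle track at a time; comparing subjects requires a merged track.

## The reference rasterizer

Visual output of a media player cannot be asserted in tests, so the package
carries the drawing model itself: integer Bresenham lines (8-connected,
both endpoints included), midpoint circles (8-way symmetric; verified
equal to a per-octant brute-force minimizer of $|x^2+y^2-r^2|$), and
even-odd scan-line polygon fill sampling pixel centers $(x+0.5,\,y+0.5)$ —
a pixel is filled iff its center is inside, which makes the fill exactly
reproducible by a point-in-polygon oracle and handles self-intersecting
polygons. Filled circles use per-scanline spans between the boundary's
x-extents. No anti-aliasing anywhere: binary rasterization keeps every
primitive oracle-checkable. Overlaps resolve in painter's order (later
event wins per pixel); shapes are clipped to the frame after
rasterization.

## Sonification

The alpha-band power envelope is computed as: demean, band-pass 8–13 Hz
with a zero-phase 4th-order Butterworth design (order-2 forward–backward
via `signal::filtfilt`; demeaning avoids DC edge transients), square,
moving-average over `window_s` (default 0.25 s, edge-truncated windows),
linear-resample to the audio clock, and normalize so the trace maximum
maps to 1 (an all-zero trace stays zero; `normalize = FALSE` exposes raw
power, ≈ $A^2/2$ for an in-band sinusoid of amplitude $A$). The band
edges, window and the FM deviation below are package defaults, exposed as
arguments — they are conventions of this implementation, not measured
constants.

Two synthesizers share the 220 Hz carrier (note *a*):

* **FM**: $s[n] = \sin\!\big(2\pi \sum_{k\le n} (f_c + \Delta f\,
  \mathrm{env}[k])/f_s\big)$ with $f_c = 220$ Hz, $\Delta f = 110$ Hz
  (half the carrier). Phase integration keeps the waveform continuous;
  amplitude is constant, pitch encodes power.
* **AM**: $s[n] = \mathrm{env}[n]\,\sin(2\pi f_c n / f_s)$ — loudness
  encodes power.

Both check the Nyquist condition and are deterministic. Audio is written
as mono 16-bit PCM WAV at 44.1 kHz.

## The container backend

Muxing is implemented natively on EBML, the binary grammar of Matroska:
the package writes and reads the subset of elements it needs (segment
info, track entries, clusters with SimpleBlocks/BlockGroups, attachments).
This keeps the tool self-contained — no system muxer binary is required
anywhere, which also makes the container tests hermetic. The written
layout follows Matroska conventions: millisecond timestamp ticks, one
cluster per second, ASS tracks stored as `S_TEXT/ASS` (script header in
`CodecPrivate`, one block per event carrying
`ReadOrder,Layer,Style,Name,…,Text` with times on the block), audio as
`A_PCM/INT/LIT` in 100 ms blocks, and the procedural stimulus as
`V_UNCOMPRESSED` RGB frames. Attachments are byte-exact by construction.
MP4/OGG output and streaming are out of scope.

## Synthetic data: what it does and does not emulate

`gen_gaze` alternates fixations (Gaussian jitter, SD 3 px by default,
around uniformly drawn on-screen points; 0.2–0.4 s) and saccades (linear
interpolation, 20–60 ms) at 250 Hz, with pupil size a smoothed positive
random walk — magnitudes typical of a desktop eye-tracking session. These
generator settings are fixed conditions of the test bed, chosen once for
plausibility. The generator emulates the *structure* the formats must
carry (event alternation, multi-sample frames, pupil variation), not
oculomotor dynamics: saccades have no main-sequence velocity profile,
fixation jitter is white rather than drift + tremor, and blinks are
absent. Passing tests therefore certify the data path — parsing, encoding,
merging, muxing, rendering, recovery — on realistic magnitudes, not
detector performance on real recordings. `gen_eeg` is white noise plus a
gated 10 Hz sinusoid (the schedule is the ground truth); `gen_annotations`
moves boxes/triangles along linear paths with one static interval per
frame so per-frame re-encoding is exact; `gen_video` draws a frame counter
as a binary strip plus a moving bar, so frames are distinguishable after
remuxing. All generators restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Round-half-up for ASS integer coordinates; fixed 6-decimal text
  everywhere else.
* Frame-boundary times: see the guard above; `frame_index` is
  `floor(t·fps)` with boundary correction.
* Empty inputs are first-class: empty trajectories, annotation lists,
  documents, and envelopes all round-trip; a zero-radius circle degrades
  to a move-only drawing; an all-zero envelope synthesizes silence (AM)
  or the bare carrier (FM).
* A USF document stripped of its payload decodes in a declared degraded
  mode (times quantized to frame starts) with a classed warning, rather
  than failing.
* Test problem sizes — 64×48 @ 25 fps video, 250 Hz gaze, 100-instance
  oracle sweeps, 50-trajectory round-trip batches — were chosen so the
  full suite exercises every path at desk scale.

## Known limitations

Single-channel EEG only; no artifact rejection. The ASS parser accepts the
subset it emits, not arbitrary scripts. The EBML reader targets containers
this package writes (plus structurally similar ones); it is not a general
Matroska validator. Real-player rendering differences (fractional
coordinates, fill rules) are outside what the reference rasterizer can
certify.
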