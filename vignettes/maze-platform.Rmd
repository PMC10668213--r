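---
title: "A headless engine for zone-triggered maze experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A headless engine for zone-triggered maze experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazesim)
```

## The experimental platform, in software

Open circular platforms ringed with cue lights and reward spouts are a
workhorse of rodent spatial-cognition research: an overhead camera tracks
the animal, virtual circular *zones* are laid over the camera image, and
entering or leaving a zone both timestamps the event (as a binary TTL word
sent to the electrophysiology acquisition system) and can trigger a reward
— a liquid drop from a solenoid valve or an electrical pulse train to the
medial forebrain bundle. mazesim re-implements that control loop without
any hardware, so the full behavior of a session — zone events, reward
sequencing, stimulation trains, tracking, calibration, post-processing —
can be run, inspected and regression-tested at a desk.

The package follows the original platform's structure: a *session
configuration* (zones, an ordered rewarded-zone list, reward type,
stimulation parameters, dwell delay, metadata), a *task engine* that
consumes a stream of tracking samples and emits timestamped events, a
*virtual I/O layer* (48-line LED/event bank, 16-line valve bank, binary
zone codes), a *vision pipeline* reproducing the threshold → connected
regions → largest region → centroid → normalization chain of the original
video workflow, and a *simulator* that stands in for the animal and the
camera.

## Zones, hysteresis and the platform geometry

A zone is a closed disk in camera-pixel coordinates (origin top-left, x
rightward, y downward); a point on the boundary counts as inside. The
platform's standard complement is 32 evenly spaced wall LEDs; zones are
usually placed at those positions by the auto-calibration routine.
Perimeter positions are generated at angles `start + (k-1)·360/n` degrees
with the mathematical convention (0° along +x, counterclockwise in a y-up
frame); because image y points down, renderers see the angular order run
clockwise — the stored coordinates are the same either way, and the y-flip
only matters when interpreting angles, which `head_direction()` handles
internally.

*Hysteresis* multiplies the zone radius while the animal is inside
(default factor 1.5, per zone), so a nose poke across the boundary is not
logged as an exit-and-re-entry. The original description states that the
radius is temporarily increased but not by how much; 1.5 was chosen once
as a middle ground — large enough to absorb head movements of a few
centimeters at typical camera scales, small enough that neighboring zones
on the 32-position ring do not capture each other — and is configurable
per zone. The enlarged radius applies whenever the animal is flagged
inside, including while the dwell-delay timer runs.

## The task engine

The engine is a deterministic state machine advanced one tracking sample
at a time (`engine_step()`). Per sample it:

1. rejects non-monotone timestamps;
2. freezes all occupancy state on invalid (lost-tracking) samples —
   dropouts must never fabricate zone exits;
3. flips per-zone occupancy flags using the hysteresis rule, emitting
   `zone_entry` / `zone_exit` events, each carrying its 8-bit TTL word;
4. applies the reward logic for the single *armed* rewarded zone.

At most one rewarded zone is armed at any time. The rewarded-zone list is
ordered, may repeat ids, and advances when the armed zone is triggered or
when the experimenter presses "Next Cue" (`next_cue()`); with
`randomize_rewards` the next armed id is a uniform draw with replacement
from the list, using a session RNG seeded from `rng_seed` (draws are
reproducible and never disturb the caller's RNG state). With-replacement
sampling mirrors the random-lights task, the only sampling scheme the
original protocol specifies.

**Dwell delay.** When `dwell_delay > 0`, the reward requires continuous
occupancy of the armed zone, measured from the entry sample; leaving the
zone (at the hysteresis radius) resets the timer, and the zone stays armed
after a failed dwell. `advance_on_passthrough = TRUE` changes the second
part: exiting the armed zone without a reward also advances the arming —
the behavior the spatial reorientation task needs, where running through
the reward zone activates the end-of-track zone. Both rules are engine
configuration because the original protocol states the delay requirement
but not the reset rule; "reset on exit, stay armed" is the strictest
reading consistent with it.

Rewarded lists may mix zones whose role is `tracked` (sequence
checkpoints, end zones): triggering them advances the arming but delivers
nothing.

## TTL encoding

Zone numbers 1–32 are announced in binary. The original description fixes
the range but not the wire format, so the package documents one and keeps
it bit-exact: lines 0–5 carry the zone id as a 6-bit big-endian code, line
6 is a direction flag (entry = 1), line 7 a per-event strobe.
`encode_zone_event()` / `decode_zone_event()` are exact inverses over all
64 combinations, and every entry/exit event in an engine log carries its
word. LED state changes are logged only when a line actually changes;
valve pulses are paired rising/falling changes separated by the valve-open
duration (default 0.1 s, a configuration parameter — the original never
states the volume calibration).

## Stimulation trains

A train is defined by frequency f (Hz), duration d (s) and duty cycle
(percent of each cycle high): `n = floor(f·d)` cycles of length `1/f`,
each high for `duty/100` of its length from cycle onset. Partial trailing
cycles are dropped — the number of stimuli is set by duration and
frequency. Total high time is exactly `n·(duty/100)/f`; at 100% duty the
intervals coalesce into one span. Edge triggering (`on_trigger()`) fires
one train per selected rising or falling edge of a sampled TTL input, with
a lockout equal to the train duration so re-triggers during an ongoing
train are ignored. Bipolar output is modeled as a symmetric biphasic split
of each pulse (equal positive and negative half-phases, signed integral
zero); physically this conversion happens in the stimulus isolator, so the
software model is explicitly an abstraction, and stimulation amplitude is
deliberately not a parameter — it lives on the isolator.

## Vision pipeline and auto-calibration

Frames are numeric matrices (or H×W×3 arrays averaged to grayscale).
The pipeline thresholds at an intensity T, labels 8-connected foreground
components (8-connectivity avoids splitting blobs that touch diagonally),
computes plain unweighted binary centroids, and selects the largest region
after discarding regions below a minimum area (default 5 px — a noise
floor the original settings imply but never state). Ties are broken toward
the smallest centroid y, then x, so tracking is deterministic. Positions
are normalized by frame size for resolution independence.

Head direction uses two marker centroids from separate color channels:
the angle of the rear→front vector in [0, 360). A missing or coincident
marker yields 0° with a single-marker flag, matching the original
tracker's behavior when two-color tracking is unavailable.

Auto-calibration lights the wall LEDs one at a time in index order,
median-combines 3 frames per LED (a per-pixel closed-form median; one
frame works, the median suppresses single-frame noise), and records the
bright region's centroid as the zone center. A missing detection names the
failing LED; more than one region above the size floor is an ambiguity
error rather than a guess.

Streaming messages are one-line JSON documents with a fixed versioned
schema (address `"/position"`, payload `[frame_index, x_norm, y_norm,
angle_deg, valid]`). The original platform streams positions over UDP; a
text-only library models the message contract, not the socket, and the
loopback tests exercise serialization, order and losslessness in-process.

## The simulator and what it does (not) show

The agent is waypoint pursuit at constant speed with Gaussian reporting
jitter, per-waypoint dwell pauses, and independent per-sample dropouts —
deliberately simple, because the simulator exercises the engine, not
rodent behavior. Rendered frames are a dark platform (background 20), the
animal as a bright disk (intensity 200, radius 6 px), lit LEDs as small
dots (255, radius 2 px), on the standard 480×480 px scene with the LED
ring at radius 200 px around (240, 240). Passing tests therefore show
that the *control logic* is correct under realistic geometry, sampling
(30 samples/s) and tracking noise; they do not show robustness to real
video artifacts (shadows, reflections, occlusions, cable drag) or to real
locomotion statistics.

Presets reproduce the published task configurations:

* **spatial_reorientation** — three tracked zones (unreachable start zone,
  rewarded zone with a 1.5 s dwell delay, end zone),
  `advance_on_passthrough` on, per-trial start positions drawn once from a
  seeded list (the movable start box).
* **sequence_task** — five zones among the 32 ring positions, rewarded in
  the repeating 8-item order 1-2-3-4-1-2-3-5 from a zone-5 start, dwell 0.
  The original fixes the order but not *which* five ring positions; the
  preset uses spread positions 5, 12, 18, 25, 31, chosen once.
* **random_lights** — all 32 zones, rewarded order a seeded uniform draw
  with replacement (default length 900, the published session scale; tests
  drive shorter scripted sequences and test the 900-element draw directly).
* **oppa** — seven zones (two choice platforms, two arms, center, two
  off-maze manual-reward zones), no automatic reward. The original figure
  legend and text disagree on the zone count (five vs seven); the preset
  follows the text's enumeration.
* **mat_allocentric / mat_transformation** — eight arm zones plus a center
  zone and an off-maze rewarded zone, rewarded list (R, off-maze) so each
  reward is delivered once until "Next Cue" re-arms; **mat_egocentric**
  timestamps zones only, with rewards recorded through the manual
  stimulation counter.

`run_session()` plays the experimenter through a preset predicate
(`next_cue_when`): the reorientation clicker fires when the animal is back
in the start-box region, the MAT re-arm when it returns to the center.

## Post-processing

`segment_trials()` splits reorientation-style logs into trials (trial
start to the next end-zone entry, reward timestamp attached, orphans
reported). `velocity_profile()` computes speed by central finite
difference over valid samples, smooths with a 5-sample moving average
(default; 1 disables), and bins by the *signed* along-track distance to
the reward-zone center — the 1-D projection onto the outbound track axis,
negative before the zone. Sign convention, bin width (5 px) and smoothing
are package choices; the original only fixes "position relative to the
reward zone". `exclude_lost_tracking()` drops trials whose longest invalid
run spans more than `max_gap` seconds (default 0.5 s — the original says
only "too extensive") and linearly interpolates shorter gaps.
`criterion_met()` implements the training criterion — strictly over 80%
correct in at least 3 of the last 4 sessions; "over" is read strictly so
the rule is reproducible, and an any-window variant is provided because
the original does not say whether the window is the most recent four or
any four consecutive sessions.

## Numerical choices and degenerate inputs

* Boundary convention: distance equal to the effective radius is inside.
* Timing is in seconds from sample timestamps, never frame counts, so all
  logic is sample-rate independent.
* Log timestamps are written with 6 decimal places for byte-stable files;
  determinism tests compare logs byte for byte.
* The engine RNG is stored in the session state (save/restore of the
  generator state), so engine draws are reproducible and isolated.
* Degenerate inputs fail loudly: non-monotone timestamps, empty rewarded
  lists on draw, zero-area calibration detections, out-of-range lines,
  sub-cycle stimulation trains.

## Problem sizes

The shipped tests run random walks of 1,000 samples, 9,000 seeded reward
draws, 10,000-element sequence draws, 50×50 noise frames against the
labeling oracle, 80–120 rendered frames for the end-to-end loop and
32-LED calibrations at 480×480 px; sessions simulate 30–150 s at 30
samples/s. These sizes were chosen as the smallest at which the
statistical checks (uniformity, dropout calibration, recovery errors) are
stable.

## Limitations

No hardware I/O: boards, valves, isolators and sockets are virtual
contracts. The simulator does not model learning, realistic locomotion, or
video artifacts. The original `.mat` settings files are not imported — the
canonical format here is the documented JSON schema. Electrophysiology
(spike data, place-cell maps) is entirely out of scope: the package stops
at the events, logs and analyses the behavioral platform itself produces.

## A worked session

```{r example}
preset <- load_preset("sequence_task", seed = 1)
session <- run_session(preset, t_max = 60, seed = 1)
session
summary(session)
```
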