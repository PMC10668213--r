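# mazesim

A headless, hardware-free engine for **zone-triggered rodent maze
experiments**. Open circular platforms ringed with cue LEDs and reward
spouts are a standard apparatus in spatial-cognition research: an overhead
camera tracks the animal, virtual circular zones are laid over the camera
image, and entering a zone both timestamps the event — as a binary TTL
word sent to the electrophysiology acquisition system — and can trigger a
reward (a liquid drop from a solenoid valve, or an electrical pulse train
to the medial forebrain bundle). mazesim re-implements the full control
loop in software so that every task such a platform runs — spatial
reorientation on a linear track, complex spatial sequences, random-lights
foraging, object–place paired associates (OPPA), map-to-action
transformation (MAT) — can be configured, executed against a simulated
animal and camera, and regression-tested at a desk. It is aimed at
behavioral/systems neuroscientists who want to prototype task logic,
validate session configurations, or analyze event logs without booking rig
time.

## What it implements

* **Zone geometry** — closed-disk zones in camera-pixel coordinates with
  entry *hysteresis*: while the animal is inside, the effective radius is
  `radius × h` (default `h = 1.5`), so small head movements at the
  boundary never log false exits. The standard platform layout is 32
  evenly spaced perimeter positions, with one reward spout over every
  fourth LED (8 spouts).
* **Task engine** — a deterministic state machine over a tracking-sample
  stream. At most one rewarded zone is *armed* at a time; the ordered
  rewarded-zone list (repeats allowed, optional seeded randomization)
  advances on each trigger or manual "Next Cue". Rewards can be gated on a
  *dwell delay*: continuous occupancy for `dwell_delay` seconds, timed
  from the entry sample and reset on exit. Lost-tracking samples freeze
  occupancy instead of fabricating exits.
* **TTL encoding** — zone events as 8-line binary words (6-bit big-endian
  zone code on lines 0–5, entry/exit flag on line 6, strobe on line 7)
  on a virtual 48-line LED/event bank plus a 16-line valve bank;
  encode/decode form a bijection over all 64 zone–direction pairs.
* **Stimulation trains** — `n = floor(frequency × duration)` cycles, each
  high for `duty_cycle`% from cycle onset; total high time is exactly
  `n·(duty/100)/frequency`. Manual and edge-triggered automatic delivery
  (rising or falling edge, lockout = train duration) and a charge-balanced
  biphasic (bipolar) conversion.
* **Vision pipeline** — threshold → 8-connected region labeling → largest
  region above a noise floor → binary centroid → frame-size
  normalization; two-marker head direction in degrees; sequential-LED
  auto-calibration that places one zone center per wall LED.
* **Simulator** — waypoint-pursuit agent with jitter and dropouts,
  synthetic camera frames (dark platform, bright blob, LED dots), and
  presets reproducing each published task configuration.
* **Post-processing** — trial segmentation, reward-aligned velocity
  profiles (signed along-track distance), lost-tracking exclusion with
  gap interpolation, and the training criterion rule (strictly over 80%
  correct in ≥ 3 of the last 4 sessions).

## A worked example

The complex spatial sequence task uses five zones among the 32 perimeter
positions, rewarded in the repeating 8-item order 1-2-3-4-1-2-3-5 from a
zone-5 start, with no dwell delay:

```r
library(mazesim)
preset  <- load_preset("sequence_task", seed = 1)
session <- run_session(preset, t_max = 60, seed = 1)
session
#> <maze session 'sequence_task'> 1800 samples over 60.0 s, 41 events
#>   rewards 8 | animal stim 0 | zone entries 9 | invalid samples 0
```

One full traversal of the loop delivers exactly **8 rewards** — one per
item of the sequence; 9 zone entries because the agent starts inside
zone 5. The event log shows each reward with its zone and timestamp:

```r
head(session$events[session$events$kind == "reward", ], 3)
#>           t   kind zone_id ttl_word detail
#> 4  1.700000 reward       1     <NA> liquid
#> 9  4.100000 reward       2     <NA> liquid
#> 14 6.266667 reward       3     <NA> liquid
```

A stimulation train of 100 Hz for 0.5 s at 50% duty cycle:

```r
build_pulse_train(stim_params(100, 0.5, 50))
#> <pulse train> 50 high interval(s), 50 cycle(s), 0.250000 s high total over 0.5 s
```

i.e. 50 cycles of 10 ms, each high for 5 ms — 0.25 s of total high time,
exactly the closed form `50 × 0.5 / 100`.

## Command line

A thin wrapper over the same functions ships at `exec/maze`:

```sh
Rscript exec/maze run-sim --preset sequence_task --seed 1 --t-max 60 --out out/
Rscript exec/maze stim --freq 100 --duration 0.5 --duty 50
Rscript exec/maze calibrate --n-leds 32 --out calibration.csv
Rscript exec/maze postprocess --events out/events.csv --samples out/samples.csv \
        --end-zone 3 --reward-x 240 --reward-y 240 --out profiles.csv
Rscript exec/maze validate-config settings.json
```

All subcommands take `--seed` wherever randomness exists and exit non-zero
on error.

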