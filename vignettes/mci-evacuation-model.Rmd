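---
title: "Modelling hospital driving times for mass-casualty evacuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hospital driving times for mass-casualty evacuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcidss)
```

## The problem

When a mass-casualty incident (MCI) overwhelms local health-care capacity,
the on-scene decision is not "which hospital is closest" but "which
hospitals, in what order, can absorb this many critically injured patients,
and how long does each evacuation take". Answering that in real time
requires three ingredients: a road-network travel-time model, a hospital
registry with trauma designation and surge capacity, and a way to combine
them in well under a second. `mcidss` implements this as a desk-scale
library: driving times are precomputed from every point of the road network
to every hospital once, so an incident query is a table lookup.

## The travel-time model

A road network is a planar graph of intersections and road segments. Each
segment carries a posted speed limit and each intersection an optional
control. The traversal time of a segment entered at its downstream node is

\[
t = \frac{L}{v \cdot f} + d(\mathrm{control}),
\]

with \(L\) the polyline arc length in metres, \(v\) the posted limit in
m/s, \(f\) the `vehicle_speed_factor`, and \(d\) a fixed impedance: 0 for
an uncontrolled node, 5 s for a stop sign, 10 s for a traffic light by
default. These impedance magnitudes are the values experienced paramedics
attach to urban controls; both are configurable (`mci_config()`), as is the
speed factor, which models the difference between an ambulance running
lights-and-sirens and a regular vehicle. The default factor is 1.0 —
neutral, i.e. driving at the posted limit — because no published magnitude
exists for the ambulance differential; users with local data can calibrate
it.

Two conventions matter and are applied consistently everywhere (the
precomputation, the single-pair checker `od_time_single()`, and the
brute-force test oracle):

* **Origins are segment centroids.** A trip starts at the point at half the
  arc length of its origin segment and first traverses the residual half,
  in either direction unless the segment is one-way. No impedance is
  charged at the origin point.
* **No impedance at the destination.** A vehicle arriving at the hospital's
  ER entrance does not wait at a final light. The delay of a controlled
  intersection is charged when a route *enters* it and continues; it is
  dropped when the snapped destination sits exactly on that node.

Directedness follows the `one_way` flag; segments default to bidirectional.
All geometry is in a projected planar CRS with metre units — geographic
coordinates must be projected before loading, because every length here is
a Euclidean arc length.

## Discretization

Driving times are precomputed per segment, so long segments would make the
origin coarse: a clicked point can be up to half a segment away from the
centroid the table actually uses. Segments are therefore capped at
`max_segment_length_m` (default 200 m): a segment at or below the cap is
kept unchanged (the boundary case stays whole, so the invariant reads
"length \(\le\) cap"), and a longer one is subdivided into
\(\lceil L / 200 \rceil\) parts of equal arc length. Equal parts — rather
than fixed 200 m steps with a short remainder — minimize the worst-case
centroid error and are trivially reproducible; either scheme satisfies the
cap. Part ids derive deterministically from the parent id and part index,
so a saved driving-time table remains valid across rebuilds of the same
network, and every part resolves back to its parent segment through a
one-to-many index.

With a 200 m cap, the centroid approximation contributes at most 100 m of
origin error — about 7 s at 50 km/h — which is below the one-minute
rounding used for display.

## Precomputation and lookup

`precompute_od()` computes, for every part centroid and every hospital, the
minimum over all paths of summed traversal times. The realization is a
single-source Dijkstra search (via `igraph`) from each hospital over the
reversed travel direction: hospitals number a handful while centroids
number thousands, so \(H\) searches beat \(N \times H\) point queries. The
contract, however, is algorithm-independent, and the test suite holds the
implementation to an exhaustive enumeration of all simple paths on small
random networks, exactly (to 1e-9, the float-summation-order limit).

Unreachable pairs (a disconnected island, or a one-way configuration with
no return path) are flagged explicitly — `reachable = FALSE` and a missing
time — never encoded as a sentinel number. Tables persist as a diff-able
CSV plus a JSON metadata sidecar holding the configuration snapshot and a
network fingerprint; loading a table against a different network refuses
unless forced.

Times are stored in full seconds and rounded only on output
(`lookup_time(..., rounding = TRUE)`, round half up), since minute-level
storage destroys information. Whole minutes are the display convention, and
the unit in which model times are comparable to ambulance logs.

## Hospitals, ranking and allocation

Hospitals are geocoded at the main emergency-room access rather than the
campus centroid — large hospitals span blocks, and the ER door is where the
ambulance stops. Each hospital carries a Canadian trauma-centre designation
(1 = tertiary/academic through 4 = secondary with bypass protocols; 9 marks
a non-trauma hospital) and a capacity, interpreted as the number of
critically injured patients the hospital can accept in the current
incident. Capacity and inclusion are session-editable and capacities
decrement as patients are allocated. Treatment specializations travel along
as a free-text services tag: displayed, never used by the ranking, since no
algorithmic use is defined for them.

`query_mci()` snaps the incident to its nearest part (minimum perpendicular
distance, ties to the lowest part id), looks up every included hospital and
returns rows sorted by driving time, unreachable last. Non-trauma hospitals
are always listed — they are the fallback when trauma centres overload.

`allocate_patients()` formalizes a policy that published accounts state
only qualitatively (trauma level 1 preferred when close; non-trauma used
when trauma centres are full): greedy and sequential, each patient goes to
the shortest-time hospital with residual capacity in the highest-priority
tier, with tiers \(\{1,2\} \succ \{3,4\} \succ \{9\}\). The tiering is a
function argument, so alternative policies can be tested. Only "full"
(capacity 0) is modelled; "busy" has no data to model. Patients beyond
total system capacity are counted as unassigned rather than dropped, and
ties break by hospital id so plans are deterministic.

## Validation against ambulance logs

`summarize_deviation()` compares model minutes with logged ambulance
minutes. Deviation is defined as *model − ambulance*, so positive values
mean the model overestimates. Because ambulance logs are minute-granular
and hand-entered, trips are first filtered to departures in low-congestion
windows — overnight 19:00–07:00 and early afternoon 12:00–15:00, closed at
the start and open at the end (no boundary convention is published; this
one is fixed here) — so a free-flow model is compared against near-free-flow
driving. Records lacking a departure time survive only an empty window
list. Per identical origin-destination group the summary reports the trip
count, whether the model time is constant within the group (it must be; the
model is deterministic), and the ambulance min/max/spread — the spread is
real-world variability a static model cannot express.

The package bundles an eleven-trip log of critical transfers between one
suburban hospital and one regional trauma centre
(`inst/extdata/ambulance_trips_smh_rch.csv`): the model's constant 13
minutes against logged times from 8 to 27 minutes, the 27 being a single
outlier trip. The accompanying prose for that log says "nine" trips while
the printed table has eleven rows; the eleven printed rows are treated as
the dataset here.

## The synthetic city generator

Real regional road data is proprietary, so every test input comes from
`generate_city()`: a seeded grid city with configurable dimensions, block
spacing, speed-limit mix, per-intersection stop-sign/traffic-light
probabilities, a fraction of edges replaced by longer dog-leg polylines
(exceeding the 200 m cap, to exercise discretization), and hospitals placed
at random intersections then offset 8 m onto an adjacent street edge,
mimicking ER-entrance geocoding. Grid topology was chosen deliberately: on
a uniform-speed, zero-control grid the shortest time between any two points
has a closed form (residual halves plus Manhattan block count times the
block traversal time), which makes whole driving-time tables checkable to
machine precision.

Generator defaults are fixed once as a plausible mid-size suburban area: a
10 × 10 grid of 150 m blocks; speeds 30/50/60 km/h; stop signs at 30% and
lights at 20% of intersections; 15% long edges; six hospitals with a
trauma-level mix weighted toward non-trauma sites (15/15/20/20/30% for
levels 1/2/3/4/9), and level-dependent surge capacities (level 1: 10–15,
level 2: 8–12, levels 3–4: 4–8, level 9: 3–6 patients). No published
capacity figures exist; these reflect that tertiary centres absorb the most
critical patients in a surge.

`generate_trip_log()` emulates a logged ambulance dataset: observed time =
rounded model time + integer-rounded Gaussian noise (SD in minutes),
floored at one minute, with an optional outlier fraction whose noise is
inflated by a factor. Only origin-hospital pairs whose model time is at
least \(1 + 3\sigma\) minutes are sampled: logged critical transfers run
well above the one-minute floor, and this guarantees the floor does not
truncate the noise, so deviations are unbiased by construction (and exactly
zero in the zero-noise limit). On a city too small to contain such trips
the generator falls back to the one-minute threshold with a warning.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: irregular street morphology, turn restrictions,
time-of-day congestion, closures, and geocoding error in hospital
locations. The grid's closed-form checkability is bought with geometric
regularity.

## Numerical choices

* Rounding to minutes is half-up throughout (`seconds_to_minutes()`).
* Snapping ties (a point equidistant from two parts within 1e-9 m) break to
  the lowest part id; length/arc comparisons use 1e-6 relative tolerance
  for declared-vs-computed lengths and 1e-9 m for exact-node detection.
* Shortest-path agreement with the enumeration oracle is asserted at 1e-9 s
  (the two routes sum identical terms in different orders).
* Degenerate inputs: empty networks after filtering are permitted;
  zero-capacity systems allocate everyone to "unassigned"; an empty trip
  log loads but refuses to summarize.
* Determinism: all generator randomness flows from one integer seed, the
  caller's RNG state is restored afterwards, and repeated runs write
  byte-identical files.

## Problem sizes

The shipped test-and-acceptance workloads use 200 random mini-networks of
at most 8 intersections for the oracle comparison, a 20 × 20 uniform grid
(3 800 table entries) for the closed form, 1 000 random polylines for
discretization invariants, 50 added-light trials on a 10 × 10 city for
impedance monotonicity, 500 random scenarios for allocation invariants,
500-trip logs for noise recovery, and a ~9 000-part (60 × 60) city for the
sub-second query-latency check — sizes at which every property is checked
exhaustively while the whole suite stays interactive.

## Known limitations

Pre-calculated tables cannot absorb live conditions: street or bridge
closures, construction, and traffic all require re-precomputation, and
real-time hospital capacity still has to be entered by hand. Turn
restrictions and time-dependent speeds are out of scope. The allocation
policy optimizes each patient greedily, not the assignment globally; with
homogeneous critical patients and minutes-granular times the greedy and
optimal plans rarely differ, but the tiering is exposed precisely so other
policies can be evaluated.
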