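---
title: "Models and methods behind homecage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homecage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`homecage` analyzes event logs from sensor-equipped group cages in which
every corner visit of every RFID-tagged mouse is recorded together with
per-side nose-poke and lick counts. This vignette explains the data model,
the statistical procedures, the simulator that stands in for animal data,
and the design choices made where the design was genuinely open. It states
no empirical result that the package's tests do not themselves compute.

## The event model

A visit record is `(animal_id, corner, t_start, t_end,
nosepokes_left/right, licks_left/right)`, with times in float seconds from
the experiment start (the first bottle exchange). Corner `k` owns bottles
`2k-1` (left) and `2k` (right), numbered clockwise. Lick and nose-poke
micro-timestamps are deliberately not modeled: every analysis implemented
here (preference, bias, episodes, breakpoints, entry sequences) consumes
per-visit counts and entry times only.

Two conventions matter downstream:

* **Half-open session windows `[start, end)`.** A visit starting exactly at
  a bottle-exchange instant belongs to the new session, never to both, so
  partitioning a table by sessions conserves records.
* **Reject-and-report validation.** Rows with impossible values (negative
  counts, `t_end < t_start`, unknown animals) are dropped with a warning
  and kept in a `rejected` attribute, because real cage logs contain
  transponder glitches; hard failure is reserved for structural problems
  (missing columns).

## Schedules

The intermittent-access builder emits three 24 h alcohol sessions per week
(Monday/Wednesday/Friday at the exchange hour, default 16:00 with a 15:00
option), alcohol corners alternating {I, III} on odd and {II, IV} on even
sessions, and a 4% → 8% → 12% v/v concentration ramp. Quinine adulteration
(seven sessions, 0.01% → 0.03% w/v against a 0.02% saccharin reference),
progressive-ratio and punishment-risk designs are emitted as explicit
session lists.

A session carries one contingency for its reward corners. The operant
designs run FR3 on the water corners at the same time; since the session
type models the reward corners, the water-corner contingency is stored
separately (`water_contingency`). This is a representational choice, not a
claim about the hardware.

**PR starting criterion.** The progressive-ratio ladder is `start`,
`start + increment`, ... The starting value is not a measured quantity; we
default to `start = 3` because animals were pre-trained on FR3 and a
typical ceiling of 21 responses is consistent with 3 + 6 × 3. It is a
visible, configurable parameter of `build_pr_sequence()` and
`pr_criteria()`.

## Metrics

* Preference: `A/(A+W)` over lick counts; side bias: `(R−L)/(R+L)`.
  Both are undefined at 0/0 and propagate as `NA`, never as 0 — "did not
  drink" must not masquerade as "indifferent". Biases beyond ±0.6
  (strictly) are classed strong.
* A *drinking episode* is a visit with ≥ 1 lick. The term is used in the
  field without a formal definition; this is the package's.
* Circadian profiles bin entries by *preceding* hour: bin `h` covers clock
  `(h−1, h]`, so bins sum exactly to the event count.
* Dose conversion: `intake_g = licks × 3 µl × conc/100 × 0.789 g/ml` under
  the default v/v reading, `dose = intake_g / kg`. The two obvious
  conventions (v/v × density vs w/v) bracket, but do not reproduce, the
  published example conversion of ~1257 licks/day to 0.436 g (they give
  0.357 g and 0.452 g); since the convention actually used is unstated,
  both are exposed and `intake_g` may be supplied directly — the
  intake-to-dose step (0.436 g at 26 g → 16.8 g/kg/24 h) is exact.
* The blood-ethanol estimate is a single-point linear calibration
  (300 licks/h ↔ 0.1 ‰ w/v) and is documented as an order-of-magnitude
  screen, not pharmacokinetics.

## Operant analysis

A PR stage completes when one visit to a reward corner contains at least
the current criterion's nose pokes on a reward-bottle side; extra pokes
have no consequence, and the next completion requires a new visit (leave
and re-enter). The breakpoint is the last completed criterion, 0 for a
mouse that completes nothing (distinct from a missing mouse). Visits
between completions and after the last completion are reported separately:
with free-moving animals in a 24 h session the breakpoint saturates, and
the continued visiting is where motivation differences show.

Whether the criterion counter is global per corner or per animal is not
observable from published material; the default pools the two reward
corners into one per-animal counter, with a per-corner option
(`scope = "corner"`).

## Social inference

Each corner's entry sequence (entry = `t_start`) is reduced to adjacent
ordered pairs whose gap lies within [1 s, 60 s]; shorter gaps are likely
chip re-contact artifacts and longer ones are unlikely to be reactions to
the previous mouse. Counts from the four corners are summed into an N × N
matrix with the *first* mouse on columns. The null distribution shuffles
each corner's animal labels over that corner's fixed entry-time slots
(default 100 permutations), so the identical gap filter applies to every
permutation, and each cell is scored as

    z(i → j) = (observed − permutation mean) / permutation SD.

Interpreting z on a standard-normal scale (±2 ↔ p ≈ 0.0455, ±3.5 ↔
p < 0.0005, two-sided) is approximate: pair counts are discrete and cells
are not independent. The package therefore reports scores and labels
(follow/avoid, weak/strong), not calibrated p-values.

Design points that were genuinely open:

* **Counts vs column frequencies.** Because the shuffle fixes the time
  slots, column-normalized frequencies differ from raw counts only by a
  per-column constant, which cancels in z. Counts are used for exactness;
  `normalize_by_first()` provides the column-stochastic view for heat-map
  display.
* **Gap structure in the null.** Shuffling over fixed slots keeps the null
  conditional on the observed timing pattern. The alternative — ignoring
  gaps in the null — is available (`permute_gaps = "ignore"`) but not the
  default, since it confounds timing with identity.
* **Repeat removal.** With `drop_repeats`, consecutive same-mouse runs are
  collapsed to their first entry (keeping its timestamp) in both the
  observed and the permuted sequences, removing self-pairs entirely; a
  skip-only variant was considered and rejected because it treats observed
  and null asymmetrically.
* **Degenerate cells.** A cell whose permutation SD is 0 carries no
  evidence either way; it scores the sentinel 0 and is flagged
  (`zero_sd`).
* **Ties and blips.** Entry-time ties break by stable input order;
  sub-second same-mouse re-entries at a corner are merged before sequence
  building.
* Diagonal cells (a mouse re-entering after itself) are reported apart
  from the social edge list: repeat entry is individual exploration, and
  in real cages it dominates the signal.

## The simulator

`simulate_cohort()` is an agent-based generator whose defaults encode the
conditions the analyses assume:

| parameter | default | rationale |
|---|---|---|
| cohort size | caller-set; 10–14 typical | typical group sizes in this cage format |
| activity curve | two truncated-Gaussian dark-phase peaks (at 2 h and 10 h after dark onset, SD 2 h, 12 and 10 visits/h) over a light floor (5% of mean peak) | reproduces the bimodal dark-phase activity of C57BL/6J group-housed mice; ~120 visits/mouse/day |
| visit duration | log-normal, median 20 s, σ(log) = 1 | majority of visits < 1 min, < 1% above 10 min |
| corner choice | uniform | no spatial preference unless a follow edge fires |
| `p_alcohol` | 0.5 | drinking attempts at alcohol bottles complete w.p. `p_alcohol`, at water w.p. `1 − p_alcohol`, so lick-based preference recovers `p_alcohol` under uniform corner use |
| licks/event | shifted negative binomial, mean 30, dispersion 5 | bursty licking; ~100–500 licks per session-day per bottle |
| `p_attempt` | 0.6 | fraction of visits with a drinking attempt |
| PR persistence | 21 | criterion up to which completion probability stays at 0.9 (0.05 above) |
| punishment suppression | 0.3 | visit rate multiplier to a corner after an air puff; produces near-zero licking under 100% immediate risk and variable licking under 25% delayed risk |
| follow latency | uniform [2, 30] s | inside the [1, 60] s pair-filter window by construction; support outside it is a configuration error |

A fixed seed makes the output bit-identical. Mice are simulated with
non-overlapping visits (one corner at a time); visits inserted by follow
edges or `inject_follower()` are exempt from that check because the social
analysis consumes entry times only.

**What the simulator does not emulate** — and therefore what a green test
does *not* establish: learning or tolerance across sessions, physiological
intoxication feedback, corner perseveration (real mice re-enter the same
corner far above chance), dominance structure, and any vendor-specific
log quirks beyond the canonical dialect.

**A known, instructive bias.** Because a simulated mouse cannot re-enter a
corner before its current visit ends, same-mouse adjacent pairs at short
gaps are *rarer* in observed sequences than under the label shuffle. The
total number of qualifying pairs is fixed by the slots, so off-diagonal
cells inherit a small positive score bias: about +0.14 mean off-diagonal z
for 6-mouse one-day cohorts, +0.08 at 10 mice, +0.06 at 14. At realistic
cohort sizes (10+) the null-calibration requirement (mean within ±0.1)
holds, and the bias is two orders of magnitude below the ±2 decision
threshold — but it is a reminder that the permutation null conditions away
individual timing constraints, in simulation and in real cages alike.

## Numerical and degenerate-input choices

* Ratios at 0/0 are `NA`; zero columns in normalization stay zero and are
  flagged.
* `n_perm ≥ 2` is enforced; permutation SD uses the n−1 denominator.
* Session lookup outside any window falls back to water with a warning
  (bottles always exist physically).
* Event files are written with 17 significant digits so read∘write is the
  identity on doubles.
* All RNG flows from explicit seeds (`cohort_config(seed)`, function
  `seed` arguments, the pipeline's master seed); the pipeline manifest
  records them and contains no timestamps, making reruns byte-identical.

## Limitations

The package computes per-cohort descriptive and permutation statistics; it
deliberately omits the cross-cohort inferential layer (ANOVA, post hoc
tests) that standard tools already provide. The social scores are
screening statistics, not calibrated hypothesis tests, and the simulator
is a test harness for the analysis code — parameter-recovery results on it
validate the pipeline's arithmetic, not any biological claim.
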