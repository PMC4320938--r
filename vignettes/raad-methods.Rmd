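---
title: "Robust anomaly-beat detection in multi-lead ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust anomaly-beat detection in multi-lead ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raad)
```

## The problem

Bedside monitors routinely flag ECG artifacts — baseline wander, powerline
(AC) interference, muscle tremor, electrode motion — as anomalous
heartbeats.  A clinically useful detector must flag morphologically deviant
beats (for example a premature ventricular contraction, PVC) while staying
silent on artifacts, and must report whole cardiac cycles: a detection that
covers only part of a beat, or bleeds into a neighbour, cannot be used for
diagnosis.  `raad` implements a detector built around three ideas borrowed
from clinical practice:

1. all leads record the same electrical activity simultaneously, so the
   least contaminated lead can anchor the analysis of every other lead;
2. the TP segment (T-wave end to next P-wave onset) is electrically silent,
   so activity there is artifact;
3. beats should be compared morphology-segment by morphology-segment, not
   as undifferentiated sample windows.

## Pipeline

### Preprocessing

Each lead is filtered by a second-order Butterworth low-pass at 20 Hz
(suppresses AC interference) followed by a second-order Butterworth
high-pass at 2 Hz (suppresses baseline wander), each applied forward and
backward so the net phase is zero and fiducial positions do not shift.
The forward–backward pass uses odd-reflection padding of `3 * (2 * order)`
samples with steady-state initial conditions — the standard filtfilt
convention — making the output reproducible across platforms to ~1e-9.
Because each biquad is applied twice, the effective attenuation is the
squared magnitude response; the package's tests verify ≥ 20 dB attenuation
at 50 Hz and 0.3 Hz relative to the 10 Hz passband gain.

### Cleanest-lead discovery by variable-length motif discovery

For window lengths on a grid from the starting length
`round((1/3) * (100/60) * fs)` — the systolic third of a cardiac cycle at
the fast end of the normal resting range — up to twice that length (step
`round(fs / 50)` samples), the closest non-overlapping pair of z-normalised
windows seeds a group whose centre is the average of the pair.  Neighbours
join in order of distance to the centre; each is accepted only if the
group's *bitsave* strictly increases, and growth stops at the first
rejection.  The lead and length whose group attains maximal bitsave define
the cleanest lead and the record's beat period; ties go to the shorter
length and the lower lead index.

Bitsave is a minimum-description-length score.  Windows are discretised to
8-bit integers over the z-score range [-4, 4]; a residual vector costs
`sum(log2(2|r| + 1) + 1)` bits.  The standalone cost of a window is its
residual against the quantised isoelectric zero line, and its conditional
cost is the residual against the group centre, so

```
bitsave = sum_members [DL(member) - DL(member | centre)] - DL(centre).
```

This zero-referenced standalone cost matters: with a flat `8 * m`-bit
standalone budget every window — including a PVC — would "compress" through
any centre, because most ECG samples sit near the baseline, and greedy
growth would never stop.  Referencing the baseline means a window only
saves bits where the centre genuinely predicts its morphology, so
dissimilar windows yield negative increments and are rejected.  The centre
deliberately stays the average of the founding pair (re-averaging as
members join is available as an option but not the default).

Two trivial-match rules keep the search meaningful: paired and co-grouped
windows must not overlap (start difference at least the window length),
and z-normalisation uses the population standard deviation with constant
windows mapping to the zero vector.

Everything not covered by a motif member becomes an anomaly candidate;
complement fragments shorter than half the motif length are boundary slack
(they cannot contain a full beat) and are dropped.

### PQRST delineation

QRS complexes are found on the first difference of the filtered signal: a
maximal positive slope followed within 0.10 s by a minimal negative slope,
both exceeding half the median of the ten largest slope-magnitude extrema
of their two-second stretch; the enclosed peak must also reach half the
tallest peak of that stretch (this rejects tall T waves) and R peaks
within a 0.2 s refractory period merge to the taller one.  Q and S are the
last/first local minima within 0.05 s around R.  The P peak is the voltage
maximum within 0.20 s (the upper normal PR bound) before Q, the T peak the
maximum within 0.38 s (upper normal QT bound minus lower normal QRS bound)
after S; wave onsets and ends are voltage minima within 0.06 s (half the
normal P-wave bound) of each peak.  Beats whose search windows would leave
the record are dropped: partial morphology cannot feed the beat
comparison.  The fiducials found on the cleanest lead are propagated
verbatim to every lead — no per-lead re-detection — which is exactly what
makes TP segments identifiable in heavily contaminated leads.

### Partial-DTW beat comparison

Unconstrained dynamic time warping between whole beats can align a P wave
with a QRS complex.  The beat distance is therefore the sum of three
independent DTW distances — P wave `[p_onset, p_end)`, PR segment
`[p_end, q)` and QT interval `[q, t_end)` — with squared pointwise cost,
steps {(1,1),(1,0),(0,1)} and no band.  Each segment is z-normalised per
beat (configurable) so the three terms are comparable across leads and
amplitudes.  We use the clinical PR *segment* (P end to QRS onset) as the
middle term; using the PR *interval* (P onset to QRS onset) would count
the P wave twice.

Per lead, a beat is flagged when its nearest-neighbour distance exceeds
`mean + sd` of the off-diagonal beat-pair distance population.  The
threshold population is a deliberate design choice: taking `mean + sd` of
the nearest-neighbour distances themselves looks natural but is
statistically untenable — among ~10 similar beats the largest
nearest-neighbour value exceeds the mean plus one standard deviation of
its own sample most of the time, so some normal beat would be flagged in
nearly every clean record.  Measured over 20 all-normal synthetic records,
the nearest-neighbour basis flagged at least one beat in all 20, the
pairwise basis in none; only the pairwise basis is consistent with a
detector whose false-alarm rate is supposed to be zero on clean data.
`threshold_on = "nearest"` remains available for comparison.

### Record-level result

A beat belongs to the motif period when at least half its span
`[p_onset, t_end)` is covered by motif member windows (the 50% rule also
decides what a shifted candidate may flag); the others are non-motif
candidates.  Candidate intervals are snapped to cycle anchors — start to
the nearest P onset, end to the nearest T end, equidistant ties to the
earlier anchor, inverted snaps falling outward to the enclosing beat.  The
record-level anomaly set is the union of distance-flagged beats across
leads (majority and cleanest-only combination rules are available) plus
the non-motif beats, reported as whole beat spans.  By construction a
detection can neither truncate a cycle nor bleed into a neighbour.

## Evaluation machinery

The overlapping ratio `|R ∩ D| / |R| * 100` compares a ground-truth
anomalous beat's morphology points R with the detected points D.  Overlap
criteria: at a 0% threshold a single overlapped point counts (strictly
positive ratio); 30/40/80% thresholds use `ratio >= t`.  The cardiologist
criterion demands that one detection covers the full morphology
`[m_s, m_e)` *and* stays within the beat bounds `[r_s, r_e)` (previous
T end to next P onset).  AoD is the mean overlap over real anomalous
beats, each paired with the union of detections touching it.  Confusion
counts are beat-level: an unmatched detection costs one false positive per
intersected normal beat (or a single one if it touches nothing);
sensitivity, specificity, PPV and false-alarm rate follow the usual
formulas, with zero-denominator rates reported as `NA` rather than 0 or
100.  `specificity + false_alarm_rate = 100` holds identically.

## The synthetic test bed

The generator is the package's ground-truth instrument, not a
physiological simulator.  Each beat is five Gaussian bumps (P, Q, R, S, T)
on a zero baseline; the default template fixes PR = 0.18 s, P width
0.12 s, QRS 0.08 s and QT 0.40 s, inside the standard clinical ranges.
Defaults: 63 bpm, RR jitter sd 0.02 s, per-beat amplitude CV 5%,
measurement noise 0.01 mV, 257 Hz, first R peak 0.15 s into the record so
excerpts begin and end mid-cycle as clinical strips do.  Leads differ by
gain; defaults are all positive because the delineator assumes a
dominant-positive R wave (inverted-lead delineation is a known
limitation).  PVC injection replaces one beat by a widened (1.5×), taller
(1.5×) QRS without a P wave and with an inverted T, relabelling the truth
with the PVC's own morphology bounds.  Artifacts are additive, local to
one lead and interval, and ramp with a raised-cosine envelope of up to
0.5 s per end — a step onset would be non-physical and its broadband edge
would dominate any band-pass residue.  The morphology mimic superimposes a
time-compressed, half-amplitude beat copy strictly inside a TP segment of
one lead, emulating artifacts that look cardiac; truth labels are
unchanged because it is not a beat.

What the generator does not emulate — and hence what green tests do not
show about real data: physiologic P/T morphology variation, respiratory
amplitude modulation, rhythm disturbances other than a replaced beat,
inverted leads, fused or consecutive ectopic beats, and recordings whose
artifacts overwhelm the morphology everywhere (on such "extremely noisy"
records the method is expected to degrade, as any morphology-based
detector does).

## Numerical choices and degenerate inputs

* All sample positions are 0-based, half-open `[start, end)`; 1-based
  indexing appears only inside R code, never in results.
* Argmax/argmin ties break to the earliest index; candidate-pair ties to
  the lexicographically smallest start pair; length ties to the shorter
  length; lead ties to the lower index; anchor ties to the earlier anchor.
* Constant windows z-normalise to the zero vector; a zero-length beat
  segment enters DTW as a single zero sample.
* The long-lead candidate search runs as a sliding dot-product scan over
  diagonals (O(n²) independent of window length) with an exact
  recomputation pass over near-maximal pairs, so its result matches the
  brute-force subsequence scan bit-for-bit on every tested instance.
* Motif discovery, and everything downstream, is deterministic: the only
  randomness in the package lives in the generator's seed.

## Problem sizes used in the test suite

Unit and acceptance tests run on 10–21 s records at 257 Hz with 1–12
leads, 20 seeds per property; the DTW oracle enumerates all warping paths
up to length 8; the motif oracle compares against an exhaustive pairwise
scan on leads of up to ~300 windows.  These sizes keep the whole suite in
the minutes range on one CPU while still exercising every pipeline stage
end to end.
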