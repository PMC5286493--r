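---
title: "Detecting QRS complexes with a Shannon energy envelope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting QRS complexes with a Shannon energy envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seeqrs)
```

## The detection problem

The QRS complex is the high-slope, high-amplitude deflection of each
heartbeat; its apex, the R-peak, anchors essentially every downstream ECG
measurement (heart rate, RR variability, ST analysis). Detecting it
reliably is hard for mundane reasons: QRS polarity and amplitude vary
between leads and patients, baseline wander moves the whole trace, tall
sharp T waves imitate beats, and powerline (48–60 Hz) and muscle
(38–45 Hz) noise ride on top of everything.

`seeqrs` implements an energy-envelope detector built around the Shannon
energy transform. The pipeline assumes only that QRS energy is
concentrated in roughly the 5–16 Hz band and that beats are at least a
refractory period apart; it makes no assumptions about polarity,
amplitude scale, or rhythm regularity.

## Pipeline

For one lead $x[n]$ sampled at $f_s$:

**Stage 1 — filter and normalize.** A Butterworth band-pass (defaults
5–16 Hz, analog prototype order 2) is applied forward and backward.
The double pass squares the magnitude response and cancels the phase,
which matters because any phase delay would bias R-peak timing; edge
transients are controlled by even-reflection padding of at least three
filter lengths (up to 1 s when the signal allows). The filtered signal
is normalized by its maximum *absolute* value,
$a[n] = f[n] / \max_i |f[i]|$. Dividing by a signed maximum would let
$|a|$ exceed 1 whenever the dominant extremum is negative and make the
next stage's logarithm blow up, so the absolute value is a mathematical
necessity, not a stylistic choice. Normalization makes the detector
exactly scale-invariant — `detect_qrs` on $c \cdot x$ returns identical
indices for any $c > 0$, which the test suite asserts.

**Stage 2 — Shannon energy.** $s[n] = -a^2[n]\,\ln a^2[n]$, with
$0 \ln 0 := 0$ by continuity. On $[0, 1]$ this transform vanishes at
both ends and peaks at $1/e$ for $|a| = e^{-1/2}$: medium amplitudes are
boosted relative to the classic squared energy, while both small noise
and occasional large transients are compressed. It is even in $a$, so
negative-polarity QRS complexes produce the same energy as positive
ones. Zero samples are masked rather than offset by an epsilon, which
keeps $s = 0$ exact at $|a| \in \{0, 1\}$ and preserves the symmetry —
both are asserted analytically in the tests. The logarithm base is
natural by default; other bases only rescale $s$ by a constant that the
scale-aware threshold absorbs, and `detector_config(log_base =)` exposes
them. The sequence is then z-standardized with the *population*
(divide-by-$N$) standard deviation: the formula standardizes one fully
realized signal, not a sample from a larger population, and the choice
is pinned by a test so it cannot drift silently.

**Stage 3 — envelope.** Two cascaded length-$L$ moving averages smooth
the standardized energy. A single boxcar merely flattens; the cascade is
an effective triangular kernel of support $2L-1$ that merges the
intra-QRS energy spikes into one lobe per beat. Each causal pass delays
by $(L-1)/2$ samples; the total delay of $L-1$ samples is removed by an
integer left shift so the envelope lobes stay on top of their beats —
without this compensation every detection would lag by about $L$
samples. Before the cascade the signal is extended by even reflection
and trimmed afterwards, so a constant input yields an exactly flat
envelope and beats near the record edges are smoothed symmetrically
(`moving_average` itself keeps the plain zero-prefilled causal contract,
which its unit tests pin down). Candidate peaks are indices where the
envelope difference changes sign from positive to non-positive —
strict local maxima, with flat tops resolved deterministically to their
leftmost sample.

The default $L$ is 100 ms ($L = \lfloor 0.10 f_s \rceil$ samples). That
window spans a full QRS complex, so its energy spikes merge, but is well
below the minimum beat separation (250 ms at the 240 bpm physiological
ceiling), so adjacent beats keep separate lobes.

**Stage 4 — threshold, refractory, localization.** One global threshold
per lead gates the candidates:

$$
\theta =
\begin{cases}
\kappa\,\mu\,(1-\sigma^2) & \sigma < \mu\\
\kappa\,\sigma\,(1-\mu^2) & \text{otherwise,}
\end{cases}
$$

where $\mu$ and $\sigma$ summarize the smoothed envelope itself — the
threshold must share units with the values it gates, and at
$\sigma = \mu$ the two branches coincide, so the rule is continuous.
The constant $\kappa$ defaults to 0.5, the value selected by a grid
search maximizing F1 over the bundled synthetic scenario corpus at
default noise levels (on that corpus the optimum is a plateau: any
$\kappa$ between about 0.3 and 1.5 gives identical results). A greedy
left-to-right refractory scan (default 200 ms) then suppresses double
detections, keeping the taller of two close candidates (ties keep the
earlier). Finally each accepted envelope peak is refined to
$\arg\max |f[n]|$ within ±100 ms, using the absolute value so
negative-polarity beats localize symmetrically; ties go leftmost and
refined indices are deduplicated.

## Evaluation harness

Detections and reference beats are matched one-to-one within a tolerance
window (default ±150 ms, the ANSI/AAMI EC57 convention). Matching is
initialized nearest-first — each reference takes its closest unmatched
detection — and then repaired by augmenting paths to a
maximum-cardinality matching. The repair step exists because pure
nearest-first matching is not always optimal: with references
$\{0, 6\}$, detections $\{5, 10\}$ and tolerance 5, nearest-first pairs
$6{-}5$ and strands both others, while the optimum pairs $0{-}5$ and
$6{-}10$. The tests verify optimality against brute-force enumeration on
random instances of up to 10 beats. Matched pairs are TP, unmatched
references FN, unmatched detections FP, and

$$\mathrm{Se} = \frac{TP}{TP+FN},\quad
{+}P = \frac{TP}{TP+FP},\quad
\mathrm{Acc} = \frac{TP}{TP+FN+FP},\quad
\mathrm{DER} = \frac{FP+FN}{TP},$$

each times 100. Values are kept at full precision internally and
rendered to three decimals (round-half-even) only at report output.
With $TP = 0$ and any errors present, DER is reported as infinite.
`run_reproduce_table()` recomputes all four percentages from every
TP/FN/FP triplet of the bundled published PTB evaluation table (72
records plus the reported total) and checks each reported cell at
3-decimal rendering; the reported total counts are not the column sums
of the per-record rows — an inconsistency in the source table — so rows
are verified independently and no column-sum identity is asserted.

## The synthetic generator

`generate_record()` builds each beat as a sum of five Gaussian bumps:

| wave | amplitude (mV) | offset from R (s) | FWHM (s) |
|------|---------------:|------------------:|---------:|
| P    |  0.15          | −0.200            | 0.060    |
| Q    | −0.10          | −0.025            | 0.025    |
| R    |  1.00          |  0.000            | 0.025    |
| S    | −0.20          |  0.025            | 0.025    |
| T    |  0.30          |  0.200            | 0.140    |

R centers are placed at RR intervals drawn from
$\mathcal N(60/\mathrm{HR},\ j \cdot 60/\mathrm{HR})$ truncated at
0.25 s (default jitter fraction $j = 0.02$), and the exact R-center
sample indices are returned as ground truth. Width means full width at
half maximum. The Q/R/S widths of 25 ms give the sharp ventricular
deflections; the T width of 140 ms (roughly 200 ms at the base) is the
physiological value and is also a load-bearing choice: a Gaussian T much
narrower than that carries 5–16 Hz energy comparable to the QRS itself,
at which point it is spectrally a second beat and no energy-band method
— this one or any other — can reject it. "Tall T" scenarios therefore
raise the T *amplitude* (to 0.8 × R via `t_over_r_ratio`), not its
sharpness beyond physiology.

Noise classes mirror what corrupts real recordings: a slow sinusoid for
baseline wander (default scenario level 0.2 mV at 0.3 Hz), a 48–60 Hz
sinusoid for powerline interference (0.05 mV at 50 Hz), white noise
band-passed to 38–45 Hz for muscle activity (0.05 mV SD), and broadband
white noise. All randomness flows from one explicit seed through a
local RNG scope, so records reproduce bit-for-bit and generation never
disturbs the caller's random stream.

`scenario_suite()` fixes eight named 60 s conditions (clean, the three
single-noise cases, tall-T, negative-QRS, irregular-RR with jitter 0.15,
and a low-SNR composite). The acceptance-level tests run the full
detector over this corpus and require perfect detection on the clean
scenario, ≥ 99% Se and +P on each single-noise scenario, zero false
positives at T locations in the tall-T scenario, and every detection
within 13 ms of its true R center on the clean and tall-T scenarios.

**What the generator does not emulate** — and hence what passing tests
do not show: real QRS morphology is not a Gaussian sum (no notching,
no bundle-branch shapes), T waves are symmetric here but skewed in
life, there are no ectopic beats, no electrode pop artifacts, no
amplitude modulation from respiration, and all scenarios are
single-lead. Corpus-level percentages on a real database depend on its
reference annotations and cannot be inferred from synthetic results;
the bundled published counts table is reproduced at the metric level
precisely because the underlying reference annotations are not public.

## Numerical and interface conventions

- Sample indices are 1-based everywhere (R convention), in memory and
  in annotation files; time $t$ maps to index
  $\lfloor t f_s \rfloor + 1$ and segments are half-open.
- Degenerate inputs fail loudly: all-zero leads, constant energy
  signals (zero variance), empty envelopes and zero-count metrics all
  raise typed errors rather than returning NaN.
- Thresholding is strict (`>`), candidate plateaus resolve leftmost,
  localization ties resolve leftmost, refractory ties keep the earlier
  candidate: every tie-break is deterministic, so identical input and
  configuration give bit-identical detections.
- The detector recomputes its threshold per lead and record; nothing is
  cached across calls.

## Problem sizes

The test suite and the acceptance script work at desk scale: 60-second
single-lead records at 1 kHz (60 beats at 60 bpm), eight scenarios per
suite, and brute-force oracles on instances of up to a few hundred
samples or 10 beats. These sizes exercise every code path — multi-minute
multi-lead records differ only in length.

## Known limitations

- The WFDB reader supports the common format 16 single-`.dat` layout
  (as used by 1 kHz diagnostic databases); other signal formats and
  multi-file records are rejected with a format error.
- One global threshold per lead assumes roughly stationary beat
  amplitude within a record; signals whose QRS amplitude drifts by
  orders of magnitude within one recording would need windowed
  re-estimation, which is out of scope.
- DER is unbounded above and undefined at $TP = 0$ (reported as
  infinity).
- The refractory rule imposes a 300 bpm ceiling at the default 200 ms;
  faster rhythms require reconfiguration.
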