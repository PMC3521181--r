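---
title: "Modeling palindrome-induced failure of sequencing-by-ligation"
author: "sblpal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling palindrome-induced failure of sequencing-by-ligation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sblpal)
```

## The phenomenon and the model

Sequencing-by-ligation reads a single-stranded template by hybridizing
short fluorescent probes and sealing them to the growing strand with
ligase. The chemistry therefore requires the template to be *accessible*
single-stranded DNA at the interrogated positions. A perfect palindrome —
a segment equal to its own reverse complement — can fold back on itself
into an intramolecular hairpin whose double-stranded stem excludes probes.
`sblpal` models the consequence as a *blocking window*: once the hairpin
stem is reached (in practice a couple of bases early, because the probe
footprint extends beyond the interrogated dinucleotide and the stem
breathes), ligation fails for the remainder of the read. Sequencing does
not recover downstream of the stem within a 35-bp read, so the window runs
from `palindrome start − blockLead` to the read end, not merely across the
palindrome.

Inside the window the simulator emits an i.i.d. uniform base over
{A, C, G, T} at exactly the floor quality value; outside it, the true
template base near the quality ceiling. This "garbage call at floor QV"
reading is one consistent interpretation of an instrument that keeps
producing calls after losing signal; the alternative (no call) would show
up as truncated reads rather than the observed random-sequence tail, and is
not modeled.

The reference system is a 61-bp ditag construct (18-bp Tag1, 26-bp central
palindrome, 17-bp Tag2). The palindrome is long enough (26 bp) to form a
stable stem at the sequencing temperature; the model takes hairpin
formation as certain above a minimum stem length rather than computing
folding energetics — the construct under study is far beyond any plausible
threshold, and a thermodynamic model would add parameters the data cannot
constrain. Sub-threshold palindromes (default `minStem = 16` bp, i.e. an
8-bp arm) are assumed not to block. That default is an assumption, not a
measurement: the data underlying the package involve only a 26-bp
palindrome, and readability as a function of stem length is expected to
decline with length but is not calibrated here.

## The interrogation schedule

Five primers, offset by one base each (start offsets 1, 0, 4, 3, 2),
interrogate a dinucleotide per ligation cycle and then leap three bases:
primer *p*, cycle *c* reads positions (s~p~ + 5(c−1), s~p~ + 5(c−1) + 1).
Position 0 is the final adaptor base; 7 cycles of 5 primers cover positions
0–35 with every interior template position read twice:

```{r schedule}
primerPositions(3, 3)
cov <- coverageMap(5, 7)
table(cov)
```

Color-space encoding (the standard rotation-invariant two-base code: the
color is the XOR of the 2-bit base codes, so identical pairs give 0,
A↔C/G↔T give 1, A↔G/C↔T give 2, A↔T/C↔G give 3) is provided for
completeness and for writing legacy csfasta, but the simulator emits
base-space reads directly: exact-call chemistry is modeled as perfect
color-to-base conversion, and no error-correction algorithmics are
implemented. The code matrix is overridable for non-standard instruments.

## Template generation

The construct is PCR-amplified (modeled as exact copying — no polymerase
error term, since none of the modeled observations is attributed to PCR)
between M13 primers and digested with *Mme*I. *Mme*I is a type IIS enzyme
cutting 18–20 nt downstream of its TCCGAC hexamer; the two hexamers sit
just inside the palindrome pointing outward, so digestion excises the
construct from its vector arms. Two modeling choices matter here:

* **Canonical cut distances.** The printed construct fixes the
  hexamer-to-end distances at 19 nt on the Tag1 side (the extra T plus the
  18-bp tag) and 18 nt on the Tag2 side, both within the enzyme's reach.
  `ditagTemplates()` therefore uses per-site cut offsets (19, 18) so that
  the zero-jitter fragment is exactly the 61-bp construct; `mmeiDigest()`
  exposes the offset as a per-site configuration value (default 18, the
  blunt post-end-repair distance).
* **Jitter.** End imprecision is additive-only, {0, +1, +2} per end, with
  default probabilities (0.6, 0.3, 0.1). The +2 cap matches the documented
  length variation; the probabilities are a free modeling choice (no
  published distribution exists) fixed once and exposed in the API. Under
  them the fragment length distribution is supported on 61–65 bp,
  consistent with a "~62 bp" gel band.

Both strands are emitted as templates with equal probability — ligation
sequencing reads whichever strand was captured — so libraries contain both
Tag1-led reads and Tag2-led reads (Tag2 in reverse-complement, as-sequenced
orientation).

## Quality and bead models

Tunable parameters (`SimParams()`), with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `readLength` | 35 bp | 7 cycles × 5 primers |
| `qvFloor` | 7 | instrument-defined baseline QV |
| `qvMax` | 34 | plausible ceiling; arbitrary, config-exposed |
| `qvDecayStart` | 4 positions | length of the pre-block decay ramp |
| `noiseRate` | 1 | Poisson rate of downward QV jitter outside the block |
| `blockLead` | 2 bp | blocking begins this far before the palindrome |
| `minStem` | 16 bp | minimum palindrome length that blocks |
| `pBadBase` / `pBadBlock` | 0.02 / 0.85 | bead-failure probability outside/inside the window |
| `pBestGivenOk` | 0.5 | best-vs-good split of non-failed beads |

The per-position QV target is `qvMax` on clean positions, ramps linearly
over the `qvDecayStart` positions before the block (the observed decline is
gradual, but no published per-position values exist to fit a shape, so the
simplest monotone ramp is used), and is *exactly* `qvFloor` inside the
window — which is why the mean in-block QV of any default simulation is 7
with zero variance, and why a QV cutoff of 8 masks the entire blocked
region while a cutoff of 7 or lower masks none of it.

Bead status is drawn independently per (primer, cycle) — no per-bead
persistence across cycles is modeled. The failure probability interpolates
between `pBadBase` and `pBadBlock` with a quadratic onset across the decay
region (weight ((p − onset + 1)/(d + 1))² for position p in the d-position
decay region, 1 inside the window, taking the worse of the two
interrogated positions). The quadratic shape encodes that probes begin to
clash with the breathing stem only close to it; with the default geometry
(palindrome at 19, window from 17, decay from 13) it places the *first*
good+best decline at exactly P3 cycle 3 (positions 14,15) and P4 cycle 3
(13,14), leaves P5 cycle 3 (12,13) above the 0.9 decline threshold, and
collapses every primer from cycle 4 — the observed run signature. A linear
onset would drag P5 cycle 3 below threshold as well.

## Downstream analyses

* **QC** (`runQc()`): filters in fixed order N → homopolymer → PCR primer →
  (optional) mean-QV, attributing each rejection to the first failing rule
  so that raw = qualified + Σ rejected always holds. The homopolymer rule
  is a run-length threshold (default 15 within a 35-bp read) and the primer
  rule a shared exact substring of ≥ 15 bp with any M13 primer or reverse
  complement — both thresholds are documented assumptions, since no
  published values exist. The QV cutoff has mask semantics by default
  (`applyQvCutoff()`: call → N where QV < cutoff, lengths and QVs
  untouched); whole-read rejection at mean QV < cutoff is available as an
  alternative (`dropReads = TRUE`).
* **Tag classification** (`classifyReads()`): anchored (zero-offset)
  Hamming match of the read prefix against Tag1 (18 bp) and as-read Tag2
  (17 bp), tolerance 1 mismatch by default ("exact or partial"); reads
  with extra 5' bases do not match by construction. If both tags match,
  the smaller distance wins and ties are unclassified. The false-match
  probability of a random 35-mer at tolerance 1 is below 10⁻⁷ per tag.
  Percentages in `statsTable()` are relative to qualified reads and
  half-up rounded to two decimals.
* **Profiling**: `perPositionQv()` uses the arithmetic mean (median would
  be equally defensible; the mean is the conventional per-base quality
  plot and is what the package documents). `detectBreakpoint()` returns
  the smallest position from which the mean profile stays within `eps`
  (default 0.25) of the floor — a suffix condition, robust to the decay
  ramp touching low values transiently, and monotone in `eps`.
  `firstDecline()` reports the earliest cycle in which any primer's
  good+best fraction drops below a threshold (default 0.9; a free choice,
  as no numeric fractions are published to calibrate against).

## What the generator does and does not emulate

The synthetic pipeline reproduces: near-homogeneous *Mme*I fragments with
≤ +2 bp end jitter, both template strands, 35-bp base-space reads under
the five-primer schedule, random-base/floor-QV emission from ~2 bp before
the palindrome, and per-(primer, cycle) bead-quality fractions that
collapse once interrogation enters the palindromic region. It does not
emulate: emulsion-PCR bead population dynamics, color-space basecalling
from raw intensities, sequence-dependent error biases outside the hairpin
mechanism, adaptor chemistry (the adaptor is only the position-0
convention), or partial hairpin recovery. Passing tests therefore show
that the analyses correctly expose the modeled mechanism, not that the
model captures every property of real ligation data; in particular, real
tag-containing fractions depend on how far blocking erodes the tag region,
which the model parameterizes (`blockLead`) rather than derives.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout the API (position 17 is the
17th template base) and converted to 0-based half-open only when writing
BED. N never pairs: any window containing N is non-palindromic, and
odd-length or empty input to `isPalindrome()` is FALSE, not an error.
Overlapping maximal palindromes are all reported, unmerged. Zero qualified
reads yield NA percentages rather than a division error; an empty read
stream yields an all-zero QC summary; an amplicon with fewer than two
cut sites yields an empty template set with a warning. All stochastic
steps take explicit seeds, and a fixed seed makes a simulation
bit-reproducible.

One inconsistency in the source material is recorded rather than resolved:
the construct's palindrome is described once as 24 bp, but the printed
26-mer verifies as a perfect palindrome and all coordinates in the package
follow it.

## Problem sizes

The shipped tests and the acceptance script use desk-scale runs chosen so
that binomial standard errors are far smaller than the effects asserted:
10⁴ reads for quality-profile and bead-ratio checks (SE of a 0.25
proportion ≈ 0.004), 4×10³ draws for jitter-frequency checks, and a few
hundred reads for I/O round-trips. The brute-force palindrome oracle is
run on sequences up to 200 bp, where its O(n³) cost is negligible.
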