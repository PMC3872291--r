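---
title: "Models and methods behind smybpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smybpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smybpc)
library(dplyr)
```

This vignette explains the models the package implements, the assumptions
they rest on, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## The splice grammar

*MYBPC1* comprises 33 exons. Nine of them vary across the 14 human
full-length variants: the frame-preserving cassettes 2–5 (11, 13, 12 and 11
residues — each exon's nucleotide count is exactly three times its residue
count, so inclusion never shifts the downstream frame), exon 10 (18
residues of the M-motif), exon 23 (19 residues inside FnIII domain C7), and
the terminal exons 31–33. The COOH-terminus is a four-state system driven
by exons 31 and 32:

| exon 31 | exon 32 | residues past C10 | stop codon in |
|---------|---------|-------------------|----------------|
| in      | in      | 19 + 7 = 26       | exon 32        |
| in      | out     | 19 + 16 = 35      | exon 33        |
| out     | in      | 3                 | exon 32        |
| out     | out     | 33                | exon 33        |

`resolve_tail()` is a total function over these four states, and the
grammar invariant "exon 33 carries coding sequence iff exon 32 is spliced
out" is enforced by `validate_pattern()` and at catalog load time.

Two modeling decisions here were open and are worth recording. First,
h-v012 is represented by `tss_truncation = 7` (an internal translation
start in exon 7) rather than as cassette skipping of exons 1–6: the variant
arises from an alternate start codon, so treating those exons as "spliced
out" would wrongly inflate the count of alternatively spliced exons.
Operations that need residue counts (`delta_aa`, `predict_mw`,
`calibrate`) refuse truncated patterns, because the truncated segment's
residue count is not part of the model; h-v012's 115.5 kDa is carried as
data only. Second, exon 33's dual coding/UTR role is one tri-state flag on
a single exon record, not two exon entries — the stop-codon table above
treats it as one element with alternate stop usage.

The packaged catalog holds exactly the 16 full-length records (14 human, 2
mouse). The two partially characterized mouse variants have no reported
inclusion row, mass or accession; the schema's `partial` flag exists for
them, and every counting and annotation operation either excludes or
refuses partial records.

## Annotation rules

All annotation is rule-based over exon presence; nothing is imputed.

- **Phosphorylation.** The mouse sites Ser-59/Ser-62 (PKA), Ser-83/Thr-84
  (PKC) and Ser-204 (PKA+PKC) map to human Ser-61, Thr-64, Ser-85 and
  Ser-206 (Thr-84 is mouse-only). The constitutive Pro/Ala sites require
  only that the Pro/Ala region is translated (h-v012 loses all of them);
  Ser-61/Ser-59 additionally requires exon 5 (unique to v1/v2); the
  M-motif site requires exon 10 (absent only in h-v8). Human sites are
  reported as *predicted*: human sMyBP-C phosphorylation has not been
  assayed, so the rules encode homology, not measurements.
- **Localization.** Both terminal exons retained → M-band periphery; exon
  32 only → A-band C-zone; the two remaining tail states (h-v5, h-v10) are
  reported `"unknown"`, never guessed.
- **Interaction.** Categorical classes only (no affinities are available):
  exons 2–5 complete → strong actin+myosin binding; exons 2–3 only →
  strong, competing with actin for the myosin head; exon 2 only → moderate,
  HMM-only; all other NH₂-termini unknown. LMM binding mirrors the
  localization rule (preferential / weak / unknown).

## The delta-mass model

Variant masses are predicted relative to an anchor:

$$\widehat{MW}(v) = MW_{\text{anchor}} + \Delta_{aa}(v, \text{anchor})
\cdot \bar m,$$

rounded half-away-from-zero to 0.5 kDa. Parameters and defaults:

- `anchor_id = "h-v9"`, `anchor_mass = 126` kDa. h-v9 lacks all four
  NH₂-terminal cassettes, so every delta against it is a sum of known
  positive contributions — the anchor with the fewest uncertain terms.
- `mean_residue_mass = 0.110` kDa: the textbook average residue mass,
  constrained to the physical range [0.100, 0.120]. With this default the
  model reproduces all 13 non-truncated human reported masses to within
  ±0.5 kDa (and h-v013 exactly, at 129.5), which is the strongest check
  available — whether the reported masses came from full sequences or gel
  estimates is not stated in the source material.
- `rounding_step = 0.5` kDa, matching the precision of the reported masses.
  Half-away-from-zero is used everywhere a printed value had to be rounded,
  because it is the convention consistent with those printed values.

`calibrate()` fits $\bar m$ by least squares through the anchor
($\hat{\bar m} = \sum_i \Delta_i y_i / \sum_i \Delta_i^2$ with
$y_i = MW_i - MW_{\text{anchor}}$); on the packaged catalog it lands at
0.1140 kDa/residue, inside the physical range, with a maximum residual of
~0.5 kDa. Predictions are anchor-independent to within one rounding step.

The six molecular-weight groups (1: v1/v5/v202, 131–131.5 kDa; 2:
v2/v6/v013, 129–129.5; 3: v3/v7/v10, 128; 4: v8/v002, 127–127.5; 5: v4/v9,
126–126.5; 6: v012, 115.5) use centers equal to the arithmetic mean of the
members' reported masses: 131.33, 129.17, 128.0, 127.25, 126.25 and 115.5
kDa. `assign_group()` takes the nearest center, refuses assignments farther
than `tolerance = 1.5` kDa (neighboring centers are ~1 kDa apart, so 1.5
accepts any plausible band without reaching across the window), and flags a
band `ambiguous` when the two best distances differ by less than
`margin = 0.5` kDa.

## Gel sizing

Band sizing is the standard semilog model: ordinary least squares of
$\log_{10}(MW)$ on relative migration (Rf, 0 at the well, 1 at the dye
front), inverted to size unknown bands. A logistic migration model was
considered and rejected: the bands of interest span only 115–132 kDa, a
window narrow enough that log-linearity holds and the extra logistic
parameters would be unidentifiable from a six-marker ladder. Preconditions
are enforced (≥3 markers, strict monotonicity); Rf values outside the
calibrated marker range by more than 0.05 trigger an extrapolation warning
rather than an error.

Within a lane, bands that size to within `merge_within = 0.25` kDa of each
other are merged before assignment — half the 0.5 kDa reporting precision,
i.e. the resolution floor below which two bands cannot be meaningfully
distinct. Lanes are processed independently; no cross-lane normalization is
attempted (loading across the published fibers was reported similar, and
the pipeline starts from migration tables, not intensities).

## The synthetic generator

The generator serves two distinct purposes.

**Deterministic reconstruction** (`generate_fixture()`): the published
soleus (48 fibers, 13 patterns) and FDB (41 fibers, 5 patterns) datasets
are reconstructed from their printed pattern percentages. Printed "~"
percentages are rounded values, so they are treated as targets, not
constraints: `solve_integer_counts()` finds, by exact dynamic programming,
the integer count vector summing to the fiber total that minimizes the
maximum percent deviation (ties: minimum L1, then lexicographically
smallest). For FDB (39/32/17/7/5% of 41) this certifies counts
16/13/7/3/2; for soleus the optimum deviation is 0.5 points (the 12%
pattern realizes 12.5%). Fixture bands are placed noiselessly at each
group center's exact Rf, so the fixture → pipeline → tally round trip is
an identity and never flakes.

One printed inconsistency had to be adjudicated: the published correlation
table lists myosin "I" for the soleus single-group patterns {2} and {3},
but the published percentages only cohere if those two patterns belong to
the I+IIa class (10+4+40+12+6+4+6 = 82%, matching the stated ~82%, with
the remaining patterns summing to 16% ≈ the stated 18% I-only share). The
preset follows the percentages; `myosin_association()` keeps the table
verbatim as its reference and flags exactly those two rows as mismatches,
so the discrepancy is surfaced in output rather than silently resolved.
Recomputed totals are reported next to the printed ones throughout: the
reconstruction realizes 72.9% two-group fibers (printed "~74", per-pattern
figures sum to 72) and 83.3% I+IIa fibers (printed "~82").

**Stochastic simulation** (`simulate_gel()`): fibers are sampled from the
count-normalized pattern frequencies and each band's Rf is its group
center's Rf plus Gaussian noise, `rf_noise_sd = 0.002` by default. The
default gel places the 250 kDa marker at Rf 0 and the 50 kDa marker at Rf
1 — the flattest gel that fits this ladder in the unit Rf range — so the
noise corresponds to ~0.4 kDa of sizing uncertainty at 128 kDa. All
randomness flows through the single `seed` argument; a fixed seed gives
byte-identical output.

What the simulation does *not* emulate: band intensities and antibody
affinity, loading differences between fibers, blot-image artifacts, and
replicate lane structure (one lane per fiber is assumed). Passing recovery
tests therefore demonstrates that the sizing-and-assignment arithmetic is
unbiased under Gaussian migration noise — not that the pipeline is robust
to densitometric or staining pathologies, which are out of scope.

## Numerical behavior at the default noise

Group centers 3 (128.0) and 4 (127.25) sit 0.75 kDa apart while the
sizing noise is ~0.41 kDa, so a few percent of bands generated at those
centers necessarily land nearer the neighboring center: with
soleus-frequency weighting, strict nearest-center accuracy is ~95%, and
essentially all residual errors occur inside the 0.5 kDa ambiguity margin,
where assignments are flagged rather than trusted. Confident (unflagged)
misassignment is below 2%. The recovery tests encode exactly this:
strict accuracy ≥ 90%, correct-or-flagged ≥ 95% over 1,000 simulated
bands, every generating pattern frequency within 3 binomial standard
errors at n = 500, and a mean absolute group-occurrence error under 2
percentage points across seeds 1–20 — sizes chosen so the whole suite runs
in seconds while the binomial standard errors are still tight enough to
detect bias.

## Degenerate inputs and edge behavior

- Empty catalogs, empty lanes, empty fiber tables: empty tibbles, never
  errors.
- `calibrate()` refuses single-variant and all-identical-pattern catalogs
  (underdetermined / degenerate design).
- Percent distributions that must sum to 100 (group multiplicity) are
  reconciled by the largest-remainder method; per-pattern percentages are
  rounded half-away-from-zero independently and may not sum to 100, which
  mirrors how the published figures behave.
- Fibers with no assignable band are dropped from every denominator;
  unstained lanes are excluded from myosin association with their count
  reported.

## Known limitations

- Amino-acid sequences are not modeled; every residue count is exon
  arithmetic. Consequently nothing can be said about h-v012's truncated
  segment, or about sequence-level identity questions between variants.
- The interaction and localization calls are categorical rules transcribed
  from qualitative findings; they carry no uncertainty and should not be
  read as measurements.
- The mass model ignores post-translational mass shifts; it predicts
  migration-relevant size only as well as the average-residue-mass
  approximation allows (±0.5 kDa here).
- The counts of "fifteen" (human) and "seven" (mouse) splicing *events*
  reported in the source material depend on a definition of "event" that
  is not stated; no operation reproduces those two numbers.
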