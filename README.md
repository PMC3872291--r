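# smybpc

Slow Myosin Binding Protein-C (sMyBP-C), encoded by the single *MYBPC1*
gene, is not one protein but a family of proteoforms: alternative splicing
at the 5′ and 3′ ends of the transcript produces 14 known human and 2
full-length mouse variants that differ by short unique segments in the
Pro/Ala-rich NH₂-terminus (cassette exons 2–5), the M-motif (exon 10),
FnIII domain C7 (exon 23) and the COOH-terminal tail (exons 31–33). Because
the variants run within ~1 kDa of each other on a gel, single-fiber western
blots can only resolve *groups* of candidate variants by molecular weight —
and the question of which groups a given muscle fiber co-expresses has to
be answered through careful band sizing and tallying.

`smybpc` implements that entire analysis as a tested R package, for muscle
biologists and anyone working with exon-level proteoform catalogs:

- **Variant catalog** — a machine-readable table of the 16 full-length
  variants with their exon-inclusion patterns, reported molecular weights
  and accessions, plus the splice grammar: frame-preserving cassette logic,
  the four-state COOH-terminal tail (`resolve_tail()`), NH₂-terminal
  combination counting and the set of alternatively spliced exons.
- **Proteoform annotation** — rule-based prediction of phosphorylation-site
  complements (PKA/PKC sites in the Pro/Ala region and M-motif), sarcomeric
  localization (A-band C-zone vs M-band periphery from the exon 31/32
  state) and categorical actomyosin/LMM interaction classes.
- **Delta-mass model** — predicts each variant's molecular weight from its
  exon composition relative to an anchor variant (default h-v9 at 126 kDa):

  `MW(v) = MW(anchor) + Δaa(v, anchor) × m̄`,

  with `m̄ = 0.110` kDa per residue and half-away-from-zero rounding to
  0.5 kDa; `calibrate()` fits `m̄` by least squares against the reported
  masses. The model partitions the variants into the six standard MW groups
  (group 1, 131–131.5 kDa … group 6, 115.5 kDa).
- **Gel pipeline** — ladder-calibrated SDS-PAGE sizing
  (`log₁₀(MW) = a + b·Rf`, ordinary least squares), band-to-group
  assignment with ambiguity flagging, and per-lane collapse to fiber group
  sets.
- **Fiber profiling** — expression-pattern tallies, group-multiplicity and
  group-occurrence distributions, and association of patterns with myosin
  heavy-chain complements (I/IIa/IIx) against the published reference table.
- **Synthetic data** — deterministic reconstructions of the published
  48-fiber soleus and 41-fiber FDB datasets from their printed pattern
  frequencies (an exact integer-apportionment solver turns rounded percents
  into counts), and seeded noisy-gel simulation with ground truth for
  recovery testing.

## Worked example

```r
library(smybpc)
library(dplyr)

catalog <- mybpc_catalog()
nrow(catalog)                              # 16 variants (14 human, 2 mouse)
nrow(nterm_combination_set(catalog))       # 7 NH2-terminal combinations
alternative_exons(catalog)                 # 2 3 4 5 10 23 31 32 33

# predicted vs reported molecular weights
predict_mw(catalog) |>
  left_join(select(catalog, id, printed_mw_kda), by = "id") |>
  head(3)
#> # A tibble: 3 × 4
#>   id    delta_aa predicted_mw_kda printed_mw_kda
#>   <chr>    <int>            <dbl>          <dbl>
#> 1 h-v1        47            131            131.5
#> 2 h-v2        24            128.5          129
#> 3 h-v3        20            128            128

# rebuild the soleus single-fiber dataset and push it through the gel
# pipeline: standard curve -> band sizing -> group assignment -> tallies
soleus <- generate_fixture(frequency_preset("soleus"))
fibers <- profile_gel(soleus)
tally_patterns(fibers) |> head(3)
#> # A tibble: 3 × 4
#>   groups n_groups count percent
#>   <chr>     <int> <int>   <dbl>
#> 1 1,6           2    19      40
#> 2 2,6           2     6      13
#> 3 2             1     5      10

multiplicity_distribution(fibers)
#> # A tibble: 3 × 4
#>   n_groups count percent raw_percent
#>      <int> <int>   <int>       <dbl>
#> 1        1    10      21       20.8
#> 2        2    35      73       72.9
#> 3        3     3       6        6.25
```

The dominant soleus pattern is the co-expression of group 1 (v1/v5/v202)
with group 6 (v012) at 40% of fibers, and about 73% of fibers express
variants from two groups — the pipeline recovers the published picture
exactly from the reconstructed band tables. `fit_standard_curve()`,
`assign_bands()` and `myosin_association()` expose the individual steps;
`autoplot()` and the `plot_*()` helpers draw the standard curve and the
distributions.

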