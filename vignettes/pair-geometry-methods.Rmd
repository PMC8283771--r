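---
title: "Base-pair geometry of snRNA:splice-site recognition — methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pair geometry of snRNA:splice-site recognition — methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicepairs)
```

## The model

Human splice sites are only weakly conserved — apart from the intron
termini and the branchpoint, only the exon-end guanine (−1G, ~82%),
the intron +5 guanine (~80%) and a handful of other positions exceed 75%
conservation — yet splicing stays precise. The hypothesis implemented
here is that precision is enforced cooperatively in the pre-catalytic
spliceosome by the *geometry* of the base pairs that snRNA recognition
loops form with their binding sites. Every ordered pair of RNA bases is
assigned to one of three classes:

* **Watson–Crick**: G=C/C=G and A-U/U-A;
* **isosteric**: G-U/U-G, U-U, C-U/U-C and A-C/C-A — mismatches that can
  adopt Watson–Crick-like geometry through rare tautomers or
  protonation, and therefore do not distort an A-form helix;
* **non-isosteric**: the purine–purine pairs and C-C, which cannot.

The three sets partition the 16 ordered pairs 4/7/5. Because uracil
forms Watson–Crick or isosteric pairs with *every* base, uracil-rich
loops (U5 snRNA Loop1; the homologous Id3 loop of the group IIA Ll.LtrB
intron) are natural semi-specific recognition elements: Watson–Crick
pairs are selected for, isosteric pairs are tolerated, non-isosteric
pairs are excluded. Base modifications (pseudouridine, 2′-O-methyl,
N6-methyl) are carried as annotations but never change the class: Ψ43
pairs as an ordinary U.

Loop models bundle the residues with a *pairing map* from substrate
positions to loop positions. The default U5 Loop1 map is the proposed
fixed binding register that places the exon junction at loop C39|C38:
exon −1..−8 against loop 39..46 and exon +1..+3 against 38..36, so the
conserved exon-end G forms G=C with C39. The default U6 map pairs
intron +5..+10 with positions 42..37 of the ACAGAGA box; the U1 map
covers exon −3..−1 and intron +1..+8. Loop residues 45–46 of U5 are not
printed in machine-readable form anywhere we could consume; the
defaults (A, C) are forced by internal consistency — exactly five
uracils in the loop, and uridine partners exactly at exon −2..−6, the
five positions where non-isosteric pairs cannot occur — and are
constructor arguments, not constants. The same applies to the Id3 loop
default, which is a documented reconstruction.

## Register scanning

The pilot procedure scores a 15-nt window (last 10 nt of upstream
sequence + first 5 nt of downstream sequence, boundary declared at
10|11) against an 11-nt loop in the five registers that keep the 5′-side
helix at least as long as the 3′-side (splits 6+5 … 10+1). Registers are
ranked by Watson–Crick count only; ties are *reported, never broken*,
because multi-register fits are themselves a result. The grid's
mismatch-preference order (WC, then G-U/U-G, U-U, C-U/U-C) is recorded
as a secondary score vector but deliberately excluded from the choice;
whether it was ever used as a manual tiebreaker is unknowable from the
published record, so the engine exposes both views and commits to
neither.

## Dataset construction

`extract_splice_elements()` slices, per intron: the 11-nt junction
(8 nt of 5′-exon end + 3 nt of 3′-exon start), the 10-nt intron start
and the 60-nt intron end. Annotation input is 1-based inclusive (GTF
convention); minus-strand transcripts are reverse-complemented before
slicing; one isoform per gene is kept (maximum exon count, ties broken
lexicographically by transcript id). Introns are routed to `minor` when
positions +3..+8 match the U12-type core (default motif `ATCCTT`,
configurable — the published rule is stated only as a U6atac-motif
criterion), to `atypical_plus2` when +2 ≠ U, and to `major` for GT…AG
termini. The 5′-site partitions (`plus5G`, `minus1G`) admit only major
introns; the 3′-site partition (`minus3C`) also admits the
+2-substituted atypical introns, which are processed by the same
spliceosome. Introns shorter than 60 nt keep their whole sequence as
the end fragment and are flagged; only positions −1..−6 of the end are
ever consumed. Exons too short for their flank yield `N`-padded,
flagged records that every analysis drops with a message (or are
skipped at extraction, per configuration).

## Statistics

**sKL divergence.** Distributions of pair classes over a *subsite*
(exon −8..−6, −5..−3, −2..−1, +1..+3 for U5; dinucleotides +5/+6, +7/+8,
+9/+10 for U6) are compared with the symmetrized Kullback–Leibler
divergence, with an increment of 0.0001 added to every probability —
without renormalization — to avoid division by zero. Because the two
natural groups are unequal (e.g. ~445 substituted vs ~1545 conserved),
the "no difference" baseline is resampled: each of 10,000 iterations
draws two *disjoint* subsets of the case-set size from the reference
set (indices sampled without replacement; one subset pair is reused
across subsites) and records control (subset vs subset) and case
(subset vs case set) divergences. Sequence-level deduplication is *not*
applied: "non-redundant" is interpreted at the record-index level. The
per-subsite summary is the ratio of mean case to mean control sKL. Note
that with a single fixed case set this ratio inherits the case set's own
sampling deviation; under the null it is centred near 1 only on average
over case draws, which is how the test suite checks it.

**Bootstrap differences.** For each defined (position, class) cell,
both groups are resampled with replacement at their own sizes, and the
difference of resampled frequencies (BD) is recorded over 10,000
iterations. `P(H0)` is the smaller tail of the BD distribution beyond
zero, with ties (BD = 0) counted in both tails before the minimum — at
10,000 iterations this affects the value by at most ~1e-4, but on
degenerate inputs it can push `P(H0)` above 0.5, which we accept rather
than hide. Under the null `P(H0)` is approximately uniform on [0, 0.5],
so rejecting at `P(H0) < α` has type-I error ≈ 2α; the package therefore
also reports the calibrated two-sided p-value `2·P(H0)`. Threshold
comparisons against Dunn-corrected α′ use `P(H0)` directly, matching the
published convention; calibration claims are made on the two-sided
p-value. Cells whose class cannot occur (uridine partners) are marked
undefined and never tested. The same machinery applied to the four
nucleotide frequencies at one position (`nucleotide_bootstrap()`, used
at exon −3) separates U5's preference (A, pairing Um41) from U1's
(C, pairing G11).

Resampling is implemented as multinomial weight vectors multiplied into
per-record indicator matrices, in chunks of 1000 iterations, which keeps
a 10,000-iteration run over ~2000 records well under a second without
changing the record-level resampling semantics; within each iteration
class frequencies at a position sum to 1 by construction.

**Multiple testing.** Dunn's α-splitting gives α′ = α/m. Because the
class frequencies at one position sum to 1, the per-position tests are
strongly correlated, and the effective count per group of m correlated
tests with interclass correlation R is m′ = (m+1) − [1 + (m−1)R],
rounded to the nearest integer per group and summed (the per-group
rounding is required to reproduce the published counts). Defaults:
R = 1 for two tests, 0.5 for three, 0.33 for four. The U6 map (five
three-class positions + one uridine partner) gives m = 17, m′ = 11; the
U5 map (six + five) gives m = 28, m′ = 17; appending the four
nucleotide tests at exon −3 gives m = 32, m′ = 20. The published count
of m = 31 for the 5′-site experiment is not derivable from the 28-cell
structure that yields the other experiments' counts; the plan builder
exposes both countings (with and without the appended nucleotide group)
and hard-codes neither — the adjusted values m′ = 20 and α′ = 0.0025
agree either way.

## The synthetic generator

`generate_dataset()` draws records from positional nucleotide vectors
(GT/AG termini enforced; the intron end beyond −6 filled i.i.d. from a
pyrimidine-rich background). The default vectors are configuration
data approximating the human consensus qualitatively, anchored at the
marginals the analysis depends on: P(−1G) = 0.82, P(+5G) = 0.80,
P(exon +1 G) = 0.50, P(−3C) = 0.61, +6U below 0.5, +1A ≈ twice +1U.
Dependencies are injected by a mixture construction: the intron
position is drawn first, and the exon-side Watson–Crick-forming
nucleotide mass is shifted conditionally so that
P(−1G | +5 substituted) − P(−1G | +5G) equals `delta_5ss` exactly while
the marginal is preserved (likewise `delta_3ss` between intron −3 and
exon +1). With deltas 0, exon and intron positions are independent by
construction.

What the generator does *not* emulate: branchpoint sequences, GC
content heterogeneity, linkage beyond the two configured dependencies,
duplicate junction sequences, alternative isoforms, and any length
distribution of real introns. Passing calibration and recovery tests
therefore demonstrates that the statistical machinery is correct and
adequately powered at realistic sizes and effect strengths — not that
any particular biological effect exists in real transcriptomes.

## Problem sizes and numerical choices

The test suite runs the calibration study as 200 replicate null
experiments at group sizes 445/1545 with 1000 bootstrap iterations, and
the recovery study as 100 reruns at ~380/1520 (a +5G split of 1900
records) with an injected delta of 0.15 — sizes chosen to mirror the
real partition sizes while keeping a full run of the suite within a few
minutes; production analyses default to 10,000 iterations. Type-I
calibration is asserted within 3 binomial standard deviations of
nominal α at α ∈ {0.05, 0.01}; recovery requires the exon −1
Watson–Crick cell to beat the Dunn-adjusted threshold (0.0025) in at
least 95 of 100 reruns while the untouched 3′-exon cells stay at their
null rate. Every stochastic function takes an explicit seed and records
it, with the subset sizes and iteration counts, in its result's
provenance block; orchestrated stages derive their seeds from the
experiment seed by fixed offsets so each stage is independently
reproducible.

Degenerate inputs are handled explicitly rather than silently: empty
datasets and empty partitions are rejections; truncated records are
dropped with a count; zero-variance PSI groups return descriptive
summaries with the undefined test set to `NULL`; `P(H0)` above 0.5 on
tie-dominated cells is documented behaviour.

## Worked example

```{r example}
model <- site_frequency_model(delta_5ss = 0.15)
ds <- generate_dataset(model, 1900, seed = 1)
exp5 <- run_substitution_experiment(ds, "plus5G", iterations = 1000,
                                    seed = 1)
exp5
```

The exon −1 Watson–Crick cell is flagged at the adjusted threshold;
3′-exon cells are not — the qualitative contrast the pipeline is built
to detect.

## Known limitations

* The Id3 loop default sequence and U5 45–46 are reconstructions (see
  above); analyses that depend on them accept overrides.
* The published exclusion lists for minor/atypical introns are not
  machine-readable; the motif rule here is a stated approximation and
  classification is configurable.
* PSI values for three of the fourteen +1G mutations are not printed in
  any source available to the package and ship as `NA`; the group
  comparison drops them with a notice.
* The sKL mean-ratio for a single fixed case set is a noisy summary (by
  construction); treat per-subsite ratios comparatively, not as
  calibrated statistics.
* No energy or thermodynamic scoring, no tautomer enumeration, no 3D
  geometry: the classification is a static geometric partition.
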