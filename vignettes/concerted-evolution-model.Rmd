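---
title: "Modelling concerted evolution of an rDNA tandem array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling concerted evolution of an rDNA tandem array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaconcert)
```

## The biological problem

The ribosomal RNA cistron occurs in large head-to-tail tandem arrays —
around 120 to 130 copies per cell in the fungus this package models,
*Ceratocystis manginecans*. Despite that multiplicity, the copies stay
nearly sequence-identical: mutations do not accumulate independently per
copy but are either spread to all copies or purged, a pattern called
concerted evolution. The two mechanisms usually invoked are **unequal
crossing over** (homologous recombination between misaligned repeats, which
changes copy number) and **gene conversion** (non-reciprocal transfer of a
tract between duplexes, which does not).

*C. manginecans* is haploid and homothallic: a single isolate completes
both the mitotic (hyphal growth) and the meiotic (selfed sexual) cycle on
an identical genetic background. Some isolates carry two distinguishable
ITS sequence variants, labelled Z and Y, inside one array. Following the
Z:Y ratio of cloned ITS amplicons through sequential vegetative transfers
and through single-ascospore sexual generations turns those isolates into a
natural experiment on how fast, and during which life stage, the array is
re-homogenized. This package re-creates that experiment end to end *in
silico*: the array model and event simulator, the PCR-RFLP clone typing
used to score the variants, the replicated chi-square / Fisher combination
statistics, and the minimum-division combinatorics that bound how quickly a
ratio can change.

## The array model and the event simulator

An array is an ordered sequence of unit labels (`repeat_array()`); order
matters because crossover outcomes depend on breakpoint positions.
A division replicates the array into two sister chromatids and applies:

* `Poisson(crossover_rate)` unequal exchanges at breakpoints drawn
  independently and uniformly over positions `0..length` of each chromatid
  (no homology-weighted alignment preference — nothing in the data
  constrains one). Each exchange is reciprocal with probability
  `reciprocal_fraction`; a reciprocal exchange swaps the flanks and
  conserves the combined composition exactly, while a non-reciprocal
  exchange replaces a coin-flipped recipient with the single recombinant
  and leaves the donor intact, so copies can be gained or lost.
* `Poisson(conversion_rate)` gene conversions of geometric-like tract
  length (mean `conversion_tract`, default 3 units — conversion tracts span
  one to a few repeat units), overwriting the recipient in place.

Each daughter receives one product. Viability selection culls extreme copy
numbers: daughters outside `[n_min, n_max]` trigger either a redraw of the
whole event set (`"resample"`, the default — selection without lineage
death) or death of that daughter (`"death"`). The defaults `n_min = 12`
(the copy number an extreme single-division reduction would need, and a
plausible floor for rRNA supply) and `n_max = 600` are deliberately wide.

The life cycle wraps this division kernel three ways:

* `hyphal_tip_transfer()` — a sub-culture transfer is one mitotic lineage:
  `divisions_per_transfer` successive divisions (default 20 for a two-week
  culture; no nuclear-division count is measurable from the study design,
  so this is a sensitivity parameter, not a truth), keeping one uniformly
  chosen daughter each time.
* `meiotic_ascospores()` — homothallic selfing pairs two identical copies
  of the parent array, then three division rounds (meiosis I, meiosis II,
  and the post-meiotic mitosis) produce exactly eight ascospores. Because
  the homologs of a selfer are sequence-identical, inter-homolog and
  sister-chromatid exchange are statistically the same process, and one
  event model serves all three rounds. Meiotic and mitotic rates are shared
  by default: the stronger meiotic signal can then only come from the three
  event-bearing divisions per spore, which is exactly the hypothesis the
  calibration experiment interrogates.
* `fixation_run()` — iterate a single lineage until the array is monotypic,
  the end state of homogenization.

With all rates zero every operation is the identity on composition; with
`reciprocal_fraction = 1` total copy number across products is conserved
exactly. Both are enforced as tests, as is the martingale property that
neutral exchange leaves the expected variant frequency unchanged.

## PCR-RFLP clone typing

Clone scoring digests a 920 bp cloned amplicon (646 bp ITS insert plus
vector flanks) and reads the fragment pattern: one cut at 460 gives the
460 bp doublet diagnostic of type Z; cuts at 525 and 860 give 525/335/60 bp
for type Y, with the 60 bp fragment below detection on a 3 % agarose gel
(`min_detectable = 100` bp). `find_sites()` does IUPAC-aware forward-strand
pattern matching (the default pattern `ACGT` is palindromic, making
strandedness moot), `digest()` turns cut coordinates into fragment sizes
(0-based cuts, half-open intervals, left-to-right order), and
`score_clone()` matches observed against expected fragment multisets with a
20 bp gel-sizing tolerance, returning `"unknown"` on no match or ambiguity.
The enzyme's true recognition sequence is not recoverable from the printed
record, so the site is configurable and `make_amplicon_fixtures()`
engineers synthetic amplicons that place whatever pattern is chosen at
exactly the canonical cut coordinates (both cuts are placed inside the
insert; the printed record does not locate them relative to the vector).

## The statistical pipeline

For each (isolate, stage) series of `n` transfers with `k` scored clones
each, `chisq_gof()` accumulates `sum((O - E)^2 / E)` over transfers and
both types, with expected counts from the isolate's baseline type-Z
frequency. Two degrees-of-freedom conventions are exposed:

* `"study"` — `df = n - 1 = 4`, the convention under which the published
  tables were computed; the default for reproduction work.
* `"orthodox"` — `df = n (types - 1) = 5`, the standard convention for `n`
  independent binomial observations. This is the convention under which the
  test is actually calibrated, and the one the type-I-error checks use.

Per stage, the four per-isolate tail probabilities are combined with
Fisher's method (`fisher_combine()`): `-2 * sum(log p)` on `2k = 8` degrees
of freedom, with an underflow floor of `1e-300` before the log.
Significance is a strict comparison against `chisq_critical(alpha, df)`;
the published tables use `alpha = 0.01` (critical value 13.28 at df 4)
while describing it as a "99.999 % level of confidence", so reports always
state the alpha actually applied.

`reproduce_tables()` recomputes every downstream transform of the printed
per-isolate statistics. Two printed probabilities are not reproducible from
the df-4 tail: 0.010 for the statistic 18.34 (the tail gives 1.059e-3) and
0.7155 for 2.21 (0.6972). They are flagged `WARN` in the report and fed
into the combination exactly as printed — which is what reproduces the
published combined statistics 68.726 (meiosis) and 24.482 (mitosis) — never
silently corrected. The summary and combination tables also disagree on one
statistic (11.99 vs 11.98 for one mitotic series); both values are kept as
printed in their respective tables.

```{r reproduce}
reproduce_tables()
```

## Synthetic data: what it emulates and what it does not

`generate_null_dataset()` draws every observation binomially from the
isolate's fixed baseline frequency: the no-drift null with pure
clone-sampling noise. `generate_drift_dataset()` instead evolves a founder
array (125 units at the designed baseline frequency, random unit
arrangement) through the simulator and samples clones from the current true
composition, returning the true trajectories alongside the counts.

Design choices worth knowing:

* **Baseline records are deterministic** (`round(freq * k)`), i.e. the
  original isolate's composition is treated as known. If baselines were
  themselves sampled, the expected frequency fed to the test would be
  noisy and the null calibration below would not hold at nominal alpha.
* **Clone sampling is binomial by default**: PCR amplifies the ~125 copies
  into a vast pool before cloning, so clones are effectively draws with
  replacement from the copy frequencies. A hypergeometric mode (draws of
  physical copies without replacement) is provided for the alternative
  interpretation.
* **Meiotic observations default to fresh meioses** of the maintained
  culture, one spore scored per observation; `serial_meiosis = TRUE`
  passages spore-to-spore instead, modelling five sequential selfed
  generations. The distinction matters: under fresh sampling, meiotic
  deviations from baseline are independent (three divisions each) while the
  mitotic series accumulates a random walk, and the two stages end up with
  comparable detection rates. Under serial passaging the meiotic divergence
  accumulates at three divisions per generation versus one per vegetative
  transfer, and the meiosis-over-mitosis detection asymmetry — the
  qualitative signature the real experiment reported — is robustly
  expressed. The power-contrast test therefore runs serially, and
  `calibration_experiment()` exposes the switch.
* The generator does **not** emulate PCR or polymerase artefacts (the
  original workflow excluded them empirically), chromatogram noise,
  additional rare ITS variants (representable but off by default), or any
  chromosomal context beyond a single array locus. Passing tests on
  synthetic data therefore validate the statistical machinery and the
  internal consistency of the model — they cannot validate the biological
  rates, which are unknown; `crossover_rate = 0.05` per division is a
  deliberately conservative working default, config-exposed everywhere.

## Minimum-division combinatorics

How fast can a ratio change? If total copy number is constrained, a
variant's copy count can at most double per division (each copy replicates
once; a daughter is assembled from the two sisters), so moving from 5 to at
least 51 copies in a 60-copy array needs `ceil(log2(51/5)) = 4` divisions —
`min_divisions_constrained(5, 51, 60)`. Without a size restriction a single
unequal exchange can produce an arbitrarily short, variant-pure recombinant,
so any target *ratio* is reachable in one division
(`min_divisions_unconstrained()`). Note the ratio reading is essential: two
copies of a 55Z:5Y array contain only 10 Y copies in total, so no
single-exchange product can hold 51 Y copies — but a short product can
easily exceed the 51/60 Y *proportion*, which is what a clone ratio
measures. `reachable_compositions()` is the exhaustive per-division
enumeration of the copy-duplication rule, used as an oracle against the
closed forms on every small instance (totals up to 12, four divisions); it
is exponential by design and refuses large instances.

## Numerical and testing choices

* Chi-square tails and quantiles come from `stats::pchisq()`/`qchisq()`;
  the df-4 closed form `exp(-x/2)(1 + x/2)` is kept only as an independent
  cross-check in the tests.
* All stochastic operations consume the ambient R RNG; generators and
  pipeline entry points accept a seed and record it, making every table
  bit-reproducible from (design, params, seed).
* Monte-Carlo test scales were chosen to keep the default suite in a few
  minutes on one core: the fixation-martingale check runs 2000 lineages on
  8-unit arrays (the property is scale-free; small arrays keep the
  absorption-time tail short), type-I calibration uses 5000 series, the
  Fisher null-distribution check 5000 draws, and exact conservation is
  asserted on 100&nbsp;000 random exchange events.
* Boundary cases: a statistic exactly at the critical value is *not*
  significant; `detectable()` keeps fragments exactly at the threshold;
  an empty array is representable but non-viable; a single-transfer series
  under the `"study"` convention has `df = 0` and `p = NA` rather than a
  fabricated probability.

## Known limitations

Event rates are not estimated from data anywhere in the package — the
printed record contains no per-division information that would identify
them; the simulator is a forward model for calibration and power
exploration, not an inference engine. The `"study"` df convention is
reproduced faithfully but is anticonservative relative to the orthodox one
(df 4 instead of 5 for the same statistic); drawing fresh scientific
conclusions from it is not recommended. The minimum-division bound covers
the at-most-doubling growth law only; trajectory probabilities are the
simulator's job.
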