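---
title: "Deep indel mutagenesis atlases of amyloid nucleation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep indel mutagenesis atlases of amyloid nucleation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimatlas)
```

## The experiment this package models

Deep indel mutagenesis (DIM) extends deep mutational scanning beyond amino-acid
substitutions: a designed library covering substitutions, single-residue
insertions, single and multi-residue deletions, and truncations of a peptide is
expressed in a cellular selection assay, where each variant's abundance before
and after selection is read out by amplicon sequencing. For the 42-residue
amyloid beta peptide (Abeta42) the selection couples growth to amyloid
nucleation, so the relative enrichment of a variant measures how strongly it
promotes or impairs fibril nucleation — the *nucleation score* (NS).

`dimatlas` implements that pipeline end to end: library enumeration and
canonicalization, a generative simulator of the selection assay, read-level
quantification, score estimation with replicate error models and FDR
classification, and the downstream atlas analyses (regional frequencies,
deletion hotspot detection, alternative aliphatic cores, truncation series,
ROC against disease labels).

## The designed library and canonicalization

For a wild type of length $L$ the library contains:

* all $19L$ substitutions (798 for Abeta42);
* single insertions at every gap, $20(L+1)$ raw specs;
* single deletions at every position and every internal multi-residue
  deletion $[s, e]$ with $2 \le s \le e \le L-1$ and length 2–39;
* all truncations removing $a$ N-terminal and $b$ C-terminal residues with
  $a + b \in [2, \min(39, L-3)]$, i.e. leaving 3 to $L-2$ residues.

Different mutations can yield the same protein product — deleting either of
two adjacent identical residues, or shifting a deletion window across a
repeat. `build_library()` collapses all specs by product string and assigns
exactly one class per unique sequence, with precedence: single-residue
removal > truncation > internal multi-deletion. This precedence is the one
that reproduces the published per-class counts for Abeta42 (37 single
deletions after collapsing five adjacent identical pairs, 817 truncations,
731 internal deletions, with exactly four internal deletion windows that
coincide with truncation products). Substitutions and insertions can never
collide with removal classes because their products differ in length.

One deliberate deviation from the published library description: the printed
insertion count (780) is not reproducible from any stated rule — full
enumeration over all 43 gaps dedupes to 818 unique products, while 780 would
correspond to a restricted gap range that the experimental description does
not specify. The gap range is therefore a configuration parameter whose
default is the complete enumeration; we report 818 and do not guess the
synthesis vendor's restriction.

Each variant also carries a nucleotide coding sequence under a configurable
one-codon-per-residue usage table (an E. coli-biased table by default) and,
for substitutions, the minimum number of nucleotide changes to reach the
variant from the wild-type sequence — needed by the input-read filter below.
The true synthesized nucleotide sequences are not published; any fixed,
consistently applied table serves, because the annotation only defines which
variants are reachable by a single nucleotide change.

## Scoring model

For variant $i$ in biological replicate $r$,

$$ES_{i,r} = \ln F_{i,r}^{\text{out}} - \ln F_{i,r}^{\text{in}}, \qquad
NS_{i,r} = ES_{i,r} - ES_{WT,r},$$

with $F$ the read frequency in the sample (technical replicates pooled by
summation within each biological replicate). Natural log is used throughout;
the published formulas write "log" without a base, and since NS only ever
enters relative comparisons the base is a unit choice, recorded in the score
table metadata.

Per-replicate errors use the Poisson delta method,
$\sigma^2 = 1/c^{\text{in}}_i + 1/c^{\text{out}}_i + 1/c^{\text{in}}_{WT} +
1/c^{\text{out}}_{WT}$, optionally (and by default) inflated by a single
multiplicative overdispersion factor $\phi$ estimated from the
between-replicate scatter of NS: $\phi$ is the ratio of the pooled
inverse-variance-weighted residual chi-square to its degrees of freedom,
floored at 1. This parallels the error models of established deep
mutational scanning pipelines such as DiMSum without re-implementing their
per-replicate shrinkage internals; it has the same leading-order behaviour
and is validated against a parametric bootstrap in the test suite
(agreement within 10%).

Replicates are merged by inverse-variance weighting
($w_r = 1/\sigma_r^2$, $SE = (\sum_r w_r)^{-1/2}$) and the merged table is
re-centered so that NS(WT) $= 0$ exactly. Variants with input reads in every
kept replicate but zero output reads anywhere are flagged *non-nucleating*
and receive no NS — no pseudocounts are added. Classification applies a
two-sided z-test with Benjamini–Hochberg adjustment (Benjamini–Yekutieli
selectable): $q <$ FDR and NS $> 0$ is NS+, $q <$ FDR and NS $< 0$ is NS−,
otherwise WT-like. The default FDR is 0.1.

A known property of WT-referenced scores worth keeping in mind: the wild-type
replicate noise term $\varepsilon_{WT,r}$ is shared by every variant's NS in
that replicate. With few biological replicates an unlucky wild-type draw
shifts the whole library coherently, and because the z-scores are then
correlated, an all-null library occasionally produces a block of calls in a
single simulation even though the *mean* call fraction over repeated
simulations stays within the FDR bound. Likewise the FDR controls false
rejections of the exact null NS $=0$, not directional errors among variants
with genuinely tiny effects.

## Read-level quantification

Paired 125-bp reads covering the amplicon (25-nt 5' constant region, variant
coding sequence, 21-nt 3' constant region) are merged by ungapped overlap
consensus — the construct length minimising the overlap mismatch fraction
wins, and within the overlap the higher-quality base is taken, with the
per-base maximum quality retained. Constant regions are then matched at
their expected positions, allowing at most $\lfloor 0.20 \cdot
\text{flank length}\rfloor$ mismatches per flank (5 for the 25-nt flank, 4
for the 21-nt flank); reads failing either flank are discarded, as are reads
with any variant-region base below Phred 30. "Below 30" is read strictly
(Q30 passes) and per base, not as a read average: downstream matching is
exact, so single low-quality bases are the relevant failure mode (a
mean-quality mode is available). The surviving region is matched *exactly*
against the designed set, at nucleotide level by default or by translated
product; everything else is tallied as non-designed and dropped. Exact
matching against a complete designed set replaces alignment-based variant
calling.

Count filtering then drops variants with fewer than 10 input reads in any
biological replicate (technical replicates pooled — "any of the replicates"
is read at the biological level, matching how replicates enter the scoring
model) and variants reachable by a single nucleotide change with fewer than
1000 input reads pooled across all replicates (whether the published
threshold was per replicate or pooled is unstated; pooled is the default and
both are configurable). The wild type is never dropped. Filters are
idempotent.

## The synthetic selection assay

The simulator generates data with exactly the statistical structure the
scoring model assumes, so every downstream stage is testable without the
original sequencing archive:

1. each variant draws a latent true score $NS^{\text{true}}$ from a
   three-component Gaussian mixture (decrease / null / increase) whose
   weights depend on mutation class and region;
2. per biological replicate, input frequencies are
   $\text{Dirichlet}(\alpha)$; output frequencies are proportional to
   $f^{\text{in}}_i \exp(NS^{\text{true}}_i + \varepsilon_{i,r})$ with
   $\varepsilon \sim N(0, \sigma_{\text{rep}}^2)$, and dead variants are
   zeroed before renormalization;
3. technical replicates share the biological replicate's frequencies and
   differ only by multinomial resampling at the sequencing depth, mirroring
   how technical replicates are pooled in scoring;
4. optionally, each counted molecule is emitted as one read pair with
   independent per-base errors; correct bases carry Q37 and erroneous bases
   Q20, so an error-free dataset round-trips exactly through quantification
   while any error rate exercises the Phred-30 filter.

Selection is modelled as a single bulk exponential enrichment rather than an
explicit colony-growth branching process: NS is defined purely from
frequency ratios, so any monotone generative link suffices, and this one
makes the truth analytic.

Defaults are the study conditions of the emulated assay: 3 biological × 5
technical replicates, depth $10^6$ reads per sample, $\alpha = 50$ (mild
input unevenness), $\sigma_{\text{rep}} = 0.2$ (log scale, consistent with
the high between-replicate reproducibility reported for the assay), dead
probability $9/3164$ (the nine observed non-nucleating variants), and
mixture weights per (class, region) cell taken from the published NS+/NS−
fractions per mutation class in the N-terminal (1–28) and C-terminal core
(29–42) regions — e.g. half of N-terminal truncations increase nucleation
and none decrease it, while nearly all core truncations are strongly
deleterious. Component parameters $(\mu, \sigma)$ are $(-3, 1)$, $(0, 0.1)$
and $(+1.5, 0.5)$, chosen once to span the NS range the assay reports.
Variants are assigned the "core" cell when the mutation touches residues
29–42 (for removals: any removed residue in the core; insertions at the
28/29 gap count as N-terminal).

What the simulator deliberately does not model: PCR amplification bias,
chimeras, jackpot effects, position-dependent Illumina error profiles, or
position-specific effect structure within a region (true effects are
exchangeable within a mixture cell). Passing recovery tests therefore shows
that the estimator is unbiased and calibrated *given the assumed noise
model*; they do not validate the model against real sequencing artefacts.

## Atlas analyses

*Regions.* Positions partition into 1–11, 12–16, APR1 (17–21), 22–28 and
APR2 (29–42) — APR1/2 being the two aggregation-prone stretches composed of
aliphatic residues and glycines — with derived N-terminal (1–28) and core
super-regions. The aliphatic set is {G, A, V, L, I, M}; glycine is included
deliberately, following the composition of the aggregation-prone regions,
and is configurable. Point mutations take the region of their position (an
insertion is reported at the mutant position of the inserted residue, and
the insertion between 28 and 29 counts as N-terminal); removals take the set
of regions they intersect plus an APR category (APR1 only / APR2 only /
APR1+APR2 / no APR).

*Degenerate expansion.* Position-indexed analyses (the deletion matrix and
its marginals) expand each variant to all of its member specs, so a
degenerate deletion populates every (first, last) cell it can be written as,
with one shared score; library-level statistics count each variant once.

*Hotspot detection.* From the per-position NS+ frequency vectors (by first
and by last deleted position), the detector reports all maximal runs of
consecutive positions with frequency strictly above half the vector maximum;
the hotspot is the longest run, with ties reported in full. The rule is
invariant to positive scaling of the frequencies.

*Alternative aliphatic cores.* Internal deletions bridging the N-terminal
and core regions remove $e - 28$ core residues and slide the $e - 28$
residues preceding the deletion start onto former core positions. A variant
is an alternative-core candidate iff that replacement segment is exclusively
aliphatic; its core length is the maximal contiguous aliphatic run ending at
the C terminus (14 for the wild type). The replacement-segment length
definition is the most literal reading of "replacing part of the core";
other readings (e.g. requiring a minimum core length) are possible, and the
candidate count is reported rather than asserted — the published figure
(n = 64) was produced under a criterion whose details are not fully
specified.

*Truncation series, ROC, correlation, growth.* Pure N- and C-terminal
truncation profiles are ordered by residues removed (2–39 under the design
bounds; the 27 N-terminal truncations removing at most 28 residues leave the
core intact). AUC uses the Mann–Whitney midrank form (ties count one half),
making it invariant under strictly monotone transforms. Weighted Pearson
correlation uses weighted means and covariances with $1/SE^2$ as the natural
weight choice. Growth rates are the maximum over sliding windows (default 10
points) of the least-squares slope of $\ln(\text{OD})$ against time.

## Numerical choices and edge cases

* Coordinates are 1-based with inclusive intervals; deterministic ordering
  (class, then position, then residue) keeps outputs diff-stable.
* Zero counts never receive pseudocounts: a zero input count means the
  variant is unobserved in that replicate (no score), a zero output count
  with full input support means non-nucleating.
* `merge_replicates()` requires at least one finite replicate; SE $= 0$ with
  NS $\ne 0$ is flagged as degenerate rather than classified.
* Read merging requires a minimum overlap of 10 nt and tolerates at most 25%
  overlap mismatches; ties in overlap search prefer the shorter construct.
  Flank matching is ungapped: an indel inside a flank costs the read.
* The hotspot detector returns an empty result for all-zero or all-missing
  frequency vectors.
* Every random routine consumes an explicit seed from its configuration;
  rerunning any stage with the same configuration reproduces byte-identical
  tables.

## Scale of the shipped validation runs

The test suite and the acceptance script validate parameter recovery at the
assay's nominal scale (full Abeta42 library, depth $10^6$, 3 × 5
replicates) and FDR calibration over 20 all-null simulations at the same
scale. Read-level round trips run on a reduced wild type (12 residues, ~500
variants) at depths around $10^3$ — read merging is exercised
identically there, and the construct/read geometry (overlapping 125-bp
pairs) matches the full design. The full-scale read-level reprocessing of
hundreds of millions of archived reads is out of scope by design; the
round-trip and property tests substitute for it.

## Known limitations

* The error model is a delta-method approximation with a single global
  overdispersion factor; DiMSum's per-replicate shrinkage estimators are not
  re-implemented, so per-variant classifications on real data can differ
  near the significance boundary.
* The simulator's effect mixture is exchangeable within (class, region)
  cells; analyses that depend on finer positional structure (e.g. hotspot
  location) are validated with explicitly planted truths instead.
* Alternative-core candidate counting depends on an under-specified
  published criterion (see above).
* fAD (familial Alzheimer's disease) variant labels and in-vitro kinetic
  rate constants are consumed as user-supplied tables; they are not
  redistributed with the package.
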