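---
title: "Profiling sequence selectivity of RNA loop-closing ligation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sequence selectivity of RNA loop-closing ligation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplig)
```

## The scientific problem

RNA hairpins closed by four-nucleotide loops (tetraloops) are among the
most common secondary-structure elements in biology, and two families,
UNCG and GNRA (N = any base, R = purine), dominate structured RNAs.
Nonenzymatic *loop-closing ligation* builds such hairpins in one step: a
short duplex carrying a randomized 4-nt 3' overhang (5'-NNNN-3') and an
activated 5'-phosphate on the opposing strand closes the nicked loop
without any external template. The same overhangs can instead anneal to
a complementary overhang on another duplex and undergo *splinted
(nicked-duplex) ligation*, which is intermolecular and therefore
concentration dependent.

`looplig` implements the computational side of a deep-sequencing assay
that separates these two pathways and profiles the sequence selectivity
of each. Two duplex pools (A:a and B:b) react in one pot; four junction
products are distinguishable by sequence: P1 (A-a), P2 (A-b), P3 (B-a),
P4 (B-b). P2 and P3 can only arise from cross-duplex splinted ligation,
so the read fraction

$$ s = \frac{P2 + P3}{P1 + P2 + P3 + P4} $$

is a *lower limit* on the splinted contribution (same-type nicked-duplex
events are absorbed into P1 and P4). The variant space of the assay is
256 overhangs x 6 closing base pairs (C:G, G:C, U:A, A:U, U:G, G:U)
= 1536 hairpin variants, enumerated by `variant_space()`.

Because no raw sequencing data are publicly deposited for this kind of
assay, the package ships a first-class synthetic-data module whose
defaults encode the study conditions, so that every downstream stage is
testable end to end with known ground truth.

## The generator: what it emulates

**Input-library bias.** Solid-phase synthesis does not deliver an even
NNNN distribution. `position_base_frequencies()` defaults to the
measured marginals — A 0.33, G 0.26, U 0.22, C 0.19 at positions 1–3 and
C 0.33, A 0.28, G 0.21, U 0.18 at position 4 — and
`sample_input_library()` draws multinomially under positional
independence. Only marginal compositions are reported for such
libraries, so independence is the simplest consistent model; it yields
an approximately 10-fold spread between the most and least common
sequence, of the same order as the measured 8–20-fold range.

**Sequence-dependent loop closing.** `efficiency_model()` assigns
consensus-group mean efficiencies (first matching pattern wins):
UNCG 0.62, CNNG 0.30, GNNA 0.28, UNNC 0.20, RNNY 0.002, and a fallback
of 0.05 for unmatched sequences — a nominal 310-fold spread between the
best and worst groups. Within-group dispersion is not constrained by any
published per-sequence table, so it is exposed as a lognormal noise
parameter (`noise_sd`, default 0.25 on the log scale) rather than
asserted; the middle fallback value of 0.05 places unclassified
sequences between the favored and disfavored groups, consistent with
middling sequences being neither top- nor bottom-ranked.

**Splinted ligation.** The propensity of an overhang to direct splinted
ligation is the product of four per-base-pair annealing weights over the
Watson–Crick splint (`w_gc = 3`, `w_au = 1` by default; no wobble pairs
in the splint), times the partner's pool frequency, times the duplex
concentration, times a scale factor. This makes splinted products
CG-rich, reflecting the stronger C:G pairing that drives the observed
preference.

**The competition.** `simulate_reaction()` partitions every molecule
among loop closing, splinting with a same-type or cross-type partner,
and hydrolysis of the activated phosphate, with probabilities
proportional to the mass-action rate terms; reads are then drawn from
the ligated pool by a single multinomial. The hydrolysis constant
(`k_hyd = 4` against `k_loop = 1`) was chosen once so that expected
ligated yields fall at roughly 2 % in the 5 nM regime and 10 % at
250 nM, inside the observed 2–10 % window.

**Calibration of the concentration scale.** The assay's two regimes
bracket the competition: about 44 % of reads are P2+P3 at 250 nM versus
about 3 % at 5 nM. A single-step mass-action partition that is linear in
concentration cannot reproduce both numbers exactly — its odds can drop
at most 50-fold over a 50-fold concentration range, which compresses the
achievable spread relative to the bimolecular annealing equilibrium of
the real system. `calibrate_splint_scale()` therefore solves for the
scale matching each target by bisection against the deterministic
per-molecule enumeration (`expected_splinted_fraction()`) and uses the
geometric mean. Under the defaults the expected observed fractions are
about 41 % and 4.7 %, each inside the reported ranges (39–49 % and
2–6 %). This compression is a known limitation of the partition model,
accepted for its transparency and analytic tractability.

**Mock tetraloop reference.** `generate_reference()` emulates a
redundant tetraloop table extracted from an automated secondary-
structure annotation resource: entries (loop, closing pair, context of
30–80 nt, frequency) with the canonical biological families over-
represented (default weights UNCG 40, GNRA 25, CUUG 10, the broader
UNNG group 4, all others 1) and a configurable fraction of
near-duplicate contexts to exercise deduplication. It is a synthetic
stand-in — it reproduces the enrichment *structure* of biological
tetraloop tables, not any real database's counts. Consequences: the
pipeline's loop-closing/biological overlap statistics land near twice
the chance expectation (as in the real comparison), but their exact
values reflect the generator's weights, not biology.

**What the generator does not model.** No kinetic ODE integration or
nearest-neighbor thermodynamics; no PCR/RT amplification bias; no indel
sequencing errors (an optional uniform substitution rate is available in
`write_reads()` for robustness testing; qualities are constant).
Passing tests therefore demonstrate that the *analysis* is correct and
well calibrated on data with the assumed statistical structure — they do
not validate the chemistry itself.

## Demultiplexing and counting

`construct_spec()` describes the product layout: 5' handle, 12-nt
donor-strand tag (A/B), the 4-nt overhang, 12-nt acceptor-strand tag
(a/b), 3' handle. The default sequences are invented plumbing;
classification depends only on the spec. `classify_reads()` matches each
tag window by Hamming distance (default `max_mismatch = 0`; no indel
alignment, since the constructs are fixed-length and products are
distinguished by exact identity), rejecting reads as `no_donor_tag`,
`no_acceptor_tag`, `ambiguous`, or `bad_overhang`. Tag pairs must be
separated by more than `2 * max_mismatch` so no read can match both. T
is mapped to U on input; coordinates are 1-based inclusive. Counts are
conserved: classified plus rejected always equals reads in.

## Normalization and profiling

Input frequencies come from a near-complete control ligation
(`input_frequencies()`, optional pseudocount for zero cells), and each
sequence gets a normalization factor

$$ \alpha_i = \frac{f_i}{1/256} = 256 f_i, $$

the only form consistent with the stated anchor (alpha = 1 at frequency
1/256) and multiplicative bias; product counts are divided by alpha and
renormalized (`normalize_counts()`). Each overhang-bearing strand gets
its own input distribution; the alpha applied to a product class is that
of the strand contributing the overhang (a for P1/P3, b for P2/P4).
Ranks are assigned by descending frequency with lexicographic
tie-breaking (zero-count sequences last), so rankings are deterministic
under any input order. `fold_range()` excludes zero-frequency sequences
from the denominator and reports their number separately — with real
data even the rarest sequences had tens to hundreds of reads, so zeros
are a synthetic-only edge case.

`position_composition()` gives the frequency-weighted (sequence-logo)
base composition, and `information_content()` the per-position
information $IC_j = 2 + \sum_b p_{bj}\log_2 p_{bj}$ bits, ranging from 0
(uniform) to 2 (invariant). `classify_top_k()` assigns the top-k ranked
sequences to ordered consensus groups (favored: UNNG, CNNG, GNNA;
disfavored: RNNY, ANNR, CNNU). Both alpha-normalized and raw-read
rankings are computed and exported, since published top-k tables do not
always state which was used.

## Reference overlap statistics

The biological reference is deduplicated before ranking: contexts are
compared by global ends-free alignment (`pairwise_similarity()`, unit
match, -1 mismatch, -1 gap), and an entry is dropped when identity
exceeds 0.90 with coverage of at least 0.70 relative to the shorter
sequence. The alignment scheme behind the published thresholds is not
specified, so an end-gap-free global alignment was chosen for
determinism; the greedy scan keeps the most frequent representative
(ties broken lexicographically by context) and discards — rather than
merges — the frequencies of removed entries. A shared-8-mer prescreen
skips alignments that could not reach the identity threshold on
contexts of at least 30 nt. After grouping by the six closing pairs and
ranking loops by summed frequency (`group_rank()`), the top-k ligation
sequences are intersected with the top-k biological tetraloops.

Under the null of unrelated rankings the overlap of two top-40 sets from
a 256-sequence population is hypergeometric with expectation
$40 \cdot 40 / 256 = 6.25$ (`hypergeom_expected()`; this is the "about
6" chance level). `hypergeom_tail()` sums the exact pmf in log space:
the enrichment p-value is the inclusive upper tail, depletion the
inclusive lower tail; two-sided tests are not used because the scientific
claims are directional. With these conventions, $P(X \ge 12) = 0.0093$
and $P(X \le 2) = 0.029$ at (N, K, n) = (256, 40, 40) — matching the
significance levels reported for the real comparisons, which supports
this reading of the published test construction (the per-reaction
versus averaged-statistic choice is not fully specified there; the
package reports per-group tails and their mean). `enrichment()` reports
fold enrichment as observed/expected and depletion as
expected/observed.

## Validation statistics

`spearman_rho()` is the Pearson correlation of midranks; ties are
handled by average ranks because the published analysis does not state
its tie policy (its two reported values, 0.83 in the text and 0.84 in a
figure caption, suggest minor methodological latitude — neither is
asserted as exact here). `rank_yield_correlation()` reverses the rank
order before correlating so that high yield at a good (numerically
small) rank gives positive rho. The packaged 34-sequence yield panel
(`validation_panel()`) is synthetic at the per-sequence level but
constructed so the consensus-group means equal the measured ones
(UNCG 62 %, CNNG 30 %, GNNA 28 %, UNNC 20 %, RNNY 0.2 %); the 310-fold
UNCG/RNNY spread follows exactly.

## Numerical choices and degenerate inputs

* Tail sums, pmf values and binomial coefficients are computed in log
  space (`lchoose` + log-sum-exp) to avoid underflow at extreme tails.
* Partition probabilities per molecule are exact ratios of rate terms;
  a reaction in which nothing can ligate raises a degenerate-input
  error rather than emitting an empty pool silently.
* Constant vectors make rank correlations undefined: that is an error,
  never NaN.
* Zero-frequency control cells make alpha undefined; using them is an
  error naming the sequences, and a pseudocount is the documented
  remedy.
* Every stochastic function takes an explicit seed and is a pure
  function of (parameters, seed); the pipeline derives all stage seeds
  from the single mandatory config seed and keeps them below 2^31.
* Serialized reports round floating point to 10 significant digits and
  exclude the output path from the configuration hash, so identical
  analyses give byte-identical reports wherever they are written.

## Problem sizes and what the defaults compute

The default pipeline (`pipeline_config(seed = ...)`) simulates all six
closing-pair reactions at 5 and 250 nM with 10^6 molecules per duplex
pool and 2 x 10^5 reads per reaction, estimates per-strand input
distributions from 10^6-read controls, and uses a 1200-entry mock
reference. Parameter-recovery checks use 10^6 reads per simulation
(median Spearman between true efficiency and normalized frequency
around 0.95, required >= 0.9 over 20 seeded runs), and the
flat-profile normalization identity is checked at 10^7 reads
(fold range within 10 % of 1). These sizes were chosen so the full
analysis, including tests, completes in minutes on one CPU while
keeping the rarest sequences at tens of reads or more in the regimes
where quantitative claims are tested.

Two printed observables are deliberately not reproduced numerically,
because they depend on features the generator does not model: the
product-frequency fold range at default depths exceeds the 70–280-fold
seen in the wet data (the simulated efficiency spread of 310-fold,
widened by lognormal within-group dispersion and low-count granularity
at the disfavored end, is wider than the effective wet-lab spread), and
the exact 44 %/3 % splinted fractions are replaced by the calibrated
41 %/4.7 % pair discussed above. Both are properties of the chosen
study conditions, not of the analysis code, and the corresponding
checks are therefore property-based (lower-limit, monotonicity,
recovery) rather than equality assertions.

## Known limitations

* The partition model is single-step mass action: no time courses, no
  annealing equilibria, hence the compressed concentration dependence.
* The mock reference reproduces enrichment structure only; overlap
  magnitudes with it are generator properties.
* Demultiplexing is substitution-only (Hamming); reads with indels in
  the tag windows are rejected, not rescued.
* Paired-end merging, UMI handling and quality trimming are out of
  scope; reads are single-end full constructs.
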