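---
title: "Mining logic rules from phylogenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining logic rules from phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profrules)
```

## The problem

A phylogenetic profile is the presence/absence pattern of a gene family
across a collection of complete genomes.  Genes acting in consecutive
steps of the same pathway tend to be gained and lost together, so
correlated profiles are evidence of functional linkage.  Pairwise
correlation, however, cannot express the logic of a pathway whose first
step is carried out by any one of several non-homologous enzymes: the
urate oxidation pathway converts urate to allantoin through one of the
alternative oxidases Uox, HpxO, HpyO or PuuD (COG3748), followed by the
shared downstream enzymes Urah (HIU hydrolase) and Urad (OHCU
decarboxylase).  No single alternative correlates cleanly with the
downstream pair; what does is the *logical* statement

```
urah & urad & !uox & !hpxO & !hpyO  ->  COG3748
```

— the downstream genes are present and no known oxidase is, so whatever
carries out the first step must be the remaining candidate.  `profrules`
searches for such implications systematically.

## The method

**Negation augmentation.**  Every family contributes two literals, its
presence and its logical negation, so rules can require absence as well
as presence (`augment_with_negations()`).

**Frequent item sets.**  Antecedent candidates are conjunctions of
literals.  They are enumerated level-wise (Apriori): a set can only be
frequent if all its subsets are, because support — the number of genomes
satisfying every literal — is anti-monotonic.  Sets mixing both
polarities of one family are contradictions and are pruned at candidate
generation.  Internally, genome sets are bit-packed (31 genomes per
integer word) so that support counting is a vectorised AND plus a
16-bit popcount table; this keeps a 2000-genome x 32-literal mining run
around a second without compiled code.

**Rules and confidence.**  For a fixed consequent literal, each frequent
antecedent yields one rule with its 2x2 truth table: TT/TF/FT/FF counts
of genomes by antecedent truth x consequent truth.  Confidence is the
number of cases where the rule is correct relative to the cases where it
is applicable, TT/(TT+TF).  A rule applicable nowhere raises an error
rather than returning 0 or NaN.

**Significance.**  The dependency between antecedent and consequent is
scored with a two-sided Fisher exact test using the point-probability
convention: with margins fixed, the p-value sums the hypergeometric
probabilities of all tables at most as probable as the observed one
(relative tolerance 1e-12 on the comparison, so boundary ties are not
flipped by rounding).  The evaluation runs entirely in log space
(`lgamma` + log-sum-exp), which keeps p-values of the order of 1e-196 —
routine for strong associations over ~1700 genomes — exact; `log10_p` is
carried alongside `p` to survive double underflow.  The two-sided choice
is forced by a property the analysis relies on: a rule and its opposite
(same antecedent, negated consequent; column swap of the truth table)
receive the same p-value, so significance measures dependency, never the
direction of the implication.  One-sided tails do not have this
symmetry.  Degenerate tables (an empty margin) return p = 1 with a flag.

**Ranking.**  Rules are ranked by confidence (descending), with ties
broken by p-value, antecedent size, and antecedent label, making output
order fully deterministic.

**Printed p-values.**  Rule tables print p at one significant digit with
the mantissa truncated toward zero (1.5e-185 prints as `1e-185`,
2.4e-172 as `2e-172`), the convention that matches published rule
listings of this kind; the full-precision `log10_p` is always written in
a parallel column.

## Capacity classification

`classify_capacity()` applies the pathway logic genome by genome: the
labels are the explainer (first-step) families present, plus
`unexplained` when all downstream genes are present but no explainer is
— the residue class that points at a still-missing gene — and
`downstream_incomplete` when only part of the downstream set is present.
Genomes with several explainers keep all labels; no priority is imposed
because co-occurrence, although rare, is real.  `summarize_by_class()`
cross-tabulates labels against a metadata grouping such as
monoderm/diderm membrane class, counting a multi-label genome once per
label.

## The synthetic generator

Real 1700-genome matrices with curated gene calls are not
redistributable at desk scale, so validation uses
`simulate_pathway_profiles()`, which plants exactly the structure the
miner is supposed to find:

* a pathway indicator per genome, Bernoulli(`pathway_prevalence`);
* pathway genomes carry every downstream family and exactly one
  alternative, drawn with mixture `weights`; each such gene is lost with
  probability `dropout` (false absence from imperfect gene calling);
* any gene a genome does not truly carry appears with probability
  `spurious` (false presence), which also produces the rare
  co-occurrence of two alternatives;
* background families are independent Bernoulli noise.

Defaults are calibrated to the observed prevalences of the urate
oxidation system in a 1690-genome survey: 25% pathway prevalence
(the marginal frequency of *urad*), alternative weights
0.45/0.08/0.07/0.40 for *uox*/*hpxO*/*hpyO*/*puuD* (putting *puuD* at
~9.4% and *uox* at ~11% marginal prevalence), 5% dropout, 1% spurious
presence, ten background families at 30% prevalence.  Genomes are
i.i.d.: the generator does not model phylogenetic autocorrelation (the
clustering of PuuD in proteobacteria, say), mirroring the statistical
treatment of genomes as exchangeable observations; passing tests
therefore validate the mining machinery, not robustness to lineage
effects.

`expected_truth_table()` is the closed-form oracle: conditioning on the
latent pathway indicator and alternative choice makes family presences
independent, so expected truth-table cells are exact finite sums.  Tests
compare simulator means against it at 3 standard errors.

**Random numbers.**  One seed determines the matrix; draws are consumed
in a fixed documented order (pathway indicators, alternative choices,
then one uniform vector per family in configuration order), so
reproducibility cannot depend on iteration order.

## The recovery experiment

The stochastic end-to-end check plants the rule "downstream genes
present and all other alternatives absent implies the chosen
alternative" and asks how often mining ranks it first.  Design choices,
fixed ahead of the experiment by a power analysis of the generative
model:

* problem size 2000 genomes, 100 independent matrices;
* support floor 7.5% of genomes (150), just below the planted rule's
  expected applicability of ~9.4%.  A lower floor admits antecedents
  with small applicable sets whose confidence estimates have standard
  errors of ~0.05; among tens of such near-siblings, one will
  occasionally out-rank the planted rule by sampling noise alone.  At
  7.5% the main competitors are either excluded or are antecedent
  subsets of the planted rule, whose applicable genomes contain the
  planted rule's and which therefore almost never win the confidence
  comparison;
* confidence floor 0.5 and maximum antecedent size 5 (the planted rule's
  own size).

Under these conditions the planted rule is top-ranked in ≥95 of 100
runs.  For the routine analysis of real matrices the default support
floor is much lower — `max(2, 0.5% of genomes)` — so that rules at the
prevalence scale of the published urate-oxidase table (support ≈ 9% of
genomes) survive by a wide margin; the threshold is logged in the run
manifest because rule lists are threshold-sensitive.

## Numerical and edge-case choices

* Missing cells are rejected at parse time, never imputed; the row and
  column of the first offending cell are named.
* The reader accepts `1/0` and `Y/N` tokens; the writer emits `0/1`
  TSV, bit-exact under round trip.
* Literal order is canonical everywhere (family id in C-locale order,
  presence before absence), so mining output is independent of hash or
  locale ordering.
* An empty antecedent is vacuously true: its truth table puts every
  genome in the TT/TF row.
* No multiple-testing correction is applied to rule lists by default
  (published tables report raw P); `log10_p` makes any correction a
  one-liner downstream.
* Species deduplication (`dedupe_species()`) is available but off by
  default, and reports what it drops.

## Problem sizes used in the test suite

Oracle-equivalence tests run the miner against exhaustive enumeration on
200 random matrices of up to 6 families (12 literals) x 64 genomes, and
the Fisher evaluator against direct point-mass enumeration on a dense
sweep of tables with totals up to 40 (about 70,000 tables).  The
recovery experiment uses the full 2000-genome condition over 100 seeds;
simulator calibration uses 200-500 replicate matrices.  These sizes keep
the whole suite within a few minutes on one CPU while leaving each
check's power intact.

## Known limitations

* No phylogenetic correction: shared ancestry can inflate apparent
  association; significant rules are hypotheses for experimental
  follow-up, not proofs of function.
* The miner enumerates frequent sets exhaustively level by level; with
  very low support floors and hundreds of families the candidate space
  grows combinatorially.  Mine with a restricted `literal_universe` or a
  higher floor in that regime.
* The capacity classifier encodes one pathway topology (shared
  downstream steps, alternative first steps); other logics need their
  own scheme.
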