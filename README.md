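# profrules

Association rule learning on phylogenetic presence/absence profiles, for
predicting gene function from comparative genomics.

## The problem

Genes of one pathway are gained and lost together across genomes, so
correlated presence/absence profiles point at functional links.  But a
pathway whose first step is carried out by any one of several
non-homologous enzymes defeats pairwise correlation: in urate
oxidation, the downstream enzymes Urah and Urad are shared while the
first step is done by *uox*, *hpxO*, *hpyO* **or** the membrane-bound
*puuD* (COG3748), so no single oxidase tracks the downstream pair.  The
informative statement is a logic rule over presence (`urah`) and absence
(`!uox`) literals:

```
urah & urad & !uox & !hpxO & !hpyO  ->  COG3748
```

`profrules` mines such rules systematically from a binary genome ×
gene-family matrix:

* **negation augmentation** — every family contributes a presence and an
  absence literal;
* **Apriori mining** — level-wise enumeration of frequent,
  contradiction-free literal conjunctions (support is anti-monotonic),
  with bit-packed support counting;
* **confidence** — TT/(TT+TF) from each rule's 2×2 truth table
  (antecedent truth × consequent truth over genomes);
* **significance** — two-sided Fisher exact test (point-probability
  convention) evaluated in log space, exact down to p ≈ 1e-300 and
  reported as `log10_p` beyond that; a rule and its opposite provably
  share a p-value, so significance measures dependency, not direction;
* **capacity classification** — per-genome pathway logic (which
  explainer oxidases are present; `unexplained` genomes have the
  downstream pair and no known oxidase);
* **a synthetic generator** with planted pathway structure, dropout and
  spurious-presence noise, plus its closed-form expected truth tables,
  used to validate the whole pipeline.

## Worked example

Score the strongest published urate-oxidase rule from its truth table:

```r
library(profrules)
t1 <- truth_table(154, 12, 5, 1519)
rule_confidence(t1)          # 0.9277108  -> prints as 0.928
fisher_exact_two_sided(t1)
#> p = 1e-196 (log10 p = -195.813649)
```

154 of the 166 genomes where the antecedent holds also carry COG3748
(confidence 0.928), and the association is overwhelming (p ≈ 1.5e-196,
printed at one significant digit as `1e-196`).

Mine a simulated matrix with the pathway structure planted and recover
that rule shape end-to-end:

```r
cfg <- pathway_sim_config(seed = 7)          # 2000 genomes, 16 families
m <- simulate_pathway_profiles(cfg)
rules <- generate_rules(m, "puuD", min_support = 150, min_confidence = 0.5)
head(rank_rules(rules)[, c("rank", "antecedent", "tt", "tf", "confidence",
                           "log10_p")], 2)
#>   rank                 antecedent  tt tf confidence log10_p
#> 1    1 !hpxO&!hpyO&!uox&urad&urah 160 26     0.8602  -170.5
#> 2    2      !hpxO&!hpyO&!uox&urad 166 39     0.8098  -170.5
```

The top-ranked rule is exactly the planted one: downstream genes present,
all other alternatives absent, implies *puuD*.  Its confidence (~0.86)
reflects the configured 5% dropout and 1% spurious-presence noise.

The same pipeline is available from a shell:

```sh
inst/cli/profrules simulate --config cfg.yaml --seed 7 --out m.tsv
inst/cli/profrules mine --input m.tsv --consequent puuD \
    --min-support 150 --min-confidence 0.5 --out rules.tsv
inst/cli/profrules fisher 154 12 5 1519
inst/cli/profrules summarize --input m.tsv --tree species.nwk --out labels.tsv
```

See `vignettes/association-rule-profiling.Rmd` for the model, parameter
choices and limitations.

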