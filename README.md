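# connmap

Gene-expression connectivity mapping with signed-rank reference profiles,
for drug-repositioning analyses that start from a ranked
differential-expression (DE) table — whether it came from an RNA-seq tool
or a microarray analysis — and end in a ranked list of candidate
compounds.

## The method

A **reference profile** encodes one compound-treatment experiment as a
signed ranking of all N probes on a platform: the probe with the
strongest differential expression gets rank magnitude N, the weakest gets
1, and the sign records the regulation direction. All replicate profiles
for one compound form its **reference set** (cardinality: the *setsize*).

A **gene signature** is an ordered list of m probe identifiers
g<sub>1</sub>…g<sub>m</sub> with up/down signs s(g<sub>i</sub>) ∈ {+1, −1},
obtained by walking a ranked DE table in position order and mapping each
gene to its platform probes (genes without probes are skipped; a
multi-probe gene contributes consecutive entries and may be cut mid-gene
at m).

The **connection score** of a signature to a profile with signed ranks
R(·) is

> c = Σ<sub>i</sub> s(g<sub>i</sub>) · R(g<sub>i</sub>),  
> C = c / c<sub>max</sub>,  with c<sub>max</sub> = Σ<sub>i=1..m</sub> (N − i + 1),

so C ∈ [−1, 1], reaching +1 exactly when the signature probes occupy the
top m magnitudes with matching signs. A compound's **setscore** is the
mean of C over its replicate profiles; a negative setscore marks a
compound that inverts the signature's phenotype (a candidate inhibitor).

Significance comes from a randomization null: `n_random` random
signatures (m distinct probes, the query's sign composition) are scored
against each reference set, and the two-sided add-one estimate
p = (#{|C<sub>rand</sub>| ≥ |C<sub>obs</sub>|} + 1)/(n_random + 1) is
compared against the Bonferroni threshold α/D over the D compound sets
(α = 1 by default, so the estimated FDR of a query with n<sub>sig</sub>
hits is 1/n<sub>sig</sub>). Each significant connection is then
stress-tested by **single-gene-omission perturbation**: the m
leave-one-out variants of the signature are re-queried and the compound's
*stability* is the fraction of variants under which it stays significant.
Candidates are ranked by stability, then setsize, then |setscore|.
Finally, candidate lists from two platforms can be compared by exact
hypergeometric overlap and setscore sign concordance.

A synthetic-study generator plants signature–compound connections of
tunable strength λ into an otherwise null database (every profile a
uniform signed permutation), so the whole pipeline is testable without
any external data.

## Worked example

```r
library(connmap)

cfg <- synth_config(
  N = 2000, D = 200, K_range = c(4, 4),
  planted = data.frame(compound = "planted", strength = 0.9, direction = -1),
  sig_m = 10, seed = 42
)
study <- gen_connectivity_study(cfg)
study$db
#> <ref_db> 2000 probes, 800 profiles, 200 compound sets (setsize 4-4)

qcfg <- query_config(n_random = 20000, seed = 42)
res  <- query_database(study$signature, study$db, qcfg)
glance(res)
#> # A tibble: 1 × 7
#>   n_sets query_length alpha_family threshold n_random n_sig fdr_est
#>    <int>        <int>        <dbl>     <dbl>    <int> <int>   <dbl>
#> 1    200           10            1     0.005    20000     1       1

rep    <- perturbation_stability(study$signature, study$db, qcfg, res)
ranked <- rank_results(add_stability(res, rep))
head(ranked, 3)
#> # A tibble: 1 × 8
#>   refsetname setsize queryName queryLength setscore    pvalue   sig stability
#>   <chr>        <int> <chr>           <int>    <dbl>     <dbl> <int>     <dbl>
#> 1 planted          4 synthetic          10   -0.872 0.0000500     1         1
```

The one planted compound (connection strength 0.9, inverse direction) is
the only significant hit among 200 sets: its setscore −0.872 is close to
the planted −0.9, its p-value sits at the add-one floor 1/(20000 + 1),
and it survives all ten single-gene omissions (stability 1). `autoplot(res)`
draws the corresponding volcano plot; `tidy(res)` returns the per-compound
table.

Real analyses substitute `read_de_table()` / `read_annotation()` /
`read_ref_db()` for the generator, `map_genes_to_probes()` (or
`optimize_signature_size()`, which finds the smallest signature meeting
an FDR target) for `study$signature`, and `compare_queries()` to contrast
candidate lists from two platforms.

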