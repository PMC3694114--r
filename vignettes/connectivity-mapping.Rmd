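---
title: "Connectivity mapping with signed-rank reference profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmap)
```

## The model

Connectivity mapping asks which compounds in a reference database induce
transcriptional changes that mimic — or invert — a phenotype of interest.
The phenotype is summarised as a gene signature; each compound experiment
is summarised as a signed-rank reference profile.

**Reference profiles.** A profile over an N-probe universe assigns every
probe a signed rank: magnitude = position when probes are ordered by the
strength of differential expression (N for the most extreme), sign =
regulation direction. The magnitudes of a valid profile are exactly the
permutation 1..N; this invariant is enforced on construction and on every
load. Putting the *largest* magnitude on the most differentially
expressed probe makes the normalisation constant
$c_{\max} = \sum_{i=1}^{m}(N-i+1)$ attainable, so the score below reaches
exactly ±1 at the extremal configurations.

**Connection score and setscore.** For a signature
$(g_1,s_1),\dots,(g_m,s_m)$ and profile ranks $R(\cdot)$,
$$ c \;=\; \sum_{i=1}^m s_i\,R(g_i), \qquad C \;=\; c/c_{\max} \in [-1,1]. $$
A compound's setscore is the arithmetic mean of $C$ over its replicate
profiles. Because $C$ is linear in the profile, the mean signed-rank
vector of a set is a sufficient statistic for its setscore — the
implementation scores sets through that vector, and the identity
"setscore = mean of per-profile scores" is verified by a dual-route test
at full platform scale (N = 22,283, six replicates). The mean is one of
several defensible combination rules (a variance-scaled mean is another);
it is adopted here because it makes a single-replicate set reduce exactly
to the profile score and keeps the null machinery identical at every
setsize.

**Assumptions.** The score treats ranks as interchangeable across
experiments (no batch structure within a reference set), weights
signature genes by the *profile's* ranking only (signature order does not
weight the sum — it matters only through which genes survive the cut at
m), and reads direction from gene-level regulation status shared by all
probes of a gene.

## Signature construction

DE tables are consumed as ranked tables; the `position` column is the
ordering authority. Re-sorting by p-value is deliberately avoided: source
tools document their own tie handling (typically sub-sorting equal
p-values by descending absolute log2 ratio), and `position` preserves it.
The walk appends, for each gene in position order, all of that gene's
annotated probes that exist on the platform, each signed by the gene's
log2-ratio sign, and stops at m — possibly mid-gene. A probe already
contributed by an earlier gene is not added twice. Unmapped genes are
skipped, so deleting them from the table provably changes nothing.

`optimize_signature_size()` scans an ascending grid of sizes (default
5, 10, …, 100 — a conventional sweep; the grid is a tuning surface, not a
scientific constant) and returns the smallest size whose query yields at
least one significant connection with estimated FDR at or below the
target. By construction its result is identical to calling
`query_database()` directly at that size: there is no hidden state, which
a test asserts.

## Randomization significance

The tested statistic is the setscore itself. The null draws random
signatures — m *distinct* probes uniform over the universe — and scores
them against the same reference set with the same combination rule. Two
implementation choices deserve note:

* **Sign handling.** The null specification assigns the query's multiset
  of signs in random order. Since a uniformly drawn ordered tuple of
  distinct probes has exchangeable coordinates, scoring every draw with
  the query's *fixed* sign vector yields the same distribution; the
  implementation exploits this and skips the per-draw permutation.
* **Distinct sampling.** Draws are taken iid with replacement and rows
  containing a duplicate are redrawn; conditioning on distinctness keeps
  the law exactly uniform and is fast when m ≪ N.

The p-value uses the add-one form $(b+1)/(n_{\text{random}}+1)$: it can
never be zero, which keeps Bonferroni scaling honest. Comparisons between
observed and null strengths happen on the unnormalised $c$ scale, where
all values are sums of exact dyadic rationals, so ties are compared
exactly rather than through a floating tolerance. Significance is
two-sided (on $|C|$), with direction reported separately by the setscore
sign, because one query is expected to surface both phenotype-enhancing
and phenotype-suppressing compounds.

One null stream is drawn per query length and reused across all D sets of
a query (sub-seeded as `seed + 100003·m`, so queries of different lengths
— in particular the leave-one-out variants — never share a stream). This
mirrors computing one benchmark distribution per signature size and cuts
the cost D-fold; p-values across sets of one query are therefore weakly
dependent through the shared draws, which the null-calibration test shows
is immaterial at the sizes used here.

With the family budget α (default 1) a set is significant when
p ≤ α/D, D the number of *compound sets* (not individual treatment
instances — results are reported per compound, so the compound set is the
natural testing unit). The expected number of false positives is then at
most α, giving the estimated FDR α/n_sig. The default α = 1 makes the
threshold 1/D and the FDR estimate 1/n_sig — the unique choice under
which queries with a few hundred significant connections land in the
0.003–0.007 FDR range that a 0.01 target contemplates.

`query_config()`'s `n_random` defaults to 10^6; the constraint
`n_random ≥ 10·D/α` guarantees the grid of attainable p-values resolves
the Bonferroni threshold. Tests and the acceptance script pass 2,000 to
100,000 draws, matched to the database sizes they use (see *Problem
sizes* below).

## Perturbation stability

Each of the m leave-one-out variants of the signature (omit entry i,
restore it, omit the next) is re-queried at its own length's Bonferroni
threshold with its own null stream (seed offset by the variant index);
a compound's stability is the fraction of variants under which it stays
significant, so it lives on {0, 1/m, …, 1} and 1 means the connection
never hinged on a single gene. "Omission with replacement" is read as
restore-then-omit-next rather than substitution by the next-ranked gene:
only omission is required for the robustness semantics, and substitution
would entangle the perturbation with the DE table's tail. The
`perturb_mode` configuration field records the choice and leaves room for
a substitution mode.

Stability is computed only for base-significant compounds (the others
keep `NA` and are excluded from ranking, which orders candidates by
stability, then setsize, then |setscore|, then name — name last as a
deterministic tie-break).

## The synthetic generator

`gen_reference_db()` emulates the study conditions the pipeline targets:
a database of D compound sets (desk-scale default 200; the
`paper_scale = TRUE` switch gives the full microarray-era shape of 1,309
compounds over a 22,283-probe universe with setsizes up to 32), each
profile an independent uniform signed permutation. A planted compound of
strength λ and direction ±1 starts with the signature probes occupying
magnitudes N..N−m+1 with matching (direction-flipped for −1) signs; each
planted probe is then swapped with a uniformly chosen probe with
probability 1−λ. Swap corruption — rather than additive rank noise — is
used because it preserves the permutation invariant exactly at every λ:
λ = 1 forces a setscore of exactly ±1, λ = 0 is provably
indistinguishable from null (a uniformity test on its p-values across
seeds checks this).

`gen_de_table()` emulates the consumed table, not the upstream read-level
data: a top tier of `n_signal` strongly up-regulated genes (|log2 ratio|
log-normal around 3, matching the 2.7–5.6 range typical of a strong
stimulus contrast; p-values at or near zero, with the first third of the
tier underflowing to exactly 0 to exercise the tie sub-sort) above a null
remainder; per-gene annotation leaves a gene unmapped with probability
0.3 (the shape observed when three of a top ten fail to map to an array
platform) and fans it out to 2–3 probes with probability 0.2.
`gen_connectivity_study()` ties the halves together: the planted
signature *is* the signature mapped from the generated table, so
end-to-end recovery runs exercise the same code path a real analysis
uses.

What the generator does **not** emulate: correlated probes within genes
or pathways, batch effects across replicate profiles, platform-specific
intensity artefacts, and realistic compound-to-compound correlation
(every null compound is independent). Passing tests therefore demonstrate
the statistical machinery — scoring, calibration, multiplicity control,
perturbation, ranking — not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Ties in |statistic| during profile construction are broken by universe
  order (earlier probe → larger magnitude). The convention is declared,
  not inferred: any deterministic rule works, and this one makes builds
  reproducible across runs and platforms.
* A zero statistic receives sign +1 by convention (a signed rank must be
  nonzero).
* m ≥ N is rejected (degenerate null); empty databases, empty
  signatures, empty reference sets and zero setscores in concordance are
  rejected with named errors rather than propagating NaN.
* An empty candidate-list overlap has undefined direction concordance
  and returns `NA`.
* The hypergeometric overlap tail is the exact sum
  $P(X \ge k)$ (upper tail, ≥ convention stated to avoid off-by-one
  drift), delegated to R's `phyper`; a test pins it to an independently
  computed exact rational-arithmetic value at the 64/122/1,309
  configuration and to a binomial-coefficient convolution oracle at small
  sizes.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so a full
run finishes in about a minute while keeping every statistical check
resolvable: null calibration at N = 1,000, D = 200, K = 2 over 50 seeds
with 2,000 null draws per query (the add-one grid then crosses the 1/200
threshold on 10 of its 2,001 points, expected significant count 0.9995);
planted recovery at N = 2,000, D = 200, K = 4, λ = 0.9 over 20 seeded
end-to-end runs; enumeration cross-checks at N ≤ 8 with 10^5 draws.

## Known limitations

Dose- and cell-line-stratified querying is out of scope (metadata columns
are carried but not used for scoring). The FDR estimate is the coarse
α/n_sig bound, not a q-value. The randomization null is sampled, never
analytic, so p-values inherit Monte-Carlo granularity of
1/(n_random + 1). Signature construction trusts the annotation map's
probe order; alternative orderings within a gene change which probe is
cut at m for mid-gene truncations.
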