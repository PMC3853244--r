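---
title: "Predicting drug target groups from ontology term distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug target groups from ontology term distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ontarget)
```

## The problem and the model

A drug exerts its effects — wanted and unwanted — by binding target
proteins, and those targets fall into a small number of broad classes:
G Protein-coupled Receptors, Nuclear Receptors, Ion Channels and Enzymes
in the KEGG grouping. Predicting the *class* of a compound's targets from
cheap annotation narrows every downstream search. `ontarget` does this
from chemical-ontology annotation alone, on the premise that compounds
whose ontology terms sit close together in the ontology graph tend to hit
the same class of proteins.

The model has three parts.

**The term graph.** An OBO ontology (such as ChEBI) is parsed into an
undirected graph: one node per `[Term]` stanza, one edge per `is_a` or
`relationship` assertion. Direction is discarded because the score built
on the graph is used symmetrically, and all relationship types are kept
as edges since each asserts some semantic proximity. Parallel assertions
between the same pair of terms collapse to a single edge; obsolete terms
are retained by default (a `drop_obsolete` switch removes them). The
distance $d(t, t')$ between two terms is the unweighted shortest-path
hop count, computed lazily per query through breadth-first search rather
than as an all-pairs matrix — real ontologies have tens of thousands of
terms, and a full matrix would be wasteful when a prediction touches only
a few hundred of them.

**The compound-pair score.** Two compounds $c_1$, $c_2$ with ontology
term sets $T(c_1)$, $T(c_2)$ are scored by

$$Q(c_1, c_2) = \mathrm{Mean}\{\, d(t_1, t_2) : t_1 \in T(c_1),\ t_2 \in
T(c_2) \,\},$$

the arithmetic mean over the full Cartesian product of the two sets.
Smaller $Q$ means a stronger functional relationship. Two readings of
"Mean" are possible — over the multiset of distances or over the set of
distinct distance values — and the package implements the multiset mean,
the standard convention in semantic-similarity work; the choice is
isolated inside `compound_similarity()`. In the common single-term case
the score reduces exactly to the term distance.

**The classifier.** A query drug is assigned the majority target group of
all training drugs at the exact minimum $Q$ (the "nearest" drugs); a tie
among top groups is broken uniformly at random under a caller-supplied
seed, and every prediction records whether randomness was used. The
comparison predictor swaps the neighbor criterion for the maximum
chemical-chemical interaction score $I$, a STITCH-style combined score in
which 0 encodes non-interaction.

## Exact arithmetic and degenerate inputs

$Q$ is a mean of small integers, and the neighbor rule demands *exact*
equality at the minimum. Floating-point means would turn exact ties into
an epsilon policy, so `ontarget` carries $Q$ as an integer fraction —
hop-count sum over pair count — and compares candidates by integer
cross-multiplication. The magnitudes involved (hops × pair counts) are
far below $2^{53}$, so the products are exact in double precision.

Ontologies are not always connected (ChEBI's sub-ontologies largely are
not). Term pairs in different components get the distance sentinel `Inf`,
and any $Q$ touching such a pair is *undefined* (`NA`), never a large
stand-in number. Undefined candidates are skipped during neighbor
selection; a query undefined against every training drug produces an
explicit **no-prediction** outcome. The same outcome arises in the
interaction backend when the query interacts with no training drug — a
maximum of exactly 0 is non-evidence, not an all-way tie. Evaluation
counts no-predictions as errors *and* reports them separately, so
abstention can never silently inflate accuracy.

## Evaluation protocols

`jackknife()` runs the leave-one-out test: each drug is predicted with
itself removed from the training set, which makes the result unique for a
dataset up to tie-break randomness. `independent_test()` scores a
held-out partition against a fixed training set and refuses overlapping
inputs. Reports store only integer counts; percentages are formatting,
recomputed from the counts at print time, so the identity "overall =
count-weighted mean of per-group accuracies" holds exactly.

One master seed spawns a per-query tie-breaking seed by counter
(`seed + 7919 * i`, reduced modulo a large prime), so a full report is
reproducible and any single prediction can be re-run in isolation.
`predict_target()` itself does **not** exclude a query that happens to be
in the training set — exclusion is the protocol's job, and the jackknife
loop asserts on every iteration that the held-out drug is absent.

Train/test splitting draws `round(f * n)` drugs (round half up — 10% of
876 drugs gives exactly 88) uniformly without replacement, unstratified:
group proportions in the test set vary by draw, which mirrors how such
benchmarks are usually split and keeps the operation a pure function of
`(data, fraction, seed)`.

## The synthetic benchmark

Historical benchmark accuracies for this method depend on particular
snapshots of ChEBI, KEGG and STITCH and on unreported tie-break
randomness, so they cannot be regression targets. Instead the package
ships a generator whose ground truth is known by construction, and the
test suite certifies the method's *properties* on it.

`generate_synthetic_ontology()` builds a rooted tree with one branch per
target group. Each branch has `branch_depth` levels of
`terms_per_branch` terms; the first term of each level is a hub, level-1
hubs attach to the root, deeper hubs chain to the hub above, and all
other terms attach to their level's hub. Branches therefore meet only at
the root: within-branch distances are bounded by the short spine, while
cross-branch distances grow with the depth of both endpoints. At depth
≥ 2 each branch also gains one `relationship`-typed shortcut edge, so
parsers and graphs see non-`is_a` edges without ever connecting branches.
The class signal is structural — no tuned distance threshold anywhere.

`generate_synthetic_drugs()` samples each drug's terms from its group's
branch; a `cross_branch_noise` fraction of drugs has one term replaced by
an off-branch term, emulating annotation that ignores class boundaries.
`generate_synthetic_interactions()` makes within-group pairs interactive
at one rate and cross-group pairs at another, with within-group scores
drawn uniformly from 500–999 and cross-group from 1–499 (STITCH-like
integer scores), encoding the premise that functionally similar compounds
interact more strongly.

Defaults — 4 groups × 50 drugs, 12 terms per level × 3 levels, 2 terms
per drug, 5% noise, interaction rates 0.30 within / 0.05 across, seed 7 —
are sized so a full jackknife runs in a couple of seconds on one core
while leaving room for genuine errors (the noisy drugs). On these
defaults the ontology backend's leave-one-out accuracy is about 96%:

```{r benchmark}
bench <- generate_benchmark(synth_config())
ev <- jackknife(bench$drugs, backend = "ontology", g = bench$graph, seed = 7)
ev
glance(ev)
```

```{r plot, fig.width = 6, fig.height = 3}
autoplot(ev)
```

What passing tests on this benchmark do and do not show: they certify
the algorithmic contracts — distances equal to brute-force oracles,
neighbor sets equal to exhaustive scans, exact tie handling, protocol
bookkeeping, class recovery when the signal is real — but the generator
does not mimic ChEBI's degree distribution, its multiple disconnected
sub-ontologies, STITCH's score distribution, or annotation depth
heterogeneity, so accuracy *levels* on synthetic data say nothing about
accuracy levels on real drugs.

## Benchmark-construction rules

Real drug lists arrive messy. `apply_benchmark_filters()` implements the
standard screening cascade as a total function: drop drugs without
ontology annotation, drop drugs mapped to more than one target group,
drop drugs in explicitly excluded groups (classically Cytokine
Receptors, too small to model); each record is charged to the first rule
it trips, and the per-rule casualty counts are returned alongside the
survivors. The drug-table carrier format is deliberately minimal TSV —
`drug_id`, `group`, semicolon-joined `terms` — chosen to be inspectable
and diff-friendly; `read_drug_table()`/`write_drug_table()` round-trip it
exactly.

## Known limitations

- Single-label only: a drug gets one group; genuinely multi-target drugs
  are excluded by the filtering rules rather than modeled.
- The single-shell neighbor rule uses only the drugs at the exact
  minimum; there is no $k$-shell extension, distance weighting, or
  ensemble of the two backends.
- All relationship types are treated as identical unweighted edges; no
  reasoning over relation semantics and no information-content
  similarity.
- Identifier cross-mapping (KEGG ↔ ChEBI ↔ STITCH) is out of scope;
  inputs must arrive pre-mapped.
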