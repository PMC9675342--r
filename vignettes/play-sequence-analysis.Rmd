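---
title: "Analysing play sequences: transitions, predictability and games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing play sequences: transitions, predictability and games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Social play in animals is a stream of discrete, coded actions ("play
elements") exchanged by several players. `playseq` asks two questions of
such data: does knowing the preceding element (or elements) help predict
the next one, and do elements organise into higher-order clusters —
"games" — whose members follow each other at above-chance rates and are
positionally interchangeable? The package takes BORIS-style event logs
(one row per element onset, per player, per bout), an ethogram describing
the repertoire, and returns transition statistics, permutation-test
significance, prediction accuracies, similarity clusters and network
communities. Element durations are deliberately ignored: the analysis is
purely about sequential order within each player (partner behaviour is
treated as noise).

## The model and its assumptions

The core object is the first-order conditional transition probability
$P(c \mid a) = n(a \to c) / \sum_x n(a \to x)$, estimated within
individual-bouts and never across a `BREAK`, a stretch of missing data, or
a bout boundary. Three coding artefacts have to be undone first, in a
fixed order:

1. **Lumping** (`lump_rare_elements`): elements with fewer than
   `lump_min_count = 20` total occurrences are replaced by an a-priori
   similar element named in the ethogram; passes repeat to a fixpoint so a
   rare target is itself resolved, and an element that stays rare with no
   target is retained. The order lump → collapse → linearize is a package
   convention; lumping first means the collapse sees the final repertoire.
2. **Run collapse** (`collapse_state_runs`): continuously coded state
   elements are re-marked at every change while active; only the first
   occurrence of a continuous activity period is a choice, so later
   re-markings are dropped. "In a row" means continuously active across
   consecutive steps — any step without the element, or any marker,
   restarts it.
3. **Linearization** (`linearize`): elements sharing one onset have no
   observable order, so each step's elements are emitted in uniformly
   random order and every analysis is averaged over
   `n_linearizations = 1000` such orders. This is why transition counts
   are fractional.

**Significance** comes from a bout-preserving permutation null
(`permutation_null`): per-bout slot counts, marker positions and global
element frequencies are held fixed while non-marker tokens are pooled
across bouts and reassigned at random (`n_permutations = 1000`). The
p-value is the fraction of randomisations whose transition probability
reaches the observed one; ties count against significance, the
conservative reading. A fresh linearization is drawn per randomisation so
co-occurrence noise is part of the null. Transitions with
`p <= alpha = 0.01` and at least `min_transition_count = 5` (fractional)
occurrences are retained. Whether the original analysis pooled tokens
across bouts or shuffled within bouts is ambiguous; the package defaults
to across-bout pooling (`permutation_scope = "across"`) and exposes the
within-bout variant as a config option. Robustness is described by
bootstrap percentile intervals over resampled individual-bouts — the
natural exchangeable unit — reporting both the 2.5–97.5 percentile range
and the max–min range.

**Prediction** (`kfold_accuracy`) fits Laplace-smoothed n-gram tables up
to order `max_order = 3`: every observed context row gets one added
occurrence per vocabulary element; unseen contexts score the uniform floor
$1/|V|$. Higher orders are interpolated as the *product* of the suffix
conditionals (the probability of a consequent after `A/B/C` is the product
of its probabilities given `A/B/C`, `B/C` and `C`), following the quoted
construction rather than a weighted sum; predicted distributions
renormalise these scores. Each repetition holds out 5% of
individual-bouts (`train_fraction = 0.95`), and only held-out tokens with
a full antecedent window are scored, with the scored count reported —
the alternative denominator (all tokens) is not used. Because "correct
classification" can mean two things, both are provided: `expected_match`
(the probability assigned to the truth — the expected accuracy of
probability-matched guessing, whose order-0 value is $\sum_i p_i^2$) and
`argmax` (modal prediction, lexicographic tie-break). `expected_match` is
the default for order-comparison tables since a $\sum_i p_i^2$ baseline
matches the low zero-order accuracies such analyses report. The naive
Bayes comparison is a categorical add-one classifier whose features are
the previous `order` positions, independent given the consequent; it is
faster and better optimised but its accuracy cannot be read as purely
sequential information.

**Similarity** (`consensus_clusters`): each element is a row of
first-order transition probabilities; rows are embedded in 2-D with UMAP
and clustered with k-means, choosing `k` by mean silhouette on the
embedded Euclidean distances. Solutions above `silhouette_threshold = 0.3`
are considered structured. Because the stochastic layout varies, the
embedding and selection are repeated `n_embedding_runs = 50` times with
epochs drawn uniformly in $[0.5, 1.5] \times$ `mean_epochs = 7000`; "the
most likely solution" is operationalised as the modal `k`, and among runs
with that `k` the highest-silhouette run is reported, together with a
co-assignment stability matrix, a UPGMA dendrogram of the chosen
embedding, and the silhouette of the hierarchical cut alongside the
k-means one (either could be the basis of a reported value). UMAP
neighbourhood size and minimum distance keep the algorithm's canonical
defaults (15 and 0.1) and are exposed as arguments; PCA initialisation is
used so degenerate inputs (duplicate rows) embed without spectral
failures.

**Networks** (`build_network`, `detect_communities`): significant
transitions become weighted directed edges; elements with none are
excluded and reported as isolates. Communities maximise Newman–Girvan
modularity on the symmetrized (weight-summed) graph — the directed edges
are preserved in the stored network and exports, but the modularity
objective is undirected. Self-loops stay in the network (elements do
significantly follow themselves) but are excluded from the modularity
objective, where they would trivially inflate within-community weight.
Up to `exact_community_limit = 8` nodes the package enumerates all set
partitions, so the optimum is exact by construction; larger networks use
an exact integer-programming maximizer (igraph's `cluster_optimal`), and
a labelled multi-start Louvain fallback exists for networks beyond ILP
reach. The enumeration limit is 8 because the number of set partitions
grows super-exponentially (Bell numbers); the ILP route is equally exact,
so the limit affects cost, not results. A partition is acceptable when
modularity exceeds `modularity_threshold = 0.3`. The within-community
transition share is compared against the mean share under 1000
size-preserving label permutations — the expectation could be defined
otherwise (e.g. analytically from community sizes), and the label
permutation is the package's choice. Partition agreement between the
similarity clusters and network communities is reported as adjusted Rand
index and normalized mutual information (mean-entropy normalization,
computed in the package) on the shared elements.

## The synthetic generator

`make_game_structure` plants a known partition of the repertoire into
games: each element's transition row puts `within_mass` (default 0.9)
uniformly on its own game and the rest uniformly elsewhere. Defaults — 6
games of 10 elements, 7 continuous states spread across games, bouts of
2–4 independent players, token counts drawn from a lognormal truncated to
[3, 181] with mean 30.3 (the meanlog solved so the truncated mean is
exact), co-occurring onsets at rate 0.1, breaks at rate 0.05 — mirror the
scale and artefact structure of a detailed chimpanzee play dataset. Three
generator rules are forced by the coding semantics rather than free
choices: state elements carry no self-loop mass (a continuous state
cannot re-initiate while active, and run collapse would destroy such
tokens), breaks are inserted before persistence is painted on so a break
genuinely interrupts activity, and co-occurrence grouping never absorbs a
token into a state's step when that state re-initiates immediately after.
`make_order2_structure` provides a second-order variant (each antecedent
pair has one preferred consequent) used to show that prediction accuracy
rises with order exactly when the data warrant it, and
`simulate_null_bouts` produces structureless sequences for type-I
calibration.

One property of product interpolation is worth knowing when designing
such checks: because the suffix conditionals are correlated, their
product sharpens the predicted distribution, and on densely sampled
small-repertoire data an extra antecedent can raise measured accuracy a
little even when the generating process is strictly first-order — the
higher-order contexts recur often enough between folds to carry reusable
(if redundant) statistics. The order-3 plateau that sparse behavioural
data show is therefore checked on weakly structured first-order data at
a realistic repertoire size (60 elements, within-game mass 0.4, 100
bouts), where antecedent triples essentially never recur and the
third-order factor reduces to the uniform smoothing floor.

What the generator does *not* emulate: partner contingency and
turn-taking, durations, age or individual effects, and unbalanced
repertoire frequencies. Passing recovery tests therefore show that the
pipeline inverts its own coding artefacts and detects planted block
structure — not that real play data contain such structure.

## Numerical choices and degenerate inputs

Reproducibility flows from one master seed: every stage, ensemble member
and randomisation derives its own stream via a hash
(`derive_seed`), so stages can be re-run in isolation and results are
independent of evaluation order; UMAP runs single-threaded for exact
reproducibility. Permutation p-values use the `>=` comparison with a
`1e-12` guard against float noise from fractional averaging. Ties in
argmax prediction break lexicographically. Empty conditional rows are
omitted; elements never observed as antecedents get zero profile rows and
are flagged. All-identical embedding points yield a degenerate flag
rather than a crash; k-means retries center draws when duplicated points
collide. Bootstrap replicates in which an antecedent never occurs
contribute `NA` to its percentiles, with the defined-replicate count
reported.

## Problem sizes used in the shipped checks

The package's own test battery runs the type-I calibration on 20 elements
over 200 bouts at 1000 permutations, the power check on the 6×10 game
structure over 300 bouts, the order-monotonicity check at 200 k-fold
repetitions, and a full-pipeline recovery with 50 linearizations, 1000
permutations, 10 embedding runs and 10 k-fold repetitions; the exhaustive
community oracle covers 50 random graphs of up to 8 nodes. These sizes
make the Monte-Carlo error small relative to the margins being asserted
while keeping a full run of the battery inexpensive.

## Known limitations

Higher-order (2–3 antecedent) transitions are used for prediction only;
significance testing is first-order, as in the source analyses. Non-
adjacent dependencies and collocation-style alternatives to the
permutation null are out of scope, as are the two alternative
co-occurrence treatments (single-sampling and bag-of-words). The
similarity pipeline inherits UMAP's sensitivity to hyperparameters;
consensus over repeated runs reduces but does not remove it. Transition
estimates for rare antecedents remain volatile — that is what the
bootstrap intervals are for — and lumping decisions are a-priori inputs,
not inferred.
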