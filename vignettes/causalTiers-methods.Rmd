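---
title: "causalTiers: methods, assumptions and design choices"
author: "causalTiers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{causalTiers: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalTiers)
```

# The problem and the model

`causalTiers` discovers a partially directed causal network from a single
observational cohort: n subjects by p mixed-type variables, each variable
assigned to one of T ordered *time epoques* (measurement-or-effect periods,
e.g. constitutional/genetic through long-term follow-up), with one variable
designated the outcome. The inferential basis is the standard one for
constraint-based discovery:

* **Causal Markov condition** — every variable is independent of its
  non-effects given its direct causes; the factorisation of the joint
  distribution follows the causal DAG.
* **Faithfulness** — the *only* conditional independencies in the
  distribution are those the DAG implies via d-separation.

Together they make the dependence structure of the data a perfect map of
the generating DAG, so an algorithm that tests conditional independencies
can reconstruct the graph up to its Markov equivalence class. Temporal
tiers supply the extra background knowledge — causation cannot run
backwards in time — that orients most of what equivalence leaves open.
Two standing caveats are inherited from this framework and not solved
here: unmeasured confounders are not modelled (no FCI-style latent edge
marks), and the output of any single run is an estimate subject to
sampling noise (which the bootstrap safeguard quantifies, per edge).

# The conditional-independence test

The pipeline uses one unified test for all variable types: **Fisher-z on
the Spearman rank partial correlation**. For a test of x and y given Z,
the rows jointly observed for {x, y} ∪ Z are rank-transformed, the
partial correlation r is read off the inverse of their correlation
matrix (identical to correlating the residuals of rank-regressions on
Z), and z = atanh(r) · sqrt(n − |Z| − 3) is referred to a standard
normal.

Why this test: the cohorts this pipeline targets mix continuous
physiology, ordinal self-report scales and trinary SNP allele counts. A
monotone-association test treats all of them on one scale, at the cost
of power against purely non-monotone dependence — a deliberate trade.
The test function is pluggable (`ciFun` argument of `buildSkeleton()` /
`gllPC()`), so a likelihood-ratio/G² test for all-discrete margins can
be substituted without touching the surrounding machinery.

Missing data are handled by **test-wise complete-case deletion**. Each
test reports its effective n; when fewer than `minEffectiveN` (default
10, never below |Z| + 4) complete rows exist, or a variable is constant
on them, the result is *untestable*. Untestable results never establish
dependence — they cannot add an edge — and never remove an edge already
supported at smaller conditioning sets; each is logged. This is the
conservative reading for a cohort whose genetic block was only assayed
in a sub-sample: gene–behaviour relations are then decided on exactly
the sub-sample that can speak to them. No multiple-testing correction is
applied: the protocol fixes a raw per-test threshold (alpha = 0.05), the
constraint-based convention, and the bootstrap safeguard reports how
fragile each resulting edge is.

No imputation is attempted; test-wise deletion is unbiased under
missing-completely-at-random block designs (assays started late) but not
under outcome-dependent missingness, which the user must judge.

# Skeleton discovery

The local step is the GLL parent–children family in its semi-interleaved
form. For target t:

1. every other variable is tested marginally; those independent are set
   aside with sepset ∅;
2. the dependent ones are admitted one at a time, strongest marginal
   association first (ties broken by canonical variable order — the row
   order of the variable table, used for *all* tie-breaking in the
   package); each admission triggers an elimination attempt of the new
   candidate against all subsets (size ≤ max-k) of the other current
   candidates;
3. a final sweep re-checks every surviving candidate the same way.

The first separating set found for a rejected variable is recorded: PC
orientation needs one witness per pair, not all of them.

The global skeleton keeps edge x–y under the **AND rule** (x ∈ PC(y) and
y ∈ PC(x)), the sparser choice, preferred at n ≈ 200 where single-sided
inclusions are often false positives; `TestConfig(andRule = FALSE)`
switches to OR, bracketing the assembly variants in the local-to-global
literature. Epoques are *not* used to restrict the adjacency search —
time order bears on direction, not on the existence of dependence — they
enter at orientation only.

With the d-separation oracle substituted for the statistical test, this
procedure provably recovers the exact adjacency structure of a faithful
DAG; the test suite asserts it on randomized suites up to 10 nodes, which
is what a green skeleton test does and does not establish: correctness of
the *search logic*, not of any finite-sample inference.

# Orientation

Three stages, in order, each preserving acyclicity:

1. **Tiers** — every edge between different epoques is directed forward
   in time (`tier_oriented`). Tier orientations are immutable: statistics
   never overrule time.
2. **Colliders** — every unshielded triple A–C–B whose sepset excludes C
   becomes A → C ← B (`collider_oriented`). Conflict policy (the
   protocol's sources are silent here): if two triples demand opposite
   directions for one edge, the edge reverts to undirected and the
   conflict is logged; if a collider claim contradicts a tier edge, the
   tier wins; orientations that would close a directed cycle or point
   backwards in time are refused. Triples are visited in canonical
   order, so runs are deterministic.
3. **Propagation** — Meek rules R1–R4 to a fixed point (`propagated`).
   R4 is included because tier knowledge is background knowledge; with
   no tiers R1–R3 alone already complete the CPDAG, and the suite checks
   completeness against an exhaustive enumeration of consistent DAG
   extensions on small graphs.

Whatever remains undirected is reported as such — the Markov-equivalence
limit of observational data is honoured, and no residual edge is ever
oriented by fiat.

# Markov boundary and predictivity

The local causal model of the target is read off the oriented graph:
direct causes (parents), direct effects (children), spouses (parents of
children). Undirected edges incident to the target are *undetermined
neighbours*, reported separately rather than silently assigned — a run
that fails to orient near the target says so. `mbPredictivity()` checks
the parsimony property empirically: cross-validated variance explained
by a linear predictor on the boundary members versus on all variables.
The single linear predictor is deliberate; the property is about feature
sets, not model class, and one transparent model suffices to test it.

# Pathways and influence

`enumeratePaths()` collects all simple directed paths of 1..L edges
terminating at the target (default L = 4, excluding variables of only
distal influence; a "step" is an edge). Two semantics decisions:

* **Sub-paths count.** A path and its suffix are distinct pathways into
  the target — each is a real causal route. This is the only reading
  under which "all paths of ≤ L steps" is a well-defined enumerable set.
* **Undirected edges are not traversed** by default (`skip`): an
  unoriented edge is not an established causal step. The `either` policy
  (walk an undirected edge in one direction per path) is available for
  sensitivity analysis.

The influence of a variable is the proportion of enumerated paths
containing it — exactly the paths eliminated when the variable is
deleted, an identity the suite asserts by re-enumeration after deletion.
The full ranking is always produced (human-readable output rounds to
whole percent; files carry full precision); any top-k cutoff for
presentation is left to the user, since no principled threshold exists
for this heuristic. The ranking is a *connectivity* heuristic, not an
effect size: quantitative interventional estimation (do-calculus) is out
of scope.

# Bootstrap stability

The data are resampled by rows with replacement at the original n
(block missingness rides along with the rows), discovery is re-run B
times (default 100), and each edge gets the percentage of bootstrap
networks in which its *adjacency* appears. Adjacency rather than
direction is the default because orientation legitimately flips between
resamples while the underlying relation persists; orientation-aware
agreement is available as a separate column. Failed iterations are
logged and discarded with B adjusted, never silently. Identical seeds
reproduce reports exactly.

# The synthetic cohort: what it emulates, what it does not

`generateSystem()` + `sampleData()` provide the test bed standing in for
the (non-public) cohort the protocol was built for. The stated world:

| parameter | default | rationale |
|---|---|---|
| p | 148 | the study's pre-selected variable count |
| tiers | 7 | constitutional/genetic through 12-month follow-up |
| n | 207 | exposed sub-sample size |
| genetic sub-sample | 157 | subjects with genetic assays; the other 50 rows have all SNP columns missing |
| density | 0.03 | ≈ 2.3 edges/node at p = 148, the scale of a ~350-edge network |
| SNP fraction | 0.10 | a modest genetic block in tier 1, exogenous (no parents), Binomial(2, maf) |
| maf | 0.30 | common-variant allele frequency; arbitrary but fixed |
| edge weights | \|w\| in [0.5, 1.5], random sign | effects distinguishable from noise at study scale |
| noise SD | 1 | unit-scale structural noise |
| ordinal cutpoints | standard-normal terciles | 3-level scale items |

Structural equations are linear-Gaussian with ancestral sampling in
canonical order (sorted by tier, hence topological). Ordinal nodes are
discretised at their cutpoints and the *standardised codes* propagate
downstream — the recorded measurement is the variable, so the Bayes-net
factorisation (and with it the d-separation oracle) holds exactly for
the observed data. Within-tier edges are allowed (same-epoque causation
is real, e.g. gene–gene regulation), kept acyclic via canonical order.

Not emulated, by design: linkage disequilibrium between SNPs, nonlinear
or interaction effects, non-monotone links, missingness mechanisms other
than the late-assay block. A green recovery test therefore certifies the
pipeline's behaviour under its own assumptions at study scale — it does
not certify those assumptions for any particular real data set.

# Numerical and policy choices collected

* Correlations on ranks; partial correlation via inversion of the
  (|Z|+2)-square correlation submatrix; singular submatrices are
  untestable rather than errors. r is clamped to ±(1 − 1e−12) before
  atanh.
* Per-dataset caches: column ranks and the full Spearman matrix over
  complete columns; a second cache over the fully-complete row block,
  which block missingness makes the exact subset most incomplete-column
  tests use. Every cached test is then a small matrix inversion, which
  is what keeps 100 bootstrap re-discoveries at p ≈ 150 in minutes.
* Determinism: canonical variable order breaks all ties (admission
  order, subset enumeration, triple visiting, path ordering, ranking
  ties); results are invariant to data row order; all randomness is
  seed-parameterised.
* Degenerate (zero observed variance) columns are flagged on load and
  make any test touching them untestable.
* Disconnected nodes are retained in the node set and counted in
  reports.
* The tolerant edge-list reader maps common published column spellings
  (Source/Target/Direction/Stability) onto the canonical TSV schema and
  reads a blank or absent direction field as undirected; it exists so a
  published network can be re-analysed (`analyzeNetwork()`) without raw
  data. Its column mapping is adjustable once a concrete file is in
  hand.

# Limitations

Beyond the framework caveats above: max-k = 3 bounds the conditioning
sets, so dependencies only separable by larger sets can leave spurious
edges; the rank test has no power against non-monotone dependence;
test-wise deletion assumes benign missingness; and with n ≈ 200 the
false-negative rate on weak edges is substantial (the recovery
benchmarks document the degradation from n = 2000 to n = 200). The
influence ranking inherits every caveat of the discovered graph it walks.
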