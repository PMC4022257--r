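---
title: "Mining microbe-environment association patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining microbe-environment association patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seapattern)
```

seapattern detects association patterns between microbial taxa and
environmental factors in amplicon surveys. The pipeline has three stages:
reads are clustered into operational taxonomic units (OTUs) with a
homopolymer-aware greedy heuristic; an association network is built by
testing every pair of OTU and environmental-factor abundance vectors with
binned mutual information and a permutation test; and communities of
co-varying nodes are extracted by symmetric nonnegative matrix
factorization (s-NMF), with the number of communities chosen by fuzzy
modularity. This vignette explains each model, the tunable parameters, the
numerical choices, and what the synthetic validation data do and do not
establish.

## OTU clustering with neighbor seeds

Pyrosequencing's dominant error mode is mis-calling the length of
homopolymer runs (maximal stretches of one base). Under a plain greedy
97%-identity clusterer such reads seed spurious OTUs and inflate richness.
The clusterer here counteracts this in two ways:

1. **Neighbor seeds.** When a read founds a cluster, the full set of
   sequences reachable by changing one homopolymer run's length by up to
   `max_run_delta` (default 1, matching the predominant single-base
   miscall) is generated with `neighbor_seeds()`. Later reads are compared
   against this whole set, so a read whose only difference from the seed is
   one run-length miscall (plus whatever the identity threshold tolerates)
   is absorbed rather than founding a new OTU.
2. **Size refinement.** After the greedy pass, clusters with fewer than
   `min_cluster_size` member reads (default 2, i.e. singleton dissolution —
   the weakest nontrivial constraint) are dissolved and their reads
   reassigned to the surviving cluster of maximal seed identity, with ties
   going to the larger and then the earlier-founded cluster.

Reads are dereplicated first and visited in abundance order (ties broken by
read id), which makes the result independent of input order: abundant,
error-free sequences found the clusters that error variants later join.
Each read joins the *first* cluster whose neighbor-seed set reaches the
identity threshold; comparison is against the founding seed's neighbor set
only, not against every member, which keeps the pass linear in practice and
reflects the view that the seed is the cluster's representative sequence.

Identity is computed by global pairwise alignment with free end gaps
(match +1, mismatch −1, gap −2), as identity = matched columns / total
alignment columns, counting terminal-gap columns. Counting the flanks makes
completely dissimilar sequences score 0 rather than being undefined. When
several alignments tie on score they can differ in column count, so the
pair is aligned in a canonical lexicographic order, making the reported
identity exactly symmetric. The kernel is small C++ (Rcpp); the test suite
checks it against an independent pure-R dynamic program and against
exhaustive alignment enumeration on short strings.

**What this does not do.** No chimera detection, no quality-aware
denoising, no taxonomy assignment. The refinement cannot rescue reads
carrying three or more run miscalls: they sit beyond the neighbor-seed
radius, and when two such reads share most of their miscalls they can pair
into a small spurious cluster that survives singleton dissolution. At high
per-run miscall rates residual OTU inflation therefore remains — consistent
with heuristic clusterers generally, which reduce rather than eliminate
inflation. The property suite demonstrates exact template recovery in the
regime where multi-miscall reads are rare.

## Abundance vectors and filters

For OTU $\mu$ and sample $s$, the abundance is $x_{\mu s} = N_{\mu s} /
N_s$ with $N_{\mu s}$ the OTU's read count and $N_s$ the sample's total
read count. Two filters precede association testing:

* counts below `min_count` (default 5 reads) are zeroed, suppressing
  low-count detections that reflect sequencing effort rather than presence;
* OTU vectors with fewer than `min_nonzero` (default 3) nonzero entries are
  removed, since a vector observed in one or two samples produces spurious
  high associations. Environmental-factor vectors are exempt.

Every remaining vector is then zero-mean normalized to mean 0 and
standard deviation 1 (population SD). We read "zero-mean normalization" as
full z-scoring; a pure mean shift would be equally valid because the
downstream mutual-information estimator uses equal-width bins over each
variable's own range and is invariant under increasing affine transforms —
an invariance the tests assert explicitly. Normalization is kept because it
puts OTU and environmental variables on one documented scale in the
written artifacts.

## Mutual-information association networks

Dependence between two variables is scored by plug-in mutual information
over binned values: each variable's observed range is split into $M$
equal-width bins (rightmost bin closed), bin frequencies give empirical
probabilities, and $I(X,Y) = H(X) + H(Y) - H(X,Y)$. MI is preferred to
Pearson correlation because it captures nonlinear, non-monotone
dependence. Entropies use natural logarithms internally; a `base` argument
reports bits.

The bin count default is $M = \lceil \sqrt{S} \rceil$, a standard
rule-of-thumb that gives 4–5 bins for the 15–24 samples per season typical
of seasonal marine surveys; it is exposed prominently because binned MI at
these sample sizes is sensitive to $M$.

Significance comes from a permutation test: one variable's entries are
shuffled `n_perm` times (default 1000) and the p-value is the add-one rank
$(1 + \#\{I_{perm} \ge I_{obs}\})/(1 + n_{perm})$, which is never 0 and at
least $1/(n_{perm}+1)$; with the default 1000 permutations the smallest
attainable p-value (≈0.001) resolves the 0.01 threshold. Edges are
retained at `alpha_otu` (default 0.01) when at least one endpoint is an
OTU and at `alpha_env` (default 0.05) for pairs of environmental factors —
the laxer within-environment threshold reflects that those 18-odd
variables are few and of direct interest. No multiple-testing correction is
applied by default, matching the raw-threshold convention of co-occurrence
studies; a Benjamini–Hochberg option exists (`p_adjust = "BH"`).

Each pair's permutation stream is seeded from a hash of the sorted pair
labels, so the network is exactly invariant to variable ordering and
reproducible for a fixed master seed. Retained edges carry the observed MI
as weight; untestable (constant) variables and non-significant variables
remain in the node set flagged as isolated.

## Community detection by symmetric NMF

The weighted network is summarized by its adjacency matrix $A$; the
feature matrix $O$ factorized below defaults to $A$ itself, since $A$
already encodes node–node similarity. A symmetrically normalized
alternative $D^{-1/2} A D^{-1/2}$ is available for degree-dominated
networks but fails on isolated nodes.

s-NMF seeks a nonnegative $r \times n$ clique–node matrix $W$ minimizing

$$F_G(O, W) = \tfrac12 \lVert O - W^{\mathsf T} W \rVert_F^2 ,$$

the symmetric constraint ($H = W$) of generic NMF $O \approx W^{\mathsf T}
H$. The textbook multiplicative rule for this problem,
$W \leftarrow W \circ (W O) / (W W^{\mathsf T} W)$, is not guaranteed
monotone when applied symmetrically: it can overshoot and oscillate. The
implementation therefore uses the damped form

$$W \leftarrow W \circ \left( 1 - \beta + \beta\,
\frac{W O}{W W^{\mathsf T} W} \right),$$

with $\beta = 1/2$ by default. The damped rule has the same fixed points
(any stationary $W$ of one is stationary for the other) and keeps $F_G$
non-increasing at every step, which the tests check to $10^{-12}$ slack on
random symmetric inputs; $\beta = 1$ recovers the undamped rule exactly.
The Hadamard division is guarded by adding machine epsilon to the
denominator, which prevents 0/0 without shifting converged values. $W$ is
initialized elementwise uniform scaled by $\sqrt{\overline{O}/r}$ so
$W^{\mathsf T} W$ starts at the right magnitude; iteration stops when the
relative decrease of $F_G$ falls below `tol` (default 1e-6) or after
`max_iter` (default 500) steps.

Column-normalizing $W$ yields the fuzzy membership matrix $U$ ($U_{ki}$ is
node $i$'s degree of belonging to clique $k$); the hard label is the
column argmax with ties to the smallest clique index. All-zero columns
(nodes attached to no clique) become uniform $1/r$ with a warning.

The community count $r$ is selected by fuzzy modularity

$$Q_f = \frac{1}{2I} \sum_{ij} \left[ A_{ij} - \frac{k_i k_j}{2I} \right]
s_{ij}, \qquad s_{ij} = \sum_k U_{ki} U_{kj},$$

with weighted degrees $k_i$ and total edge weight $I$ (an unweighted
toggle exists for edge-count comparisons). For a one-hot $U$ this is
exactly Newman modularity, which the tests verify against an independent
community-sum oracle over exhaustive partitions of small graphs.
`detect_communities()` scans $r$ from `r_min` (2) to `r_max` (default
$\min(n, 20)$ — the scan needs some cap and community counts beyond ~20
are uninterpretable at the network sizes involved), runs `restarts`
(default 10) seeded factorizations per $r$, keeps the best by $F_G$, and
returns the $r$ with the highest $Q_f$, ties to the smaller $r$. Everything
is deterministic given the master seed; per-(r, restart) seeds are derived
by hashing.

## Topology report and random references

`topology_report()` collects node and edge counts, average degree
$2E/N$, the mean unweighted local clustering coefficient (degree-<2 nodes
contribute 0), the degree-distribution power-law exponent, and the
selected model's $Q_f$. The power-law exponent is the least-squares slope
magnitude of log frequency versus log degree over positive degrees — the
simplest scalar summary of degree-distribution heaviness; a Clauset-style
continuous MLE ($1 + n / \sum \ln(k/(k_{min}-0.5))$) is available via
`method = "mle"` and is preferable when the fit matters scientifically.
The null reference is the uniform $G(n, m)$ graph with the same node and
edge counts (`random_reference()`), so clustering and modularity are
compared at equal density; degree-preserving alternatives are outside the
current scope.

## Synthetic data: what it emulates, what it does not

`simulate_reads()` emulates pyrosequencing: each homopolymer run of length
≥ 2 in a template is lengthened or shortened by one base with probability
`homopolymer_error_rate`, and bases are substituted at
`substitution_rate`. Restricting miscalls to multi-base runs reflects that
run-length miscalls arise from flow-intensity ambiguity, which is
negligible for isolated bases; it also keeps a per-run rate meaningful —
applied to every length-1 run, a 10% rate would corrupt random sequence
beyond what any 97% clusterer could relate to its template. Default
templates are 3 random 60-nt sequences (short-amplicon scale, e.g. a V6
fragment) with pairwise identity kept below 0.9 so the planted OTUs are
unambiguous. Reads are spread uniformly at random over `n_samples`. Not
modeled: chimeras, quality scores, phylogenetically structured template
sets, and seasonal time-series dynamics — so passing recovery tests shows
the clusterer absorbs run-length errors, not that it handles every
artifact of real surveys.

`simulate_abundance()` plants exact dependence: linked pairs satisfy
$b = \rho a + \sqrt{1-\rho^2}\,\varepsilon$ among otherwise independent
Gaussian rows. Real relative abundances are compositional, zero-inflated
and autocorrelated in time; none of that is modeled, so network tests
establish calibration and recovery of planted signal only.
`planted_graph()` is a standard stochastic block model with optional
uniform(0.5, 1.5) weights, the conventional benchmark for community
recovery.

## Validation problem sizes

The shipped test-and-validation suite uses: 200 random instances
($S \le 20$, $M \le 4$) for the MI oracle; 1000 replicates of $S = 20$,
$M = 5$, 99 permutations for test calibration; 50 random symmetric
matrices ($n \le 10$) for objective monotonicity; exhaustive partitions of
100 random graphs ($n \le 8$) for the modularity oracle; 20 seeds of
three 20-node blocks ($p_{in} = 0.3$, $p_{out} = 0.02$) for community
recovery; and 10 seeds of 3 × 50 simulated reads for clustering recovery.
These sizes make the whole suite run in minutes while leaving each
statistical check adequately powered.

## Known limitations

* Binned MI with $S \approx 20$ samples and 4–5 bins is a high-variance
  estimator; the permutation test protects the error rate but power to
  detect moderate dependence is limited.
* The permutation null assumes exchangeable samples; for strongly
  autocorrelated time series the p-values are optimistic.
* s-NMF is a nonconvex optimization: restarts mitigate but do not remove
  initialization dependence, and the $Q_f$ model selection inherits
  modularity's resolution limit.
* The greedy clusterer's first-match rule is order-dependent by
  construction; determinism is recovered through the abundance sort, not
  through order-invariance of the underlying objective.
* Conditional (partial) associations are out of scope: an edge means
  marginal dependence and may be mediated by a third variable.
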