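# seapattern

Association-pattern mining for amplicon surveys of microbial communities.
Given 16S rRNA (or similar) reads from a set of samples plus a table of
environmental measurements, seapattern answers three questions in sequence:

1. **Which taxa are there?** Reads are clustered into operational taxonomic
   units (OTUs) at a fixed identity threshold (conventionally 97%) by a
   greedy heuristic that is robust to pyrosequencing homopolymer errors:
   each cluster seed is expanded into its set of *neighbor seeds* — every
   sequence one homopolymer-run-length change away — so reads whose only
   defect is a run-length miscall are absorbed instead of inflating the OTU
   count. Undersized clusters are dissolved and reassigned.
2. **What co-varies with what?** Each OTU's relative abundance vector
   x<sub>μs</sub> = N<sub>μs</sub>/N<sub>s</sub> (low counts zeroed, sparse
   vectors removed, rows z-scored) and each environmental-factor vector is
   tested pairwise with binned mutual information,
   I(X,Y) = H(X) + H(Y) − H(X,Y), estimated by plug-in frequencies over M
   equal-width bins. Significance comes from a permutation test; edges are
   kept at p ≤ 0.01 for pairs involving an OTU and p ≤ 0.05 for
   environment–environment pairs, weighted by the observed MI.
3. **Which groups move together?** The weighted network's adjacency matrix
   O is factorized by symmetric nonnegative matrix factorization,
   min<sub>W≥0</sub> ½‖O − WᵀW‖²<sub>F</sub>, via a damped multiplicative
   update. Column-normalizing W gives a fuzzy membership matrix U; the
   community count r is chosen by maximizing the fuzzy modularity
   Q<sub>f</sub> = (1/2I) Σ<sub>ij</sub> [A<sub>ij</sub> −
   k<sub>i</sub>k<sub>j</sub>/2I] Σ<sub>k</sub> U<sub>ki</sub>U<sub>kj</sub>.

A topology report (node/edge counts, average degree 2E/N, clustering
coefficient, degree-distribution power-law exponent, modularity) compares
each network against uniform G(n, m) random references of the same size.
Seeded synthetic-data generators (homopolymer-error reads, planted linked
abundance pairs, stochastic block model graphs) make every stage testable
end to end without external data.

All user-facing functions take and return tibbles (or small S3 objects with
`tidy()`, `glance()` and `autoplot()` methods) and chain with the pipe.

## Worked example

Cluster simulated pyrosequencing reads from three templates, then mine a
small abundance matrix with three planted dependencies:

```r
library(seapattern)

reads <- simulate_reads(n_templates = 3, reads_per_template = 50,
                        homopolymer_error_rate = 0.02, n_samples = 10,
                        seed = 42)
cluster_otus(reads, threshold = 0.97)
#> <otu_clustering> 150 reads in 3 OTUs (threshold 0.97)

sim <- simulate_abundance(n_otu = 8, n_env = 3, S = 20,
                          n_linked_pairs = 3, link_strength = 0.99, seed = 42)
mat <- zero_mean_normalize(sim$matrix)
net <- build_network(mat, n_perm = 999, seed = 42)
tidy(net)
#> # A tibble: 4 × 6
#>   node_a node_b weight p_value node_a_type node_b_type
#>   <chr>  <chr>   <dbl>   <dbl> <chr>       <chr>
#> 1 E1     OTU_7   1.42    0.001 env         OTU
#> 2 OTU_2  OTU_4   0.746   0.001 OTU         OTU
#> 3 OTU_3  OTU_6   1.06    0.001 OTU         OTU
#> 4 OTU_5  OTU_8   0.585   0.01  OTU         OTU
```

The 150 error-laden reads collapse to exactly the 3 planted OTUs. All three
planted pairs (`OTU_2–OTU_4`, `OTU_3–OTU_6`, `E1–OTU_7`) are recovered with
p = 0.001 (the smallest value 999 permutations can resolve) and weights
equal to the observed mutual information in nats; `OTU_5–OTU_8` at
p = 0.01 is a borderline chance association, the kind the raw 1% threshold
admits. Community detection on a planted three-block graph:

```r
pg <- planted_graph(c(20, 20, 20), p_in = 0.3, p_out = 0.02, seed = 42)
model <- detect_communities(pg$network, r_min = 2, r_max = 6,
                            restarts = 10, seed = 42)
topology_report(pg$network, model)
#> # A tibble: 1 × 6
#>   n_nodes n_edges avg_degree avg_clustering power_law_exponent modularity
#>     <int>   <int>      <dbl>          <dbl>              <dbl>      <dbl>
#> 1      60     198        6.6          0.214              0.240      0.403
```

The selected community count is the planted r = 3; modularity here is the
fuzzy Q_f of the selected model. `autoplot(net)`, `autoplot(model)` and
`autoplot(model, "selection")` draw the network, the membership heatmap and
the Q_f-versus-r selection path.

A thin command-line front end (`inst/cli/seapattern`) exposes each stage
(`cluster`, `abundance`, `network`, `communities`, `topology`, `simulate`,
`convert`, `run`) over the same functions, and `run_pipeline()` orchestrates
the whole flow from FASTA + sample map (+ optional environment table) to a
topology report, with a JSON manifest and byte-reproducible reruns.

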