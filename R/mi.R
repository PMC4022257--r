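#' Equal-width bin partition of a variable's range
#'
#' Splits the observed range `[min(x), max(x)]` into `M` equal-width
#' subintervals. The first M-1 bins are closed on the left and open on the
#' right; the rightmost bin is closed on both ends, so every sample falls in
#' exactly one bin.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param M Number of bins (>= 1).
#' @return An object of class `bin_partition`: list with `M` and `edges`
#'   (length M + 1, strictly ascending).
#' @export
make_bins <- function(x, M) {
  if (M < 1) abort("M must be >= 1")
  rng <- range(x)
  if (rng[1] == rng[2]) abort("make_bins(): constant vector has no partition")
  structure(list(M = as.integer(M),
                 edges = seq(rng[1], rng[2], length.out = M + 1)),
            class = "bin_partition")
}

#' Bin index of each sample
#'
#' @param x Numeric vector.
#' @param bins A [make_bins()] partition covering `x`.
#' @return Integer vector of bin assignments in `1..M`.
#' @export
bin_index <- function(x, bins) {
  stopifnot(inherits(bins, "bin_partition"))
  findInterval(x, bins$edges, rightmost.closed = TRUE, all.inside = TRUE)
}

entropy_from_counts <- function(counts, S, base = exp(1)) {
  p <- counts[counts > 0] / S
  -sum(p * log(p, base = base))
}

#' Binned (plug-in) entropy
#'
#' H(X) = -sum_l p(D_l) log p(D_l) with p the empirical bin frequencies;
#' the 0 log 0 terms are dropped.
#'
#' @param x Numeric vector.
#' @param bins A [make_bins()] partition covering `x`; defaults to
#'   `make_bins(x, M)`.
#' @param M Bin count used when `bins` is not given (default
#'   `ceiling(sqrt(length(x)))`).
#' @param base Logarithm base; natural log by default, use 2 for bits.
#' @return Nonnegative entropy value.
#' @export
bin_entropy <- function(x, bins = NULL, M = ceiling(sqrt(length(x))),
                        base = exp(1)) {
  bins <- bins %||% make_bins(x, M)
  idx <- bin_index(x, bins)
  entropy_from_counts(tabulate(idx, bins$M), length(x), base)
}

# MI from two integer bin-index vectors (fast path used by permutations).
mi_from_idx <- function(ix, iy, Mx, My, S, base = exp(1)) {
  joint <- tabulate((ix - 1L) * My + iy, Mx * My)
  hx <- entropy_from_counts(tabulate(ix, Mx), S, base)
  hy <- entropy_from_counts(tabulate(iy, My), S, base)
  hxy <- entropy_from_counts(joint, S, base)
  max(hx + hy - hxy, 0)
}

#' Binned mutual information
#'
#' Plug-in estimate I(X,Y) = H(X) + H(Y) - H(X,Y) over independent
#' equal-width partitions of `M` bins per variable. Nonnegative and
#' symmetric in its arguments; invariant under increasing affine transforms
#' of either variable (the bins move with the data).
#'
#' @param x,y Numeric vectors of equal length S >= 2, both non-constant.
#' @param M Bins per variable; default `ceiling(sqrt(S))`.
#' @param base Logarithm base (natural log by default).
#' @return Mutual information (nats unless `base` changes it).
#' @export
mutual_information <- function(x, y, M = ceiling(sqrt(length(x))),
                               base = exp(1)) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 samples")
  bx <- make_bins(x, M)
  by <- make_bins(y, M)
  mi_from_idx(bin_index(x, bx), bin_index(y, by), bx$M, by$M, length(x), base)
}

#' Permutation-test significance of a mutual-information score
#'
#' The observed MI is compared against a null distribution obtained by
#' uniformly permuting `y`'s entries `n_perm` times; the p-value uses the
#' add-one estimator p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm), which is
#' never zero and never below 1/(n_perm + 1).
#'
#' @inheritParams mutual_information
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return A tibble row: `I`, `p_value`, `n_permutations`.
#' @export
permutation_pvalue <- function(x, y, M = ceiling(sqrt(length(x))),
                               n_perm = 1000, seed = 1, base = exp(1)) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (length(x) != length(y)) abort("x and y must have equal length")
  S <- length(x)
  bx <- make_bins(x, M)
  by <- make_bins(y, M)
  ix <- bin_index(x, bx)
  iy <- bin_index(y, by)
  i_obs <- mi_from_idx(ix, iy, bx$M, by$M, S)
  exceed <- withr::with_seed(seed, {
    n <- 0L
    for (b in seq_len(n_perm)) {
      ip <- iy[sample.int(S)]
      if (mi_from_idx(ix, ip, bx$M, by$M, S) >= i_obs) n <- n + 1L
    }
    n
  })
  i_out <- if (identical(base, exp(1))) i_obs else i_obs / log(base)
  tibble::tibble(I = i_out, p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = as.integer(n_perm))
}

#' Assemble a mutual-information association network
#'
#' Tests every unordered pair of variables with [permutation_pvalue()] and
#' keeps an edge when the p-value passes the threshold for its pair type:
#' `alpha_otu` when at least one endpoint is an OTU (default 0.01),
#' `alpha_env` when both endpoints are environmental factors (default
#' 0.05). Retained edge weight is the observed MI. Variables left without
#' edges stay in the node set, flagged `isolated`; constant variables are
#' untestable and always isolated.
#'
#' Per-pair permutation seeds are derived from `seed` and the sorted pair
#' labels, so the result is invariant to variable ordering.
#'
#' @param matrix A (normalized) abundance tibble with >= 2 variables.
#' @param M Bins per variable; `NULL` (default) uses `ceiling(sqrt(S))`.
#' @param alpha_otu,alpha_env Significance thresholds by pair type.
#' @param n_perm Permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param p_adjust `"none"` (default, raw thresholds) or `"BH"` for a
#'   Benjamini-Hochberg correction applied within each pair-type family
#'   before thresholding.
#' @return An [assoc_network]; its `tests` attribute holds the full tibble
#'   of pairwise results (including rejected pairs).
#' @export
build_network <- function(matrix, M = NULL, alpha_otu = 0.01,
                          alpha_env = 0.05, n_perm = 1000, seed = 1,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  check_abundance_tbl(matrix)
  vals <- abundance_values(matrix)
  S <- ncol(vals)
  M <- M %||% ceiling(sqrt(S))
  vars <- matrix$variable
  types <- matrix$var_type
  testable <- apply(vals, 1, function(r) length(unique(r)) > 1)

  pairs <- which(upper.tri(diag(length(vars))), arr.ind = TRUE)
  rows <- purrr::pmap(list(pairs[, 1], pairs[, 2]), function(i, j) {
    if (!testable[i] || !testable[j]) return(NULL)
    lab <- sort(c(vars[i], vars[j]))
    # permute the second variable in label order for order-invariance
    xy <- if (vars[i] == lab[1]) list(vals[i, ], vals[j, ]) else list(vals[j, ], vals[i, ])
    res <- permutation_pvalue(xy[[1]], xy[[2]], M = M, n_perm = n_perm,
                              seed = derive_seed(seed, lab[1], lab[2]))
    tibble::tibble(node_a = lab[1], node_b = lab[2],
                   weight = res$I, p_value = res$p_value,
                   pair_type = if (types[i] == "env" && types[j] == "env")
                     "env-env" else "otu")
  })
  tests <- dplyr::bind_rows(rows)
  if (nrow(tests) && p_adjust == "BH") {
    tests <- tests |>
      dplyr::group_by(.data$pair_type) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  keep <- if (nrow(tests)) {
    ifelse(tests$pair_type == "env-env",
           tests$p_value <= alpha_env, tests$p_value <= alpha_otu)
  } else {
    logical(0)
  }
  net <- assoc_network(
    nodes = tibble::tibble(node = vars, type = types),
    edges = tests[keep, c("node_a", "node_b", "weight", "p_value")]
  )
  attr(net, "tests") <- tests
  attr(net, "M") <- M
  net
}
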