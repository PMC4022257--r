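#' Simulate amplicon reads with homopolymer errors
#'
#' Generates reads from template sequences under the pyrosequencing error
#' model: each homopolymer run of length >= 2 has its length changed by
#' +/- 1 with probability `homopolymer_error_rate` (run-length miscalls
#' affect multi-base runs; lengths never drop below 1), and each base is
#' substituted with probability `substitution_rate`. Read ids encode the
#' originating template, giving ground truth for clustering benchmarks.
#'
#' @param templates Character vector of template sequences, or `NULL` to
#'   draw `n_templates` random templates of `template_length` whose
#'   pairwise identity is below `max_template_identity`.
#' @param n_templates,template_length Used when `templates` is NULL;
#'   defaults 3 templates of 60 nt (short-amplicon scale).
#' @param reads_per_template Reads generated per template (default 50).
#' @param homopolymer_error_rate Per-run miscall probability (default 0.1).
#' @param substitution_rate Per-base substitution probability (default 0).
#' @param n_samples Each read is assigned uniformly at random to one of
#'   this many samples (`s1..`, default 1), so per-sample compositions
#'   fluctuate as in a real survey.
#' @param max_template_identity Pairwise template identity ceiling; checked
#'   also for user-supplied templates (default 0.9).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A read tibble (`id`, `bases`, `sample_id`, `copies`) with
#'   attribute `truth`: tibble `read_id`, `template` (1-based index).
#' @export
simulate_reads <- function(templates = NULL, n_templates = 3,
                           template_length = 60, reads_per_template = 50,
                           homopolymer_error_rate = 0.1,
                           substitution_rate = 0, n_samples = 1,
                           max_template_identity = 0.9, seed = 1) {
  stopifnot(homopolymer_error_rate >= 0, homopolymer_error_rate <= 1,
            substitution_rate >= 0, substitution_rate <= 1)
  bases4 <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    if (is.null(templates)) {
      templates <- character(0)
      tries <- 0
      while (length(templates) < n_templates) {
        cand <- paste(sample(bases4, template_length, replace = TRUE),
                      collapse = "")
        ok <- !length(templates) ||
          all(seq_identity(cand, templates) < max_template_identity)
        if (ok) templates <- c(templates, cand)
        tries <- tries + 1
        if (tries > 1000 * n_templates) {
          abort("could not draw templates below the identity ceiling")
        }
      }
    }
    if (length(templates) > 1) {
      pid <- outer(seq_along(templates), seq_along(templates),
                   Vectorize(function(i, j) {
                     if (i < j) seq_identity(templates[i], templates[j]) else 0
                   }))
      if (any(pid >= max_template_identity)) {
        abort(sprintf(
          "template pairwise identity %.3f is at or above the ceiling %.3f",
          max(pid), max_template_identity))
      }
    }
    nt <- length(templates)
    rows <- vector("list", nt * reads_per_template)
    idx <- 0
    for (t in seq_len(nt)) {
      chars <- strsplit(templates[t], "", fixed = TRUE)[[1]]
      r <- rle(chars)
      for (j in seq_len(reads_per_template)) {
        lens <- r$lengths
        hit <- lens >= 2 & runif(length(lens)) < homopolymer_error_rate
        if (any(hit)) {
          step <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
          lens[hit] <- pmax(1L, lens[hit] + step)
        }
        seq_chars <- rep.int(r$values, lens)
        if (substitution_rate > 0) {
          sub <- runif(length(seq_chars)) < substitution_rate
          if (any(sub)) {
            seq_chars[sub] <- vapply(seq_chars[sub], function(b) {
              sample(setdiff(bases4, b), 1)
            }, character(1))
          }
        }
        idx <- idx + 1
        rows[[idx]] <- tibble::tibble(
          id = sprintf("t%d_r%03d", t, j),
          bases = paste(seq_chars, collapse = ""),
          sample_id = paste0("s", sample.int(n_samples, 1)),
          copies = 1L,
          template = t
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    truth <- out[, c("id", "template")]
    names(truth)[1] <- "read_id"
    out <- out[, c("id", "bases", "sample_id", "copies")]
    attr(out, "truth") <- truth
    attr(out, "templates") <- templates
    out
  })
}

#' Simulate an abundance matrix with planted linked pairs
#'
#' Rows are standard-normal noise except for `n_linked_pairs` disjoint
#' planted pairs (a, b) with b = rho * a + sqrt(1 - rho^2) * noise, where
#' rho = `link_strength`. Mimics a normalized OTU/environment table in
#' which only the planted pairs carry real associations.
#'
#' @param n_otu,n_env Numbers of OTU and environmental-factor rows.
#' @param S Number of samples (columns).
#' @param n_linked_pairs Planted dependent pairs (drawn among all rows).
#' @param link_strength Correlation rho in (0, 1).
#' @param seed Integer seed.
#' @return A list: `matrix` (abundance tibble, samples `s1..S`) and
#'   `linked_pairs` (tibble `a`, `b` of variable labels).
#' @export
simulate_abundance <- function(n_otu = 20, n_env = 4, S = 20,
                               n_linked_pairs = 0, link_strength = 0.9,
                               seed = 1) {
  n <- n_otu + n_env
  if (2 * n_linked_pairs > n) abort("too many linked pairs for the row count")
  stopifnot(link_strength > 0, link_strength < 1)
  labels <- c(sprintf("OTU_%d", seq_len(n_otu)), sprintf("E%d", seq_len(n_env)))
  types <- c(rep("OTU", n_otu), rep("env", n_env))
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * S), n, S, dimnames = list(labels, paste0("s", seq_len(S))))
    pairs <- tibble::tibble(a = character(0), b = character(0))
    if (n_linked_pairs > 0) {
      picked <- sample(n, 2 * n_linked_pairs)
      ia <- picked[seq_len(n_linked_pairs)]
      ib <- picked[n_linked_pairs + seq_len(n_linked_pairs)]
      vals[ib, ] <- link_strength * vals[ia, , drop = FALSE] +
        sqrt(1 - link_strength^2) * matrix(rnorm(n_linked_pairs * S),
                                           n_linked_pairs, S)
      pairs <- tibble::tibble(a = labels[ia], b = labels[ib])
    }
    list(matrix = abundance_tibble(vals, types), linked_pairs = pairs)
  })
}

#' Planted-partition (stochastic block model) benchmark graph
#'
#' Nodes are split into blocks; within-block node pairs are connected with
#' probability `p_in`, between-block pairs with `p_out` < `p_in`. Edge
#' weights are 1 (`"unit"`) or uniform on (0.5, 1.5) (`"uniform"`).
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_in,p_out Connection probabilities.
#' @param weight_law `"unit"` (default) or `"uniform"`.
#' @param seed Integer seed.
#' @return A list: `network` ([assoc_network], nodes `n1..n`) and `labels`
#'   (integer ground-truth block of each node, named).
#' @export
planted_graph <- function(block_sizes, p_in = 0.3, p_out = 0.02,
                          weight_law = c("unit", "uniform"), seed = 1) {
  weight_law <- match.arg(weight_law)
  if (p_out >= p_in) abort("p_out must be smaller than p_in")
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  ids <- paste0("n", seq_len(n))
  withr::with_seed(seed, {
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- which(upper.tri(A), arr.ind = TRUE)
    p <- ifelse(labels[ut[, 1]] == labels[ut[, 2]], p_in, p_out)
    on <- runif(nrow(ut)) < p
    w <- if (weight_law == "unit") rep(1, sum(on)) else runif(sum(on), 0.5, 1.5)
    A[ut[on, , drop = FALSE]] <- w
    A <- A + t(A)
    net <- network_from_adjacency(A, type = "OTU")
    list(network = net, labels = setNames(labels, ids))
  })
}
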