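#' Collapse identical sequences
#'
#' Dereplicates a read tibble to one row per distinct base string, summing
#' multiplicities. Output is sorted by `copies` descending with ties broken
#' by `id` ascending, which fixes the seed order of the greedy clusterer and
#' makes it independent of input read order.
#'
#' @param reads Tibble with columns `id`, `bases` and optionally `copies`
#'   (default 1) and `sample_id`.
#' @return A read tibble, one row per distinct sequence; `id` is the
#'   lexicographically smallest id among the collapsed reads and
#'   `member_ids` lists all of them.
#' @export
dereplicate <- function(reads) {
  reads <- tibble::as_tibble(reads)
  if (!all(c("id", "bases") %in% names(reads))) {
    abort("reads must have columns 'id' and 'bases'")
  }
  if (!"copies" %in% names(reads)) reads$copies <- 1L
  if (any(reads$copies < 1)) abort("copies must be >= 1")
  if (any(!nzchar(reads$bases))) abort("empty sequence in reads")
  grp <- reads |>
    dplyr::group_by(.data$bases) |>
    dplyr::summarise(
      min_id = min(.data$id),
      copies = as.integer(sum(.data$copies)),
      member_ids = list(sort(.data$id)),
      .groups = "drop"
    ) |>
    dplyr::rename(id = "min_id")
  grp <- grp[order(-grp$copies, grp$id), c("id", "bases", "copies", "member_ids")]
  grp
}

#' Pairwise global alignment identity
#'
#' Identity fraction between two DNA sequences under global alignment with
#' free end gaps (match +1, mismatch -1, gap -2). Identity is the number of
#' matched columns divided by the total number of alignment columns,
#' counting terminal-gap columns, so completely dissimilar sequences score 0.
#'
#' @param a,b Character vectors of DNA sequences (recycled to a common
#'   length).
#' @param match,mismatch,gap Alignment scores.
#' @return Numeric vector of identity fractions in `[0, 1]`.
#' @details When several alignments share the optimal score they can differ
#'   in column count; the pair is therefore aligned in a canonical
#'   (lexicographic) argument order so the reported identity is exactly
#'   symmetric.
#' @examples
#' seq_identity("ACGTACGT", "ACGTACGA")  # 0.875
#' @export
seq_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  .cpp_identity(a, b, match, mismatch, gap)
}

#' Homopolymer-neighbor sequences of a seed
#'
#' Enumerates every sequence reachable from `seed` by changing the length of
#' exactly one homopolymer run by up to `max_run_delta` bases in either
#' direction (run lengths never drop below 1), plus the seed itself.
#' Pyrosequencing's dominant error mode is mis-called run lengths, so
#' comparing incoming reads against this neighbor set lets a greedy
#' clusterer absorb homopolymer errors that push raw identity below
#' threshold.
#'
#' @param seed A DNA string.
#' @param max_run_delta Maximum run-length change (default 1).
#' @return Character vector of unique neighbor sequences (including `seed`).
#' @examples
#' neighbor_seeds("AAT")  # "AAT" "AT" "AAAT" "AATT"
#' @export
neighbor_seeds <- function(seed, max_run_delta = 1L) {
  stopifnot(nzchar(seed), max_run_delta >= 1)
  chars <- strsplit(seed, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  nruns <- length(r$lengths)
  out <- seed
  for (k in seq_len(nruns)) {
    len <- r$lengths[k]
    deltas <- setdiff(seq(-max_run_delta, max_run_delta), 0)
    for (d in deltas) {
      newlen <- len + d
      if (newlen < 1) next
      lens <- r$lengths
      lens[k] <- newlen
      out <- c(out, paste(rep.int(r$values, lens), collapse = ""))
    }
  }
  unique(out)
}

#' Greedy OTU clustering with neighbor seeds
#'
#' Clusters amplicon reads into OTUs. Reads are dereplicated and visited in
#' abundance order; each read joins the first existing cluster whose
#' neighbor-seed set (homopolymer variants of the founding seed, see
#' [neighbor_seeds()]) contains a sequence at identity >= `threshold`,
#' otherwise it founds a new cluster. A size-based refinement then dissolves
#' clusters smaller than `min_cluster_size` reads and reassigns their
#' members to the surviving cluster of maximal seed identity (ties: larger
#' cluster, then earlier-founded cluster).
#'
#' @param reads Read tibble (`id`, `bases`, optional `copies`, `sample_id`).
#' @param threshold Identity threshold in (0, 1]; default 0.97, the
#'   conventional species-level OTU cutoff.
#' @param max_run_delta Homopolymer radius of the neighbor-seed sets.
#' @param min_cluster_size Clusters with fewer member reads (counting
#'   multiplicities) are dissolved in the refinement step; default 2
#'   (singleton dissolution).
#' @return An object of class `otu_clustering`: a tibble with one row per
#'   input read (`otu`, `seed_id`, `read_id`), with attributes `seeds`
#'   (per-OTU seed tibble) and the parameters used.
#' @export
cluster_otus <- function(reads, threshold = 0.97, max_run_delta = 1L,
                         min_cluster_size = 2L) {
  if (nrow(reads) == 0) abort("cluster_otus(): no reads")
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  derep <- dereplicate(reads)

  seeds_bases <- character(0)
  seeds_id <- character(0)
  nbr_sets <- list()
  assign <- integer(nrow(derep))
  for (i in seq_len(nrow(derep))) {
    q <- derep$bases[i]
    hit <- 0L
    for (k in seq_along(nbr_sets)) {
      best <- .cpp_identity_max(q, nbr_sets[[k]], stop_at = threshold)
      if (best >= threshold) { hit <- k; break }
    }
    if (hit == 0L) {
      seeds_bases <- c(seeds_bases, q)
      seeds_id <- c(seeds_id, derep$id[i])
      nbr_sets[[length(nbr_sets) + 1L]] <- neighbor_seeds(q, max_run_delta)
      hit <- length(nbr_sets)
    }
    assign[i] <- hit
  }

  sizes <- vapply(seq_along(seeds_bases), function(k) {
    sum(derep$copies[assign == k])
  }, numeric(1))

  # refinement: dissolve undersized clusters, reassign members by best seed
  # identity among survivors (ties -> larger cluster, then lower index)
  small <- which(sizes < min_cluster_size)
  keep <- which(sizes >= min_cluster_size)
  if (length(small) && length(keep)) {
    for (i in which(assign %in% small)) {
      ids <- seq_identity(derep$bases[i], seeds_bases[keep])
      best <- max(ids)
      cand <- keep[ids == best]
      if (length(cand) > 1) {
        cand <- cand[order(-sizes[cand], cand)]
      }
      assign[i] <- cand[1]
    }
  } else {
    keep <- seq_along(seeds_bases)
  }

  # relabel OTUs in order of appearance among survivors
  used <- unique(assign)
  used <- used[order(match(used, seq_along(seeds_bases)))]
  relab <- match(assign, used)

  members <- tibble::tibble(
    otu = paste0("OTU_", relab),
    seed_id = seeds_id[used][relab],
    read_id = derep$member_ids,
    derep_id = derep$id
  ) |>
    tidyr::unnest(cols = "read_id")

  seeds_tbl <- tibble::tibble(
    otu = paste0("OTU_", seq_along(used)),
    seed_id = seeds_id[used],
    seed_bases = seeds_bases[used]
  )
  out <- members[, c("otu", "seed_id", "read_id")]
  structure(out,
            class = c("otu_clustering", class(out)),
            seeds = seeds_tbl,
            threshold = threshold,
            max_run_delta = max_run_delta,
            min_cluster_size = min_cluster_size)
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("<otu_clustering> %d reads in %d OTUs (threshold %.2f)\n",
              nrow(x), dplyr::n_distinct(x$otu), attr(x, "threshold")))
  NextMethod()
}

#' OTU-by-sample count table from a clustering
#'
#' @param clustering An `otu_clustering` from [cluster_otus()].
#' @param reads The read tibble that was clustered; `sample_id` and `copies`
#'   are taken from it.
#' @return A list with `counts` (tibble: `variable`, `var_type = "OTU"`,
#'   one column per sample, integer counts N_us) and `totals` (named
#'   per-sample read totals N_s over all input reads).
#' @export
otu_count_table <- function(clustering, reads) {
  stopifnot(inherits(clustering, "otu_clustering"))
  reads <- tibble::as_tibble(reads)
  if (!"copies" %in% names(reads)) reads$copies <- 1L
  if (!"sample_id" %in% names(reads) || anyNA(reads$sample_id)) {
    abort("otu_count_table(): reads need a complete 'sample_id' column")
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(clustering), reads[, c("id", "sample_id", "copies")],
    by = c(read_id = "id")
  )
  counts <- joined |>
    dplyr::group_by(.data$otu, .data$sample_id) |>
    dplyr::summarise(n = sum(.data$copies), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  samples <- sort(setdiff(names(counts), "otu"))
  counts <- counts[order(as.integer(sub("OTU_", "", counts$otu))),
                   c("otu", samples)]
  totals <- tapply(reads$copies, reads$sample_id, sum)
  totals <- setNames(as.integer(totals), names(totals))[samples]
  tbl <- dplyr::bind_cols(
    tibble::tibble(variable = counts$otu, var_type = "OTU"),
    counts[, samples]
  )
  list(counts = tbl, totals = totals)
}
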