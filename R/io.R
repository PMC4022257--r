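#' Read amplicon reads from a FASTA file
#'
#' Parses a FASTA file into a read tibble. Sequences are uppercased and must
#' use the alphabet `A`, `C`, `G`, `T`, `N`. Dereplication size annotations of
#' the form `;size=N` in the header are honoured as read multiplicities.
#'
#' @param path Path to a FASTA file.
#' @param sample_map Optional data frame with columns `read_id`, `sample_id`
#'   assigning each read to its sample of origin (see [read_sample_map()]).
#' @return A tibble with columns `id`, `bases`, `sample_id`, `copies` — one
#'   row per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2;size=3", "GGGA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, sample_map = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  copies <- integer(0)
  cur_id <- NULL
  cur_seq <- character(0)
  cur_line <- 0L
  flush_record <- function() {
    s <- toupper(paste0(cur_seq, collapse = ""))
    if (!nzchar(s)) {
      abort(sprintf("FASTA parse error at line %d: record '%s' has an empty sequence",
                    cur_line, cur_id))
    }
    if (grepl("[^ACGTN]", s)) {
      ch <- regmatches(s, regexpr("[^ACGTN]", s))
      abort(sprintf("FASTA parse error near line %d: record '%s' contains invalid character '%s'",
                    cur_line, cur_id, ch))
    }
    size <- 1L
    id <- cur_id
    m <- regmatches(id, regexec(";size=([0-9]+);?$", id))[[1]]
    if (length(m) == 2) {
      size <- as.integer(m[2])
      id <- sub(";size=[0-9]+;?$", "", id)
    }
    ids <<- c(ids, id)
    seqs <<- c(seqs, s)
    copies <<- c(copies, size)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      if (!is.null(cur_id)) flush_record()
      cur_id <- trimws(sub("^>", "", ln))
      if (!nzchar(cur_id)) {
        abort(sprintf("FASTA parse error at line %d: empty header", i))
      }
      cur_seq <- character(0)
      cur_line <- i
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) {
        abort(sprintf("FASTA parse error at line %d: sequence before any header", i))
      }
      cur_seq <- c(cur_seq, trimws(ln))
    }
  }
  if (!is.null(cur_id)) flush_record()
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate read ids in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble::tibble(id = ids, bases = seqs,
                        sample_id = NA_character_, copies = copies)
  if (!is.null(sample_map)) {
    check_sample_map(sample_map)
    idx <- match(out$id, sample_map$read_id)
    if (anyNA(idx)) {
      abort(sprintf("reads missing from sample map: %s",
                    paste(head(out$id[is.na(idx)], 5), collapse = ", ")))
    }
    out$sample_id <- sample_map$sample_id[idx]
  }
  out
}

#' Write reads to a FASTA file
#'
#' @param reads Tibble with columns `id`, `bases` (and optionally `copies`,
#'   written as `;size=N` when greater than 1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  hdr <- reads$id
  if ("copies" %in% names(reads)) {
    hdr <- ifelse(reads$copies > 1L,
                  paste0(hdr, ";size=", reads$copies), hdr)
  }
  writeLines(rbind(paste0(">", hdr), reads$bases), path)
  invisible(path)
}

check_sample_map <- function(map) {
  if (!all(c("read_id", "sample_id") %in% names(map))) {
    abort("sample map must have columns 'read_id' and 'sample_id'")
  }
  if (anyDuplicated(map$read_id)) {
    abort("sample map: every read_id must appear exactly once")
  }
  if (nrow(map) == 0) abort("sample map is empty")
  invisible(map)
}

#' Read a read-to-sample mapping
#'
#' A two-column TSV (`read_id`, `sample_id`); extra columns (for example a
#' grouping column such as season) are preserved.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with at least `read_id` and `sample_id`.
#' @export
read_sample_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_sample_map(map)
  map
}

#' Read a numeric variables/samples table
#'
#' Reads a TSV with row labels in the first column and sample (or variable)
#' labels in the header into the package's standard orientation:
#' variables in rows, samples in columns.
#'
#' @param path Path to a TSV file.
#' @param orientation `"variables-by-samples"` (default) or
#'   `"samples-by-variables"` if the file stores one sample per row.
#' @param var_type Variable type recorded for every row: `"OTU"` or `"env"`.
#'   Ignored if the file already carries a `var_type` column.
#' @return An abundance tibble: columns `variable`, `var_type`, then one
#'   numeric column per sample.
#' @export
read_table <- function(path,
                       orientation = c("variables-by-samples",
                                       "samples-by-variables"),
                       var_type = c("OTU", "env")) {
  orientation <- match.arg(orientation)
  var_type <- match.arg(var_type)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("table %s needs row labels plus data", path))
  labels <- raw[[1]]
  has_type <- "var_type" %in% names(raw)[-1]
  type_col <- if (has_type) raw[["var_type"]] else NULL
  body <- raw[, setdiff(names(raw)[-1], "var_type"), drop = FALSE]
  if (anyDuplicated(labels)) {
    abort(sprintf("duplicate row labels in %s: %s", path,
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (anyDuplicated(names(body))) {
    abort(sprintf("duplicate column labels in %s: %s", path,
                  paste(unique(names(body)[duplicated(names(body))]),
                        collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(labels, names(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                  path, labels[bad[1]], colnames(vals)[bad[2]]))
  }
  if (orientation == "samples-by-variables") {
    vals <- t(vals)
    if (has_type) abort("var_type column requires variables-by-samples orientation")
  }
  types <- if (has_type && orientation == "variables-by-samples") {
    type_col
  } else {
    rep(var_type, nrow(vals))
  }
  abundance_tibble(vals, types)
}

#' Write an abundance tibble to TSV
#'
#' Variables in rows, samples in columns; `var_type` is kept as a column so
#' the file round-trips through [read_table()].
#'
#' @param matrix An abundance tibble (`variable`, `var_type`, samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(matrix, path) {
  check_abundance_tbl(matrix)
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}

#' Write an association network
#'
#' The edge-list format writes one line per undirected edge with
#' `node_a < node_b` lexicographically, columns `node_a`, `node_b`, `weight`,
#' `p_value`, `node_a_type`, `node_b_type`; weights keep full double
#' precision so the file round-trips losslessly. GraphML output (via igraph)
#' additionally preserves isolated nodes.
#'
#' @param net An [assoc_network] object.
#' @param path Output path.
#' @param format `"edge-list"` (TSV) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "assoc_network"))
  if (format == "edge-list") {
    ed <- net$edges
    type_of <- setNames(net$nodes$type, net$nodes$node)
    out <- tibble::tibble(
      node_a = ed$node_a, node_b = ed$node_b,
      weight = format(ed$weight, digits = 17, scientific = TRUE, trim = TRUE),
      p_value = format(ed$p_value, digits = 17, scientific = TRUE, trim = TRUE),
      node_a_type = unname(type_of[ed$node_a]),
      node_b_type = unname(type_of[ed$node_b])
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an association network
#'
#' @param path Path to an edge-list TSV written by [write_network()] or a
#'   GraphML file.
#' @param format `"edge-list"` or `"graphml"`.
#' @return An [assoc_network].
#' @export
read_network <- function(path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-list") {
    ed <- readr::read_tsv(path, col_types = readr::cols(
      node_a = "c", node_b = "c", weight = "d", p_value = "d",
      node_a_type = "c", node_b_type = "c"
    ), progress = FALSE)
    nodes <- tibble::tibble(
      node = c(ed$node_a, ed$node_b),
      type = c(ed$node_a_type, ed$node_b_type)
    )
    nodes <- dplyr::distinct(nodes)
    assoc_network(nodes, ed[, c("node_a", "node_b", "weight", "p_value")])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    from_igraph(g)
  }
}

#' Write community assignments
#'
#' TSV with one row per node: `node`, `hard_label`, then `r` membership
#' columns `u1..ur` exposing the fuzzy view.
#'
#' @param model A [community_model] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(model, path) {
  stopifnot(inherits(model, "community_model"))
  u <- t(model$U)
  colnames(u) <- paste0("u", seq_len(model$r))
  out <- dplyr::bind_cols(
    tibble::tibble(node = model$nodes, hard_label = model$labels),
    tibble::as_tibble(u)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read community assignments written by [write_communities()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with `node`, `hard_label`, and membership columns.
#' @export
read_communities <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(node = "c", .default = "d"),
                  progress = FALSE)
}
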