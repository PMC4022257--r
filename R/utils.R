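# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed from a base seed plus arbitrary string/number
# keys. Keeps every derived seed below 2^31 and independent of iteration
# order, so e.g. permutation p-values do not depend on variable ordering.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\x1f")
  codes <- utf8ToInt(key)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Columns of an abundance tibble that hold sample values.
sample_cols <- function(tbl) {
  setdiff(names(tbl), c("variable", "var_type"))
}

# variables x samples numeric matrix from an abundance tibble.
abundance_values <- function(tbl) {
  sc <- sample_cols(tbl)
  m <- as.matrix(tbl[, sc, drop = FALSE])
  rownames(m) <- tbl$variable
  storage.mode(m) <- "double"
  m
}

# Rebuild an abundance tibble from a matrix plus variable types.
abundance_tibble <- function(values, var_type) {
  stopifnot(nrow(values) == length(var_type))
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  dplyr::bind_cols(
    tibble::tibble(variable = rownames(values), var_type = var_type),
    out
  )
}

check_abundance_tbl <- function(tbl, arg = "matrix") {
  if (!is.data.frame(tbl)) {
    abort(sprintf("`%s` must be a data frame", arg))
  }
  if (!all(c("variable", "var_type") %in% names(tbl))) {
    abort(sprintf("`%s` must have 'variable' and 'var_type' columns", arg))
  }
  if (anyDuplicated(tbl$variable)) {
    abort(sprintf("duplicate variable labels in `%s`: %s", arg,
                  paste(unique(tbl$variable[duplicated(tbl$variable)]),
                        collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$var_type), c("OTU", "env"))
  if (length(bad)) {
    abort(sprintf("unknown var_type value(s): %s", paste(bad, collapse = ", ")))
  }
  sc <- sample_cols(tbl)
  if (length(sc) < 2) abort(sprintf("`%s` needs at least 2 sample columns", arg))
  invisible(tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
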