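#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end flow
#' (cluster -> abundance -> network -> communities -> topology) with the
#' package defaults, validating ranges.
#'
#' @param threshold,max_run_delta,min_cluster_size Clustering parameters,
#'   see [cluster_otus()].
#' @param min_count,min_nonzero Abundance filters, see
#'   [relative_abundance()] and [filter_sparse()].
#' @param M Bins per variable for mutual information; `NULL` = auto
#'   (`ceiling(sqrt(S))`).
#' @param alpha_otu,alpha_env,n_perm Network significance parameters, see
#'   [build_network()].
#' @param r_min,r_max,restarts,beta Community-detection parameters, see
#'   [detect_communities()]; `r_max = NULL` means `min(n, 20)`.
#' @param group_by Optional column of the sample map (e.g. a season
#'   column); when set, the network and community stages run once per group
#'   over that group's samples.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 0.97, max_run_delta = 1L,
                            min_cluster_size = 2L, min_count = 5,
                            min_nonzero = 3, M = NULL, alpha_otu = 0.01,
                            alpha_env = 0.05, n_perm = 1000, r_min = 2,
                            r_max = NULL, restarts = 10, beta = 0.5,
                            group_by = NULL, seed = 1) {
  stopifnot(threshold > 0, threshold <= 1, max_run_delta >= 1,
            min_cluster_size >= 1, min_count >= 0, min_nonzero >= 1,
            is.null(M) || M >= 1, alpha_otu > 0, alpha_otu <= 1,
            alpha_env > 0, alpha_env <= 1, n_perm >= 1, r_min >= 1,
            is.null(r_max) || r_max >= r_min, restarts >= 1,
            beta > 0, beta <= 1)
  structure(list(threshold = threshold, max_run_delta = max_run_delta,
                 min_cluster_size = min_cluster_size, min_count = min_count,
                 min_nonzero = min_nonzero, M = M, alpha_otu = alpha_otu,
                 alpha_env = alpha_env, n_perm = n_perm, r_min = r_min,
                 r_max = r_max, restarts = restarts, beta = beta,
                 group_by = group_by, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

run_group <- function(matrix_tbl, config, outdir) {
  net <- build_network(matrix_tbl, M = config$M,
                       alpha_otu = config$alpha_otu,
                       alpha_env = config$alpha_env,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, "network"))
  write_network(net, file.path(outdir, "network.tsv"))
  n <- nrow(net$nodes)
  r_max <- config$r_max %||% min(n, 20)
  model <- NULL
  if (nrow(net$edges) > 0) {
    model <- detect_communities(net, r_min = min(config$r_min, n),
                                r_max = min(r_max, n),
                                restarts = config$restarts,
                                seed = derive_seed(config$seed, "snmf"),
                                beta = config$beta)
    write_communities(model, file.path(outdir, "communities.tsv"))
  } else {
    warn("no significant associations; skipping community detection")
  }
  rep <- topology_report(net, model)
  readr::write_tsv(rep, file.path(outdir, "report.tsv"), progress = FALSE)
  list(network = net, communities = model, report = rep)
}

#' Run the full association-mining pipeline
#'
#' Orchestrates OTU clustering, abundance filtering and normalization,
#' mutual-information network construction, community detection, and the
#' topology report, writing every intermediate artifact plus a JSON
#' manifest of the configuration to `outdir`. Rerunning with the same
#' inputs and config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param reads Path to a FASTA file of amplicon reads.
#' @param samples Path to the read-to-sample TSV map (see
#'   [read_sample_map()]).
#' @param env Optional path to an environmental-factor TSV
#'   (variables-by-samples); `NULL` builds an OTU-only network.
#' @param outdir Output directory (created if needed).
#' @return A list per group: `network`, `communities`, `report`; plus
#'   `clustering` and `matrix` at the top level.
#' @export
run_pipeline <- function(config, reads, samples, env = NULL, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  smap <- read_sample_map(samples)
  rds <- read_fasta(reads, sample_map = smap)
  clustering <- cluster_otus(rds, threshold = config$threshold,
                             max_run_delta = config$max_run_delta,
                             min_cluster_size = config$min_cluster_size)
  readr::write_tsv(tibble::as_tibble(clustering),
                   file.path(outdir, "otus.tsv"), progress = FALSE)
  ct <- otu_count_table(clustering, rds)
  write_table(ct$counts, file.path(outdir, "counts.tsv"))
  abund <- relative_abundance(ct$counts, totals = ct$totals,
                              min_count = config$min_count)
  abund <- filter_sparse(abund, min_nonzero = config$min_nonzero)
  envtbl <- if (!is.null(env)) read_table(env, var_type = "env") else NULL
  mat <- bind_abundance(abund, envtbl)
  # drop constant rows (cannot be normalized or binned)
  vals <- abundance_values(mat)
  mat <- mat[apply(vals, 1, function(r) length(unique(r)) > 1), ]
  if (nrow(mat) < 2) {
    abort("pipeline: fewer than 2 non-constant variables survive filtering")
  }
  mat <- zero_mean_normalize(mat)
  write_table(mat, file.path(outdir, "matrix.tsv"))

  groups <- list(all = sample_cols(mat))
  if (!is.null(config$group_by)) {
    if (!config$group_by %in% names(smap)) {
      abort(sprintf("group_by column '%s' not in the sample map", config$group_by))
    }
    gmap <- dplyr::distinct(smap[, c("sample_id", config$group_by)])
    groups <- split(gmap$sample_id, gmap[[config$group_by]])
  }
  results <- purrr::imap(groups, function(cols, gname) {
    sub <- mat[, c("variable", "var_type", intersect(sample_cols(mat), cols))]
    keep <- apply(abundance_values(sub), 1,
                  function(r) length(unique(r)) > 1)
    sub <- sub[keep, ]
    gdir <- if (length(groups) == 1) outdir else file.path(outdir, gname)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    run_group(sub, config, gdir)
  })
  manifest <- list(
    package = "seapattern",
    version = as.character(utils::packageVersion("seapattern")),
    config = unclass(config),
    inputs = list(reads = basename(reads), samples = basename(samples),
                  env = if (is.null(env)) NULL else basename(env)),
    groups = names(groups)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(list(clustering = clustering, matrix = mat), results)
}
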