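test_that("dereplication sums multiplicities and sorts deterministically", {
  reads <- tibble::tibble(id = c("r3", "r1", "r2"),
                          bases = c("AAT", "AAA", "AAA"))
  d <- dereplicate(reads)
  expect_equal(d$bases, c("AAA", "AAT"))
  expect_equal(d$copies, c(2L, 1L))
  expect_equal(d$id, c("r1", "r3"))
  expect_equal(sort(unlist(d$member_ids)), c("r1", "r2", "r3"))

  # all-distinct input keeps length, copies 1
  reads2 <- tibble::tibble(id = c("a", "b"), bases = c("ACG", "TGC"))
  expect_equal(dereplicate(reads2)$copies, c(1L, 1L))

  # order independence
  shuffled <- reads[c(2, 3, 1), ]
  expect_equal(dereplicate(shuffled), d)
})

test_that("alignment identity matches its fixed points and the DP oracle", {
  expect_equal(seq_identity("ACGT", "ACGT"), 1)
  expect_equal(seq_identity("AAAA", "TTTT"), 0)
  expect_equal(seq_identity("ACGTACGT", "ACGTACGA"), 0.875)

  set.seed(71)
  for (i in 1:60) {
    L <- sample(4:14, 1)
    a <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    bb <- strsplit(a, "")[[1]]
    for (k in seq_len(sample(0:3, 1))) {
      p <- sample(length(bb), 1)
      bb <- if (runif(1) < 0.5 && length(bb) > 1) bb[-p] else
        append(bb, sample(c("A", "C", "G", "T"), 1), p)
    }
    b <- paste(bb, collapse = "")
    canon <- sort(c(a, b))
    expect_equal(seq_identity(a, b),
                 oracle_nw_identity(canon[1], canon[2]), tolerance = 1e-12)
    expect_equal(seq_identity(a, b), seq_identity(b, a))
  }
})

test_that("the DP oracle's optimal score matches exhaustive alignment enumeration", {
  # validates the oracle itself on tiny strings where every alignment can be
  # enumerated recursively
  set.seed(5)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), TRUE), collapse = "")
    expect_equal(oracle_nw_score(a, b), oracle_best_score(a, b))
  }
  expect_equal(oracle_best_score("ACGTACGT", "ACGTACGA"), 6)
})

test_that("neighbor seeds enumerate single-run length edits", {
  expect_setequal(neighbor_seeds("AAT"), c("AAT", "AT", "AAAT", "AATT"))
  expect_setequal(neighbor_seeds("A"), c("A", "AA"))
  expect_setequal(neighbor_seeds("AAT", max_run_delta = 2),
                  c("AAT", "AT", "AAAT", "AAAAT", "AATT", "AATTT"))
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), TRUE), collapse = "")
    nb <- neighbor_seeds(s)
    expect_true(s %in% nb)
    expect_equal(anyDuplicated(nb), 0)
    # every neighbor differs from the seed by exactly one run-length edit
    r0 <- rle(strsplit(s, "")[[1]])
    for (v in setdiff(nb, s)) {
      r1 <- rle(strsplit(v, "")[[1]])
      expect_equal(r1$values, r0$values)
      expect_equal(sum(r1$lengths != r0$lengths), 1)
      expect_lte(max(abs(r1$lengths - r0$lengths)), 1)
    }
  }
})

test_that("greedy clustering partitions reads and recovers exact templates", {
  # 100 exact copies of one template -> one cluster of 100
  tmpl <- "ACGGTTACGGAACCTGATCCGA"
  reads <- tibble::tibble(id = sprintf("r%03d", 1:100), bases = tmpl)
  cl <- cluster_otus(reads)
  expect_equal(dplyr::n_distinct(cl$otu), 1)
  expect_equal(nrow(cl), 100)
  expect_setequal(cl$read_id, reads$id)

  # two dissimilar templates, 50 reads each -> two clusters of 50
  t1 <- "ACGGTTACGGAACCTGATCCGAATC"
  t2 <- "TTACGCACCAGGTATTCACAGGTAC"
  expect_lt(seq_identity(t1, t2), 0.6)
  reads2 <- tibble::tibble(id = sprintf("r%03d", 1:100),
                           bases = rep(c(t1, t2), each = 50))
  cl2 <- cluster_otus(reads2, threshold = 0.97)
  tab <- table(cl2$otu)
  expect_equal(sort(unname(as.vector(tab))), c(50, 50))

  # homopolymer +/-1 variants merge into the template's cluster
  variants <- setdiff(neighbor_seeds(t1), t1)
  reads3 <- tibble::tibble(
    id = sprintf("r%03d", seq_len(30 + length(variants))),
    bases = c(rep(t1, 30), variants))
  cl3 <- cluster_otus(reads3, threshold = 0.97)
  expect_equal(dplyr::n_distinct(cl3$otu), 1)
})

test_that("clustering output is a partition independent of read order", {
  rds <- simulate_reads(homopolymer_error_rate = 0.05, seed = 11)
  cl <- cluster_otus(rds)
  expect_setequal(cl$read_id, rds$id)
  expect_equal(anyDuplicated(cl$read_id), 0)
  shuf <- rds[sample(nrow(rds)), ]
  cl2 <- cluster_otus(shuf)
  m <- dplyr::inner_join(tibble::as_tibble(cl), tibble::as_tibble(cl2),
                         by = "read_id")
  expect_equal(m$otu.x, m$otu.y)
})

test_that("raising the threshold never lowers the pre-refinement cluster count", {
  for (s in 1:5) {
    rds <- simulate_reads(homopolymer_error_rate = 0.08, seed = s,
                          reads_per_template = 25)
    ks <- vapply(c(0.90, 0.95, 0.99), function(th) {
      # min_cluster_size 1 disables refinement, exposing the greedy pass
      dplyr::n_distinct(cluster_otus(rds, threshold = th,
                                     min_cluster_size = 1)$otu)
    }, numeric(1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("homopolymer-only errors around k templates yield exactly k clusters", {
  # miscall rate low enough that multi-run-error reads are rare; such reads
  # appear as singletons, are dissolved and reassigned to the right template
  for (s in 1:6) {
    rds <- simulate_reads(n_templates = 3, homopolymer_error_rate = 0.02,
                          seed = s)
    cl <- cluster_otus(rds, threshold = 0.97)
    expect_equal(dplyr::n_distinct(cl$otu), 3)
    truth <- attr(rds, "truth")
    j <- dplyr::inner_join(tibble::as_tibble(cl), truth, by = "read_id")
    purity <- j |>
      dplyr::summarise(p = max(table(.data$template)) / dplyr::n(),
                       .by = "otu")
    expect_true(all(purity$p == 1))
  }
})

test_that("count tables aggregate copies per sample with full totals", {
  reads <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    bases = c("AACC", "AACC", "AACC", "GGTT"),
    sample_id = c("s1", "s1", "s2", "s2"),
    copies = c(2L, 1L, 1L, 4L))
  cl <- cluster_otus(reads, min_cluster_size = 1)
  ct <- otu_count_table(cl, reads)
  vals <- abundance_values(ct$counts)
  expect_equal(unname(ct$totals), c(3L, 5L))
  expect_equal(sum(vals), 8)
  expect_equal(unname(colSums(vals)), unname(as.numeric(ct$totals)))
})
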