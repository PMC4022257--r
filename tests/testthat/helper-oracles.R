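# Independent reference implementations used as oracles. Deliberately naive:
# plain R, explicit loops, no code shared with the package internals.

# Free-end-gap Needleman-Wunsch identity, full DP matrix with traceback.
# Same scoring scheme and tie-break order as the package kernel (diag, up,
# left; end cell scanned (n,m), last row right-to-left, last column
# bottom-to-top, strict improvement).
oracle_nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  Tb <- matrix(0L, n + 1, m + 1)  # 0 diag, 1 up, 2 left
  Tb[1, -1] <- 2L
  Tb[-1, 1] <- 1L
  for (i in 1:n) for (j in 1:m) {
    sd <- S[i, j] + if (A[i] == B[j]) match else mismatch
    su <- S[i, j + 1] + gap
    sl <- S[i + 1, j] + gap
    best <- sd; dir <- 0L
    if (su > best) { best <- su; dir <- 1L }
    if (sl > best) { best <- sl; dir <- 2L }
    S[i + 1, j + 1] <- best
    Tb[i + 1, j + 1] <- dir
  }
  bi <- n; bj <- m; best <- S[n + 1, m + 1]
  for (j in (m - 1):0) if (S[n + 1, j + 1] > best) { best <- S[n + 1, j + 1]; bi <- n; bj <- j }
  for (i in (n - 1):0) if (S[i + 1, m + 1] > best) { best <- S[i + 1, m + 1]; bi <- i; bj <- m }
  matches <- 0; cols <- (n - bi) + (m - bj)
  i <- bi; j <- bj
  while (i > 0 || j > 0) {
    dir <- Tb[i + 1, j + 1]
    if (i > 0 && j > 0 && dir == 0L) {
      if (A[i] == B[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && (dir == 1L || j == 0)) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  if (cols == 0) 0 else matches / cols
}

# Optimal score of the same DP (no traceback needed).
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (A[i] == B[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  max(S[n + 1, ], S[, m + 1])
}

# Exhaustive maximum alignment score over every global alignment with free
# end gaps, by recursion. Only usable for very short strings.
oracle_best_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  rec <- function(i, j) {
    # score of aligning A[i..n] vs B[j..m], trailing gaps free at the ends
    if (i > n || j > m) return(0)  # remaining tail is a free end gap
    best <- -Inf
    best <- max(best, rec(i + 1, j + 1) + if (A[i] == B[j]) match else mismatch)
    best <- max(best, rec(i + 1, j) + gap)
    best <- max(best, rec(i, j + 1) + gap)
    best
  }
  # free leading gaps: start anywhere along the first row/column
  best <- -Inf
  for (i in 1:(n + 1)) best <- max(best, rec(i, 1))
  for (j in 1:(m + 1)) best <- max(best, rec(1, j))
  best
}

# Plug-in entropy / joint entropy / MI by explicit summation over an
# M x M contingency table with equal-width bins (last bin right-closed).
oracle_bin_counts <- function(x, M) {
  lo <- min(x); hi <- max(x)
  e <- lo + (0:M) * (hi - lo) / M
  e[M + 1] <- hi  # close the partition at the exact maximum
  cnt <- numeric(M)
  for (v in x) {
    for (l in 1:M) {
      inb <- v >= e[l] && (v < e[l + 1] || (l == M && v <= e[l + 1]))
      if (inb) { cnt[l] <- cnt[l] + 1; break }
    }
  }
  cnt
}

oracle_entropy <- function(counts, S) {
  h <- 0
  for (c in counts) if (c > 0) h <- h - (c / S) * log(c / S)
  h
}

oracle_mi <- function(x, y, M) {
  S <- length(x)
  lo_x <- min(x); hi_x <- max(x); ex <- lo_x + (0:M) * (hi_x - lo_x) / M
  lo_y <- min(y); hi_y <- max(y); ey <- lo_y + (0:M) * (hi_y - lo_y) / M
  ex[M + 1] <- hi_x; ey[M + 1] <- hi_y  # close the partitions at the maxima
  inbin <- function(v, e, l) v >= e[l] && (v < e[l + 1] || (l == M && v <= e[l + 1]))
  joint <- matrix(0, M, M)
  for (s in 1:S) {
    for (l in 1:M) for (g in 1:M) {
      if (inbin(x[s], ex, l) && inbin(y[s], ey, g)) joint[l, g] <- joint[l, g] + 1
    }
  }
  hx <- oracle_entropy(rowSums(joint), S)
  hy <- oracle_entropy(colSums(joint), S)
  hxy <- oracle_entropy(as.vector(joint), S)
  hx + hy - hxy
}

# Newman modularity of a hard partition on a weighted adjacency matrix,
# summed community by community: Q = sum_c [ w_c / W - (d_c / 2W)^2 ],
# with W the total edge weight, w_c the weight inside community c and d_c
# its total degree.
oracle_newman_modularity <- function(A, labels) {
  W <- sum(A) / 2
  q <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    w_c <- sum(A[idx, idx, drop = FALSE]) / 2
    d_c <- sum(A[idx, , drop = FALSE])
    q <- q + w_c / W - (d_c / (2 * W))^2
  }
  q
}

# Average local clustering coefficient by explicit triangle / triple counts.
oracle_avg_clustering <- function(A) {
  A <- (A > 0) * 1
  n <- nrow(A)
  tot <- 0
  for (i in 1:n) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (u in nb) for (v in nb) if (u < v && A[u, v] > 0) links <- links + 1
    tot <- tot + links / (k * (k - 1) / 2)
  }
  tot / n
}

# All set partitions of 1..n as a list of label vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxl) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in 1:(maxl + 1)) rec(c(labels, l), max(maxl, l))
  }
  rec(1L, 1L)
  out
}

one_hot <- function(labels, r = max(labels)) {
  U <- matrix(0, r, length(labels))
  U[cbind(labels, seq_along(labels))] <- 1
  U
}

# Small deterministic fixture network: two weighted triangles joined by a
# bridge.
fixture_barbell <- function() {
  A <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  A[1, 2] <- A[1, 3] <- A[2, 3] <- 1
  A[4, 5] <- A[4, 6] <- A[5, 6] <- 1
  A[3, 4] <- 0.5
  A <- A + t(A)
  network_from_adjacency(A)
}
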