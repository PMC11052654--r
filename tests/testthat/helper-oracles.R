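# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

metric_dist <- function(x, y, metric) {
  switch(metric,
         manhattan = sum(abs(x - y)),
         euclidean = sqrt(sum((x - y)^2)),
         chebyshev = max(abs(x - y)),
         cosine = {
           nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
           sim <- if (nx > 0 && ny > 0) sum(x * y) / (nx * ny) else 0
           1 - sim
         })
}

# brute-force double-loop nearest-code search
brute_bmu <- function(X, codes, metric) {
  n <- nrow(X); m <- nrow(codes)
  cl <- integer(n); dst <- numeric(n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(m), function(j)
      metric_dist(X[i, ], codes[j, ], metric), numeric(1))
    cl[i] <- which.min(d)        # which.min takes the first minimum
    dst[i] <- d[cl[i]]
  }
  list(cluster_id = cl, distance = dst)
}

# Kruskal's algorithm with union-find, returning the MST total weight
kruskal_weight <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[pairs])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; taken <- 0
  for (e in ord) {
    a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + D[pairs[e, 1], pairs[e, 2]]
      taken <- taken + 1
      if (taken == n - 1) break
    }
  }
  total
}

# decode a Pruefer sequence into the edge list of its labeled tree
prufer_to_edges <- function(seq, n) {
  deg <- tabulate(seq, n) + 1L
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(seq)) {
    leaf <- which(deg == 1L)[1]
    edges[i, ] <- c(leaf, seq[i])
    deg[leaf] <- 0L
    deg[seq[i]] <- deg[seq[i]] - 1L
  }
  edges[n - 1, ] <- which(deg == 1L)
  edges
}

# exhaustive minimum over all n^(n-2) labeled spanning trees (Cayley)
exhaustive_mst_weight <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(as.integer(seqs[r, ]), n)
    w <- sum(D[ed])
    if (w < best) best <- w
  }
  best
}

# exhaustive one-to-one assignment maximizing total F1 over populations
exhaustive_total_f1 <- function(f1) {
  nr <- nrow(f1); nc <- ncol(f1)
  rec <- function(i, used) {
    if (i > nr) return(0)
    best <- rec(i + 1L, used)  # leave population i unmatched
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, f1[i, j] + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nc))
}

brute_purity <- function(truth, predicted) {
  groups <- split(as.character(truth), as.character(predicted))
  sum(vapply(groups, function(g) max(table(g)), numeric(1))) / length(truth)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
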