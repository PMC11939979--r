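# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and igraph): distances come from Floyd-Warshall, betweenness
# and stress from explicit enumeration of every shortest path.

# decode "n <TAB> bitmask" into an adjacency matrix; bit k of the mask is
# the k-th pair (i, j), i < j, in row-major upper-triangle order
decode_graph <- function(n, mask) {
  A <- matrix(0L, n, n)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bitwAnd(mask %/% 2^k, 1) == 1) A[i, j] <- A[j, i] <- 1L
      k <- k + 1
    }
  }
  A
}

load_connected_atlas <- function() {
  df <- read.table(test_path("fixtures", "connected-graphs-2to7.txt"))
  lapply(seq_len(nrow(df)), function(i) decode_graph(df[i, 1], df[i, 2]))
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# all shortest paths between s and t as a list of vertex sequences
all_geodesics <- function(A, D, s, t) {
  if (s == t) return(list(s))
  if (!is.finite(D[s, t])) return(list())
  out <- list()
  for (u in which(A[, t] == 1)) {
    if (D[s, u] == D[s, t] - 1) {
      for (p in all_geodesics(A, D, s, u)) out <- c(out, list(c(p, t)))
    }
  }
  out
}

# brute-force node centralities under the Centiscape conventions
oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- floyd_warshall(A)
  btw <- str <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_geodesics(A, D, s, t)
      if (!length(paths)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / length(paths)
        str[v] <- str[v] + through
      }
    }
  }
  clo <- ecc <- rad <- cen <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) < 2) next
    dv <- D[v, comp]
    clo[v] <- 1 / sum(dv)
    ecc[v] <- 1 / max(dv)
    diam <- max(D[comp, comp])
    rad[v] <- sum(diam + 1 - dv[comp != v]) / (length(comp) - 1)
    best <- Inf
    for (w in comp) {
      if (w == v) next
      gvw <- sum(D[comp, v] < D[comp, w])
      gwv <- sum(D[comp, w] < D[comp, v])
      best <- min(best, gvw - gwv)
    }
    cen[v] <- best
  }
  list(betweenness = btw, stress = str, closeness = clo,
       eccentricity = ecc, radiality = rad, centroid = cen)
}

# compare package centralities against the oracle for an adjacency matrix
expect_centralities_match_oracle <- function(A, tol = 1e-9) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(nrow(A)))
  ct <- centrality_table(g)$nodes
  orc <- oracle_centralities(A)
  expect_equal(ct$betweenness, orc$betweenness, tolerance = tol)
  expect_equal(ct$stress, orc$stress, tolerance = tol)
  expect_equal(ct$closeness, orc$closeness, tolerance = tol)
  expect_equal(ct$eccentricity, orc$eccentricity, tolerance = tol)
  expect_equal(ct$radiality, orc$radiality, tolerance = tol)
  expect_equal(ct$centroid, orc$centroid, tolerance = tol)
}

# exact two-sided presence-test p by exhaustive enumeration of all
# assignments of N subjects to a group of size na, given the pooled
# presence vector (ca + cb ones among na + nb subjects)
oracle_presence_p <- function(ca, cb, na, nb) {
  present <- c(rep(1, ca + cb), rep(0, na + nb - ca - cb))
  sets <- combn(na + nb, na)
  stat <- apply(sets, 2, function(idx) sum(present[idx]))
  lo <- mean(stat <= ca)
  hi <- mean(stat >= ca)
  min(1, 2 * min(lo, hi))
}

# exact upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_p <- function(x, m, nu, k) {
  j <- seq(x, min(m, k))
  if (!length(j) || x <= 0) return(1)
  sum(choose(m, j) * choose(nu - m, k - j)) / choose(nu, k)
}

# small deterministic PSM matrix builder for worked examples
make_psm <- function(values, proteins = NULL, subjects = NULL,
                     normalized = FALSE) {
  m <- as.matrix(values)
  if (is.null(proteins)) proteins <- rownames(m)
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(nrow(m)))
  if (is.null(subjects)) subjects <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(proteins, subjects)
  psm_matrix(m, normalized = normalized)
}
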