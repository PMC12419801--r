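# Shared fixtures and independent oracles. Oracles here never call the
# implementation paths they are used to check.

toy_scale <- function() {
  v <- rep(0, 20)
  names(v) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v["A"] <- 1
  v["R"] <- -1
  tm_scale(v, name = "toy")
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force H: explicit per-residue lookup loop, no vectorized mean
oracle_tm_score <- function(residues, scale_values) {
  aa <- strsplit(residues, "")[[1]]
  total <- 0
  n <- 0L
  for (r in aa) {
    if (r %in% names(scale_values)) {
      total <- total + scale_values[[r]]
      n <- n + 1L
    }
  }
  total / n
}

# exact hypergeometric tail by choose() summation
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  if (n == 0 || K == 0) return(1)
  x <- seq.int(a, min(K, n))
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# random Erdos-Renyi graph with named vertices, always containing "F"
random_named_graph <- function(n_nodes, p_edge) {
  g <- igraph::sample_gnp(n_nodes, p_edge)
  igraph::V(g)$name <- c("F", sprintf("V%02d", seq_len(n_nodes - 1L)))
  g
}

# exhaustive maximal-clique enumeration by bitmask subset scan (n <= 16)
oracle_focal_cliques <- function(graph, focal, min_size) {
  nm <- igraph::V(graph)$name
  n <- length(nm)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  mask <- vapply(seq_len(n), function(v) {
    as.integer(sum(bit[adj[v, ]]) + bit[v])
  }, integer(1))
  subsets <- seq_len(bitwShiftL(1L, n)) - 1L
  is_clique <- rep(TRUE, length(subsets))
  for (v in seq_len(n)) {
    in_s <- bitwAnd(subsets, bit[v]) != 0L
    ok <- bitwAnd(subsets, bitwNot(mask[v])) == 0L
    is_clique <- is_clique & (!in_s | ok)
  }
  is_max <- is_clique
  for (w in seq_len(n)) {
    absent <- bitwAnd(subsets, bit[w]) == 0L
    extendable <- bitwAnd(subsets, bitwNot(mask[w])) == 0L
    is_max <- is_max & !(absent & extendable)
  }
  focal_bit <- bit[match(focal, nm)]
  keep <- which(is_clique & is_max & bitwAnd(subsets, focal_bit) != 0L &
                  subsets != 0L)
  cl <- lapply(subsets[keep], function(s) {
    sort(nm[bitwAnd(s, bit) != 0L], method = "radix")
  })
  cl <- Filter(function(v) length(v) >= min_size, cl)
  cl[order(vapply(cl, paste, character(1), collapse = "|"),
           method = "radix")]
}

# contingency-table ARI recomputation
oracle_ari <- function(a, b) {
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_ <- sa * sb / choose(n, 2)
  (sij - exp_) / ((sa + sb) / 2 - exp_)
}

# small planted community spec shared across network tests
planted_communities <- function() {
  split(sprintf("N%02d", 1:40), rep(1:4, each = 10))
}

expect_setequal_cliques <- function(got, want) {
  key <- function(cl) sort(vapply(cl, paste, character(1), collapse = "|"))
  expect_identical(key(got), key(want))
}
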