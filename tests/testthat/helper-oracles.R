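# Brute-force oracles kept independent of the package implementation.

# Exhaustive-enumeration neighbourhood-damage probability: iterate over all
# 2^k activity patterns of the k neighbours and accumulate the probability
# mass of patterns with at most m active ones.
enum_damage_prob <- function(m, k, u) {
  if (k == 0L) return(1)  # zero neighbours: "at most m active" is certain
  total <- 0
  for (mask in 0:(2^k - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(k)]
    n_active <- sum(bits)
    if (n_active <= m)
      total <- total + u^n_active * (1 - u)^(k - n_active)
  }
  total
}

# Direct moment computation from the definitions (population central
# moments for skewness/kurtosis, n-1 for the variance).
brute_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, var = sum((x - mu)^2) / (n - 1),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Tiny deterministic graphs used across tests.
two_triangles_plus_isolate <- function() {
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4)), directed = FALSE)
  g <- igraph::add_vertices(g, 1)
  igraph::V(g)$name <- letters[1:7]
  g
}

star_plus_path <- function() {
  # node 1 is a hub of degree 4; nodes 4-5 hang off in a path
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 1, 1, 1, 4), c(2, 3, 4, 5, 5)), directed = FALSE)
  igraph::V(g)$name <- as.character(1:5)
  g
}

triangle_net <- function() {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("A", "B", "C")
  g
}
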