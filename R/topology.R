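#' Generate an Erdős–Rényi random network
#'
#' Draws a G(n, p) random graph with connection probability
#' `mean_degree / (n - 1)`, so that the expected average degree equals
#' `mean_degree`. The result is a simple undirected [igraph][igraph::igraph]
#' graph with character vertex names `"1" ... "n"`.
#'
#' @param n Number of nodes (at least 2).
#' @param mean_degree Target expected average degree, in `[0, n - 1]`.
#'   `0` yields an empty edge set, `n - 1` the complete graph.
#' @param seed Integer seed; the generator is deterministic for a fixed seed
#'   and leaves the caller's RNG state untouched. `NULL` uses (and advances)
#'   the current RNG stream.
#' @return An `igraph` object.
#' @seealso [make_ba()], [make_regular()], [read_edge_list()]
#' @export
#' @examples
#' g <- make_er(1000, 10, seed = 1)
#' mean(igraph::degree(g))
make_er <- function(n, mean_degree, seed = NULL) {
  if (!is_count(n, min = 2L)) param_error("`n` must be an integer >= 2")
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L ||
      !is.finite(mean_degree) || mean_degree < 0 || mean_degree > n - 1)
    param_error("`mean_degree` must lie in [0, n - 1]; got ", mean_degree)
  g <- with_seed(seed, igraph::sample_gnp(n, p = mean_degree / (n - 1),
                                          directed = FALSE, loops = FALSE))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Generate a Barabási–Albert scale-free network
#'
#' Preferential-attachment growth: each incoming node attaches
#' `links_per_node` edges to existing nodes with probability proportional to
#' their degree, giving an average degree close to `2 * links_per_node` and a
#' heavy-tailed degree distribution.
#'
#' @param n Number of nodes.
#' @param links_per_node Edges brought in by each new node, in `[1, n - 1]`.
#' @inheritParams make_er
#' @return A simple undirected `igraph` object.
#' @export
make_ba <- function(n, links_per_node, seed = NULL) {
  if (!is_count(n, min = 2L)) param_error("`n` must be an integer >= 2")
  if (!is_count(links_per_node, min = 1L) || links_per_node >= n)
    param_error("`links_per_node` must be an integer in [1, n - 1]")
  g <- with_seed(seed, igraph::sample_pa(n, power = 1, m = links_per_node,
                                         directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Generate a scale-free network with tunable clustering
#'
#' Holme–Kim-style growth: each new node first attaches preferentially by
#' degree; each of its remaining `links_per_node - 1` edges is, with
#' probability `triad_prob`, a triad-closure step (attach to a random
#' neighbour of the previously chosen target), otherwise another
#' preferential attachment. Expected clustering increases with `triad_prob`;
#' `triad_prob = 0` reduces to plain preferential attachment.
#'
#' @inheritParams make_ba
#' @param triad_prob Probability of closing a triangle at each extra link,
#'   in `[0, 1]`.
#' @return A simple undirected `igraph` object.
#' @export
make_ba_clustered <- function(n, links_per_node, triad_prob, seed = NULL) {
  if (!is_count(n, min = 2L)) param_error("`n` must be an integer >= 2")
  if (!is_count(links_per_node, min = 1L) || links_per_node >= n)
    param_error("`links_per_node` must be an integer in [1, n - 1]")
  if (!is_prob(triad_prob))
    param_error("`triad_prob` must be a probability in [0, 1]")
  m <- as.integer(links_per_node)
  with_seed(seed, {
    n0 <- m + 1L                     # seed clique keeps early degrees positive
    from <- to <- integer(0)
    for (a in seq_len(n0 - 1L))
      for (b in seq.int(a + 1L, n0)) { from <- c(from, a); to <- c(to, b) }
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (e in seq_along(from)) {
      adj[[from[e]]] <- c(adj[[from[e]]], to[e])
      adj[[to[e]]] <- c(adj[[to[e]]], from[e])
    }
    # pa_pool holds each existing node once per incident edge, so uniform
    # sampling from it is degree-proportional sampling
    pa_pool <- c(from, to)
    ef <- integer(n * m); et <- integer(n * m); ne <- length(from)
    ef[seq_len(ne)] <- from; et[seq_len(ne)] <- to
    if (n > n0) for (v in seq.int(n0 + 1L, n)) {
      targets <- integer(0)
      last <- 0L
      for (l in seq_len(min(m, v - 1L))) {
        pick <- NA_integer_
        if (l > 1L && stats::runif(1) < triad_prob) {
          cand <- setdiff(adj[[last]], c(v, targets))
          if (length(cand)) pick <- cand[[sample.int(length(cand), 1L)]]
        }
        if (is.na(pick)) {           # preferential attachment (with retry)
          repeat {
            pick <- pa_pool[[sample.int(length(pa_pool), 1L)]]
            if (!(pick %in% targets)) break
          }
        }
        targets <- c(targets, pick)
        last <- pick
      }
      for (w in targets) {
        ne <- ne + 1L
        ef[ne] <- v; et[ne] <- w
        adj[[v]] <- c(adj[[v]], w)
        adj[[w]] <- c(adj[[w]], v)
      }
      pa_pool <- c(pa_pool, targets, rep.int(v, length(targets)))
    }
    g <- igraph::graph_from_edgelist(cbind(ef[seq_len(ne)], et[seq_len(ne)]),
                                     directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- as.character(seq_len(n))
    g
  })
}

#' Generate a random regular network
#'
#' Every node has exactly degree `k` (used by the mean-field theory, which
#' assumes a common degree).
#'
#' @param n Number of nodes.
#' @param k Common degree; `n * k` must be even and `k < n`.
#' @inheritParams make_er
#' @return A simple undirected `igraph` object.
#' @export
make_regular <- function(n, k, seed = NULL) {
  if (!is_count(n, min = 2L)) param_error("`n` must be an integer >= 2")
  if (!is_count(k, min = 0L) || k >= n)
    param_error("`k` must be an integer in [0, n - 1]")
  if ((n * k) %% 2 != 0)
    param_error("`n * k` must be even (handshake parity); got n = ", n,
                ", k = ", k)
  g <- with_seed(seed, igraph::sample_k_regular(n, k))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Read a network from a plain-text edge list
#'
#' Parses a whitespace-separated edge list: one edge per line, first two
#' tokens are node labels, `#` starts a comment line. A third column
#' (typically a weight) is ignored with a warning; duplicate edges and
#' reverse-direction duplicates are collapsed, so directed or weighted
#' inputs are projected onto their simple undirected skeleton.
#'
#' @param path Path to the edge-list file.
#' @param keep_self_loops Keep `u u` lines as self-loop edges? Self-loops
#'   never enter the decay dynamics (a node is not its own neighbour); the
#'   flag only controls whether they are retained in the returned topology.
#' @return A simple undirected `igraph` object with character vertex names
#'   in first-appearance order. Isolated nodes (mentioned only in dropped
#'   self-loops) are retained as vertices.
#' @export
read_edge_list <- function(path, keep_self_loops = TRUE) {
  if (!file.exists(path)) io_error("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(igraph::make_empty_graph(0, directed = FALSE))
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L))
    io_error("edge-list parse error at line ", idx[which(nt < 2L)[1L]],
             ": need at least 2 tokens")
  if (any(nt > 2L))
    warning("third and later columns ignored (unweighted projection)",
            call. = FALSE)
  u <- vapply(toks, `[[`, "", 1L)
  v <- vapply(toks, `[[`, "", 2L)
  labels <- unique(c(rbind(u, v)))          # first-appearance order
  ui <- match(u, labels); vi <- match(v, labels)
  loop <- ui == vi
  if (any(loop) && !keep_self_loops) {
    warning(sum(loop), " self-loop(s) removed", call. = FALSE)
  }
  # canonical order, then dedup (collapses u-v / v-u and repeats)
  a <- pmin(ui, vi); b <- pmax(ui, vi)
  el <- unique(cbind(a, b))
  if (nrow(el) < length(a))
    warning(length(a) - nrow(el), " duplicate edge(s) collapsed", call. = FALSE)
  if (!keep_self_loops) el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
  g <- igraph::make_empty_graph(length(labels), directed = FALSE)
  igraph::V(g)$name <- labels
  igraph::add_edges(g, t(el))
}

#' Write a network as a plain-text edge list
#'
#' One `u<TAB>v` line per undirected edge (each edge written once), nodes by
#' label. Round-trips through [read_edge_list()] to an identical network.
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  con <- tryCatch(file(path, "w"), error = function(e)
    io_error("cannot open for writing: ", path))
  on.exit(close(con))
  if (nrow(el))
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Extract the giant component
#'
#' Induced subgraph on the largest connected component. Ties in component
#' size are broken by the component containing the smallest vertex index, so
#' the result is deterministic.
#'
#' @param net An `igraph` network.
#' @return An `igraph` object (empty if `net` is empty).
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # smallest minimum member index wins
    first_seen <- vapply(big, function(cc) min(which(comp$membership == cc)), 0L)
    big <- big[which.min(first_seen)]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}
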