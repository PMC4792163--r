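new_topology <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  adj <- build_adjacency(n, edges)
  structure(list(n_nodes = as.integer(n), edges = edges, adj = adj),
            class = "topology")
}

build_adjacency <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    # split once instead of looping over edges; nodes are 1..n
    both <- c(edges[, 1L], edges[, 2L])
    other <- c(edges[, 2L], edges[, 1L])
    sp <- split(other, factor(both, levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  }
  adj
}

#' @export
print.topology <- function(x, ...) {
  deg <- degrees(x)
  cat(sprintf("topology: %d nodes, %d edges, degree range [%d, %d], <k> = %.2f\n",
              x$n_nodes, nrow(x$edges), min(deg), max(deg), mean(deg)))
  invisible(x)
}

#' Node degrees of a topology
#' @param topology A \code{topology} object.
#' @return Integer vector of within-layer degrees, one per node.
#' @export
degrees <- function(topology) {
  lengths(topology$adj)
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Growth with preferential attachment: the graph starts from a complete core
#' of \code{m} nodes; each subsequently arriving node connects \code{m} edges
#' to \code{m} distinct existing nodes chosen with probability proportional to
#' their current degree. The result is an undirected simple graph with a
#' power-law degree tail (exponent about 3) and minimum degree \code{m}.
#'
#' Sampling proportional to degree uses the repeated-endpoints trick: a node
#' appears in the candidate pool once per incident edge, so a uniform draw
#' from the pool is degree-biased; duplicate targets are rejected and redrawn.
#'
#' @param n Number of nodes (n > m).
#' @param m Edges attached by each arriving node (m >= 1); also the core size.
#' @param seed Integer seed; the construction is deterministic given the seed.
#' @return A \code{topology}: node ids 1..n, edge matrix, adjacency lists.
#' @examples
#' ba <- generate_ba(100, m = 2, seed = 1)
#' nrow(ba$edges)  # 1 core edge + 2 * 98
#' @export
generate_ba <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1L || n <= m)
    stop("require n > m >= 1", call. = FALSE)
  withr_seed(seed, {
    n_core_edges <- if (m > 1L) (m * (m - 1L)) %/% 2L else 0L
    core <- if (m > 1L) utils::combn(m, 2L) else matrix(integer(0), 2L)
    n_edges <- n_core_edges + (n - m) * m
    from <- integer(n_edges)
    to <- integer(n_edges)
    if (n_core_edges) {
      from[seq_len(n_core_edges)] <- core[1L, ]
      to[seq_len(n_core_edges)] <- core[2L, ]
    }
    # pool of edge endpoints: node id repeated once per incident edge
    pool <- integer(2L * n_edges)
    pool_len <- 2L * n_core_edges
    if (n_core_edges) pool[seq_len(pool_len)] <- c(from[seq_len(n_core_edges)],
                                                   to[seq_len(n_core_edges)])
    e <- n_core_edges
    for (v in seq.int(m + 1L, n)) {
      targets <- integer(0L)
      if (pool_len == 0L) {
        # m = 1 start: the first arrival attaches to the isolated core node
        targets <- 1L
      } else {
        while (length(targets) < m) {
          cand <- pool[sample.int(pool_len, 1L)]
          if (!(cand %in% targets)) targets <- c(targets, cand)
        }
      }
      for (t in targets) {
        e <- e + 1L
        from[e] <- v; to[e] <- t
        pool[pool_len + 1L] <- v
        pool[pool_len + 2L] <- t
        pool_len <- pool_len + 2L
      }
    }
    new_topology(n, cbind(from[seq_len(e)], to[seq_len(e)]))
  })
}

# evaluate expr under a local RNG seed without disturbing the global stream;
# the seed is forced first so that computing it may still use the caller's RNG
withr_seed <- function(seed, expr) {
  force(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Couple two network layers by a random one-to-one matching
#'
#' Draws a uniformly random bijection between the nodes of two equally sized
#' layers (sampling partners without replacement, i.e. adding N external
#' links until every node on each layer has exactly one partner on the
#' other). External links carry no game interactions; they only couple
#' utilities.
#'
#' @param layer1,layer2 \code{topology} objects of equal size.
#' @param seed Integer seed; the matching is deterministic given the seed.
#' @return A \code{coupled_network}: list with \code{layer1}, \code{layer2}
#'   and \code{matching}, an integer vector where \code{matching[i]} is the
#'   layer-2 partner of layer-1 node \code{i}.
#' @examples
#' l1 <- generate_ba(50, 2, seed = 1)
#' cn <- couple_layers(l1, l1, seed = 2)
#' @export
couple_layers <- function(layer1, layer2, seed) {
  if (!inherits(layer1, "topology") || !inherits(layer2, "topology"))
    stop("layers must be 'topology' objects", call. = FALSE)
  if (layer1$n_nodes != layer2$n_nodes)
    stop("layers must have equal size", call. = FALSE)
  matching <- withr_seed(seed, sample.int(layer1$n_nodes))
  structure(list(layer1 = layer1, layer2 = layer2,
                 matching = as.integer(matching)),
            class = "coupled_network")
}

#' @export
print.coupled_network <- function(x, ...) {
  cat(sprintf("coupled_network: 2 layers of %d nodes, %d external links\n",
              x$layer1$n_nodes, x$layer1$n_nodes))
  invisible(x)
}

#' Inverse of the inter-layer matching
#' @param coupled A \code{coupled_network}.
#' @return Integer vector: layer-1 partner of each layer-2 node.
#' @export
matching_inverse <- function(coupled) {
  order(coupled$matching)
}

#' Write a topology as a plain edge list
#'
#' Two whitespace-delimited node columns preceded by a header line
#' \code{# n_nodes=<N>}, so isolated nodes survive a round trip.
#'
#' @param topology A \code{topology}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d", topology$n_nodes), con)
  utils::write.table(topology$edges, con, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a topology from a plain edge list
#'
#' Accepts the format of \code{\link{write_edge_list}}; without the header
#' the node count defaults to the largest node id seen. Loading arbitrary
#' edge lists is how custom (non-BA) topologies enter the simulator.
#'
#' @param path Edge-list file.
#' @return A \code{topology}.
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  n_header <- NA_integer_
  if (grepl("^#\\s*n_nodes=", first))
    n_header <- as.integer(sub("^#\\s*n_nodes=", "", first))
  d <- utils::read.table(path, comment.char = "#")
  edges <- if (nrow(d)) as.matrix(d[, 1:2]) else matrix(integer(0), ncol = 2)
  n <- if (!is.na(n_header)) n_header else max(edges, 0L)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list", call. = FALSE)
    if (any(edges < 1L) || any(edges > n)) stop("node id out of range", call. = FALSE)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edge in edge list", call. = FALSE)
  }
  new_topology(n, edges)
}

#' Write an inter-layer matching as a two-column node-pair list
#' @param coupled A \code{coupled_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matching <- function(coupled, path) {
  utils::write.table(cbind(seq_along(coupled$matching), coupled$matching),
                     path, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}
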