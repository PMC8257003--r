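#' @import igraph
NULL

# Stamp generator metadata onto an igraph object.
net_meta <- function(g, type, params, seed) {
  g <- igraph::set_graph_attr(g, "net_type", type)
  for (nm in names(params))
    g <- igraph::set_graph_attr(g, paste0("net_", nm), params[[nm]])
  g <- igraph::set_graph_attr(g, "net_seed",
                              if (is.null(seed)) NA_integer_ else seed)
  g
}

with_net_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Erdős–Rényi random communicative network
#'
#' `G(N, p)` baseline: every unordered pair of agents is connected
#' independently with probability `density` (0.1 throughout the simulation
#' studies shipped with the package). The graph may be disconnected at
#' small `n`; isolated agents simply never interact.
#'
#' @param n Number of agents (at least 2).
#' @param density Edge probability in \[0, 1\].
#' @param seed Optional integer seed; the generator is fully reproducible
#'   given `(n, density, seed)`.
#' @return An undirected, unweighted [igraph][igraph::igraph-package] graph
#'   with generator metadata stored as graph attributes.
#' @export
net_random <- function(n, density = 0.1, seed = NULL) {
  stopifnot(n >= 2)
  if (density < 0 || density > 1)
    stop("'density' must be in [0, 1]", call. = FALSE)
  g <- with_net_seed(seed, igraph::sample_gnp(n, density))
  net_meta(g, "random", list(density = density), seed)
}

#' Watts–Strogatz small-world network
#'
#' The "beta model": agents are placed on a ring, each connected to
#' `neighbors_per_side` neighbors on either side, and each original lattice
#' edge is then rewired with probability `rewire_p` by replacing its far
#' endpoint with a uniformly chosen node, avoiding self-loops and duplicate
#' edges. The edge count is exactly `n * neighbors_per_side` regardless of
#' `rewire_p`.
#'
#' @param n Number of agents; must exceed `2 * neighbors_per_side`.
#' @param neighbors_per_side Lattice neighbors on each side (default 4, so
#'   lattice degree 8).
#' @param rewire_p Rewiring probability (default 0.1).
#' @inheritParams net_random
#' @return An undirected igraph graph with generator metadata.
#' @export
net_small_world <- function(n, neighbors_per_side = 4, rewire_p = 0.1,
                            seed = NULL) {
  k <- as.integer(neighbors_per_side)
  stopifnot(k >= 1)
  if (n <= 2 * k)
    stop("'n' must exceed 2 * neighbors_per_side for the ring lattice",
         call. = FALSE)
  if (rewire_p < 0 || rewire_p > 1)
    stop("'rewire_p' must be in [0, 1]", call. = FALSE)
  edges <- with_net_seed(seed, {
    # ring lattice: node i connected to its k clockwise neighbors
    from <- rep(seq_len(n), each = k)
    to <- (from - 1L + rep(seq_len(k), times = n)) %% n + 1L
    adj <- matrix(FALSE, n, n)
    adj[cbind(from, to)] <- TRUE
    adj[cbind(to, from)] <- TRUE
    # rewire each lattice edge's far endpoint with probability rewire_p
    for (e in seq_along(from)) {
      if (stats::runif(1) >= rewire_p) next
      i <- from[e]; j <- to[e]
      if (sum(adj[i, ]) >= n - 1L) next  # node saturated, nothing to rewire to
      repeat {
        h <- sample.int(n, 1L)
        if (h != i && !adj[i, h]) break
      }
      adj[i, j] <- adj[j, i] <- FALSE
      adj[i, h] <- adj[h, i] <- TRUE
      to[e] <- h
    }
    cbind(from, to)
  })
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  net_meta(g, "small-world",
           list(neighbors_per_side = k, rewire_p = rewire_p), seed)
}

#' Barabási–Albert scale-free network
#'
#' Preferential attachment: growth starts from a fully connected seed of
#' `m_attach + 1` agents; each subsequent agent attaches `m_attach` edges
#' to distinct existing agents chosen with probability proportional to
#' their current degree, so well-connected agents keep acquiring
#' connections and a power-law degree distribution (hubs) emerges. The edge
#' count is exactly `choose(m_attach + 1, 2) + m_attach * (n - m_attach - 1)`.
#'
#' @param n Number of agents; must exceed `m_attach`.
#' @param m_attach Edges added per new agent (default 4, giving an
#'   asymptotic mean degree of 8, matched to the small-world lattice).
#' @inheritParams net_random
#' @return An undirected igraph graph with generator metadata.
#' @export
net_scale_free <- function(n, m_attach = 4, seed = NULL) {
  m <- as.integer(m_attach)
  stopifnot(m >= 1)
  if (n <= m)
    stop("'n' must exceed 'm_attach'", call. = FALSE)
  edges <- with_net_seed(seed, {
    seed_n <- m + 1L
    from <- integer(0); to <- integer(0)
    for (i in seq_len(seed_n - 1L)) {
      from <- c(from, rep(i, seed_n - i))
      to <- c(to, (i + 1L):seed_n)
    }
    # degree-proportional sampling via the repeated-endpoints trick
    stubs <- c(from, to)
    if (n > seed_n) {
      total <- choose(seed_n, 2L) + m * (n - seed_n)
      from <- c(from, integer(total - length(from)))
      to <- c(to, integer(total - length(to)))
      ne <- choose(seed_n, 2L)
      stubs <- c(stubs, integer(2L * (total - ne)))
      ns <- 2L * ne
      for (v in (seed_n + 1L):n) {
        targets <- integer(0)
        while (length(targets) < m) {
          cand <- stubs[sample.int(ns, 1L)]
          if (!(cand %in% targets)) targets <- c(targets, cand)
        }
        for (t in targets) {
          ne <- ne + 1L
          from[ne] <- v; to[ne] <- t
          stubs[ns + 1L] <- v; stubs[ns + 2L] <- t
          ns <- ns + 2L
        }
      }
    }
    cbind(from, to)
  })
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  net_meta(g, "scale-free", list(m_attach = m), seed)
}

#' Generate a network by type name
#'
#' Dispatcher used by simulation configurations: `"random"`,
#' `"small-world"` or `"scale-free"`, with the study defaults
#' (density 0.1; 4 lattice neighbors per side, rewiring 0.1; attachment 4).
#'
#' @param type Network class.
#' @param n Number of agents.
#' @param params Optional named list overriding generator defaults
#'   (`density`; `neighbors_per_side`, `rewire_p`; `m_attach`).
#' @inheritParams net_random
#' @return An undirected igraph graph.
#' @export
generate_network <- function(type = c("scale-free", "small-world", "random"),
                             n, params = list(), seed = NULL) {
  type <- match.arg(type)
  a <- function(nm, default) if (!is.null(params[[nm]])) params[[nm]] else default
  switch(type,
         "random" = net_random(n, a("density", 0.1), seed),
         "small-world" = net_small_world(n, a("neighbors_per_side", 4),
                                         a("rewire_p", 0.1), seed),
         "scale-free" = net_scale_free(n, a("m_attach", 4), seed))
}

#' Rank agents by centrality
#'
#' Orders agents by decreasing degree centrality, ties broken by ascending
#' agent id, so the ranking is deterministic given the network. The top of
#' this ranking defines the network's "influencers".
#'
#' @param net An igraph network.
#' @return Integer vector of agent ids, most central first.
#' @export
rank_centrality <- function(net) {
  deg <- igraph::degree(net)
  order(-deg, seq_along(deg))
}

#' Assign intrinsic-bias roles to agents
#'
#' Marks `round(upsilon * n)` agents as intrinsically biased. Under
#' `"random"` placement the biased set is a uniform sample; under
#' `"influencers"` placement the `min(upsilon, top_fraction) * n` most
#' central agents are forced biased and any remaining quota is filled
#' uniformly from the other agents.
#'
#' @param net An igraph network.
#' @param upsilon Target fraction of biased agents in \[0, 1\].
#' @param top_mode `"random"` or `"influencers"`.
#' @param top_fraction Fraction of highest-centrality agents forced biased
#'   under influencer placement (default 0.10).
#' @param seed Optional integer seed.
#' @return A list of class `"role_assignment"` with `biased` (sorted agent
#'   ids), `n`, `upsilon`, `top_mode`, `top_fraction`.
#' @export
assign_bias_roles <- function(net, upsilon, top_mode = c("random", "influencers"),
                              top_fraction = 0.10, seed = NULL) {
  top_mode <- match.arg(top_mode)
  if (upsilon < 0 || upsilon > 1)
    stop("'upsilon' must be in [0, 1]", call. = FALSE)
  n <- igraph::vcount(net)
  n_biased <- round(upsilon * n)
  biased <- with_net_seed(seed, {
    if (n_biased == 0L) {
      integer(0)
    } else if (top_mode == "influencers") {
      n_top <- round(min(upsilon, top_fraction) * n)
      top <- rank_centrality(net)[seq_len(n_top)]
      rest <- setdiff(seq_len(n), top)
      extra <- n_biased - n_top
      c(top, if (extra > 0L) rest[sample.int(length(rest), extra)])
    } else {
      sample.int(n, n_biased)
    }
  })
  structure(list(biased = sort(as.integer(biased)), n = n,
                 upsilon = upsilon, top_mode = top_mode,
                 top_fraction = top_fraction),
            class = "role_assignment")
}

#' Detect structural communities with the Louvain algorithm
#'
#' Partitions the network into communities by modularity maximization
#' (Louvain, resolution 1), using only the connection structure -- never
#' the agents' language values. Used downstream for the between-community
#' heterogeneity outcome.
#'
#' @param net An igraph network.
#' @param seed Optional integer seed making the partition reproducible.
#' @return A list of class `"community_partition"` with `membership`
#'   (integer label per agent, labels contiguous from 1) and
#'   `n_communities`.
#' @export
detect_communities <- function(net, seed = NULL) {
  if (igraph::vcount(net) == 0L)
    stop("cannot partition an empty network", call. = FALSE)
  cl <- with_net_seed(seed, igraph::cluster_louvain(net))
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, sort(unique(memb)))  # contiguous labels
  structure(list(membership = memb, n_communities = max(memb)),
            class = "community_partition")
}

#' Read / write networks as plain-text files
#'
#' Edge lists are whitespace-delimited pairs of 1-based agent ids; GraphML
#' output embeds the generator metadata as graph attributes.
#'
#' @param net An igraph network.
#' @param path File path.
#' @param n Total number of agents (to preserve isolated nodes); defaults
#'   to the largest id seen in the file.
#' @return `net_read_edgelist` returns an igraph graph; the writers return
#'   `path` invisibly.
#' @export
net_write_edgelist <- function(net, path) {
  e <- igraph::as_edgelist(net, names = FALSE)
  utils::write.table(e, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname net_write_edgelist
#' @export
net_read_edgelist <- function(path, n = NULL) {
  e <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "integer"))
  if (nrow(e) > 0 && ncol(e) != 2L)
    stop("edge list must have two columns", call. = FALSE)
  nmax <- if (nrow(e)) max(e) else 0L
  if (is.null(n)) n <- nmax
  if (n < nmax) stop("'n' smaller than the largest agent id", call. = FALSE)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  net_meta(g, "user", list(), NULL)
}

#' @rdname net_write_edgelist
#' @export
net_write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
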