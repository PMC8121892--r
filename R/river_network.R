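#' Construct a river network
#'
#' A weighted graph of sampling sites and confluence (junction) nodes with
#' along-channel edge lengths in kilometres and a single designated outlet.
#' All spatial distances used by the pipeline (pairwise river distance,
#' distance to the outlet) derive from this object.
#'
#' @param edges Data frame with columns `from`, `to`, `length_km` (> 0).
#' @param outlet Node id of the outlet (e.g. the river mouth).
#' @param site_ids Optional character vector flagging which nodes are
#'   sampling sites (defaults to all nodes). Other nodes are junctions.
#' @param node_attrs Optional data frame of per-node attributes keyed by a
#'   `node` column (altitude, width, river name, ...).
#' @param tree If `TRUE` (default) the network is required to be acyclic
#'   (dendritic); set `FALSE` to allow braided channels.
#' @return An object of class `river_network` wrapping an igraph graph.
#' @export
river_network <- function(edges, outlet, site_ids = NULL, node_attrs = NULL,
                          tree = TRUE) {
  edges <- as.data.frame(edges)
  need <- c("from", "to", "length_km")
  if (!all(need %in% names(edges)))
    stop("edges must have columns from, to, length_km", call. = FALSE)
  if (any(!is.finite(edges$length_km)) || any(edges$length_km <= 0))
    stop("edge lengths must be positive km", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- edges$length_km
  nodes <- igraph::V(g)$name
  if (!outlet %in% nodes)
    stop(sprintf("outlet '%s' is not a network node", outlet), call. = FALSE)
  if (!igraph::is_connected(g))
    stop("river network must be connected", call. = FALSE)
  if (tree && igraph::ecount(g) != igraph::vcount(g) - 1)
    stop("dendritic network must be acyclic (a tree)", call. = FALSE)
  if (is.null(site_ids)) site_ids <- nodes
  site_ids <- as.character(site_ids)
  if (!all(site_ids %in% nodes))
    stop(sprintf("unknown site ids: %s",
                 paste(setdiff(site_ids, nodes), collapse = ", ")),
         call. = FALSE)
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs)
    if (is.null(node_attrs$node))
      stop("node_attrs must have a 'node' column", call. = FALSE)
  }
  structure(list(graph = g, outlet = as.character(outlet),
                 site_ids = site_ids, node_attrs = node_attrs,
                 tree = tree),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d nodes (%d sites), %d edges, outlet '%s'\n",
              igraph::vcount(x$graph), length(x$site_ids),
              igraph::ecount(x$graph), x$outlet))
  cat(sprintf("  total channel length: %.1f km\n",
              sum(igraph::E(x$graph)$weight)))
  invisible(x)
}

#' Read a river network from an edge-list CSV
#'
#' @param path CSV with columns `from`, `to`, `length_km`.
#' @param node_path Optional CSV of node attributes with columns `node`,
#'   `is_outlet` (exactly one `TRUE`), optional `is_site`, and any further
#'   attribute columns.
#' @inheritParams river_network
#' @return A [river_network()].
#' @export
read_river_network <- function(path, node_path = NULL, tree = TRUE) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  outlet <- NULL; site_ids <- NULL; attrs <- NULL
  if (!is.null(node_path)) {
    attrs <- utils::read.csv(node_path, stringsAsFactors = FALSE)
    if (is.null(attrs$node) || is.null(attrs$is_outlet))
      stop("node CSV needs columns 'node' and 'is_outlet'", call. = FALSE)
    out <- attrs$node[as.logical(attrs$is_outlet)]
    if (length(out) != 1)
      stop("exactly one node must be flagged is_outlet", call. = FALSE)
    outlet <- out
    if (!is.null(attrs$is_site)) site_ids <- attrs$node[as.logical(attrs$is_site)]
  }
  if (is.null(outlet))
    stop("an outlet must be designated via the node attribute CSV",
         call. = FALSE)
  river_network(edges, outlet, site_ids = site_ids, node_attrs = attrs,
                tree = tree)
}

#' Write a river network as edge-list + node-attribute CSVs
#'
#' @param net A [river_network()].
#' @param path Edge-list CSV destination.
#' @param node_path Node-attribute CSV destination.
#' @export
write_river_network <- function(net, path, node_path) {
  stopifnot(inherits(net, "river_network"))
  el <- igraph::as_data_frame(net$graph, what = "edges")
  names(el) <- c("from", "to", "length_km")
  utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
  nodes <- igraph::V(net$graph)$name
  nd <- data.frame(node = nodes,
                   is_outlet = nodes == net$outlet,
                   is_site = nodes %in% net$site_ids)
  if (!is.null(net$node_attrs))
    nd <- merge(nd, net$node_attrs, by = "node", all.x = TRUE, sort = FALSE)
  utils::write.csv(nd, node_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Pairwise along-network distances between sites
#'
#' @param net A [river_network()].
#' @param sites Ordered site ids; defaults to the network's site set.
#' @return Symmetric matrix of shortest along-channel path lengths (km) with
#'   zero diagonal, dimnames = sites.
#' @export
network_distance_matrix <- function(net, sites = net$site_ids) {
  stopifnot(inherits(net, "river_network"))
  sites <- as.character(sites)
  unknown <- setdiff(sites, igraph::V(net$graph)$name)
  if (length(unknown))
    stop(sprintf("sites not in network: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  d <- igraph::distances(net$graph, v = sites, to = sites,
                         weights = igraph::E(net$graph)$weight)
  if (any(!is.finite(d)))
    stop("some sites are disconnected from the network", call. = FALSE)
  dimnames(d) <- list(sites, sites)
  d
}

#' Along-network distance from each site to the outlet
#'
#' @inheritParams network_distance_matrix
#' @return Named numeric vector of km to the outlet.
#' @export
distance_to_outlet <- function(net, sites = net$site_ids) {
  stopifnot(inherits(net, "river_network"))
  sites <- as.character(sites)
  unknown <- setdiff(sites, igraph::V(net$graph)$name)
  if (length(unknown))
    stop(sprintf("sites not in network: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  d <- igraph::distances(net$graph, v = sites, to = net$outlet,
                         weights = igraph::E(net$graph)$weight)[, 1]
  if (any(!is.finite(d)))
    stop("some sites are disconnected from the network", call. = FALSE)
  stats::setNames(as.numeric(d), sites)
}
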