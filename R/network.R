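#' Parameters for dynamical residue-network construction
#'
#' @param contact_cutoff Heavy-atom distance (Angstrom) below which two
#'   residues are in contact in a frame.
#' @param occupancy_min Minimum fraction of frames a contact must persist
#'   to become an edge.
#' @param sigma_k Number of standard deviations above the mean edge
#'   betweenness for an edge to be called critical.
#' @param weight_convention `"literal_var_over_mean"` scores an edge by
#'   the variance of the center-center distance series divided by its
#'   mean; `"sqrt_var_over_mean"` uses the conventional coefficient of
#'   variation (sd/mean).
#' @param neighbor_exclusion Intra-chain sequence separation (inclusive)
#'   excluded from the edge set; covalently forced neighbours otherwise
#'   dominate every path.
#' @return A `network_params` list.
#' @export
network_params <- function(contact_cutoff = 4.5, occupancy_min = 0.75,
                           sigma_k = 3,
                           weight_convention = c("literal_var_over_mean",
                                                 "sqrt_var_over_mean"),
                           neighbor_exclusion = 1L) {
  weight_convention <- match.arg(weight_convention)
  stopifnot(contact_cutoff > 0, occupancy_min > 0, occupancy_min <= 1,
            sigma_k > 0, neighbor_exclusion >= 0)
  structure(list(contact_cutoff = contact_cutoff, occupancy_min = occupancy_min,
                 sigma_k = sigma_k, weight_convention = weight_convention,
                 neighbor_exclusion = as.integer(neighbor_exclusion)),
            class = "network_params")
}

# Residue bookkeeping for network analyses: heavy protein atoms grouped
# into residues in file order. Returns atom subset indices, per-atom
# residue ids and the node table.
.network_atoms <- function(topology, include_hetero = FALSE) {
  a <- topology$atoms
  keep <- !(a$element %in% c("H", "D")) & !a$water
  if (!include_hetero) keep <- keep & !a$het
  if (!any(keep)) stop("no heavy protein atoms in topology")
  sub <- a[keep, , drop = FALSE]
  key <- .residue_key(sub)
  rid <- match(key, unique(key))
  first <- !duplicated(rid)
  nodes <- data.frame(node = key[first], chain = sub$chain[first],
                      resno = sub$resno[first], resname = sub$resname[first],
                      stringsAsFactors = FALSE)
  list(atom_idx = which(keep), res_index = rid, nodes = nodes, atoms = sub)
}

# Run the compiled per-frame pass over an ensemble. Returns nodes,
# occupancy matrix, center-distance moments and per-frame centers.
.pair_stats <- function(ens, cutoff, include_hetero = FALSE) {
  info <- .network_atoms(ens$topology, include_hetero)
  cols <- as.vector(rbind(3L * (info$atom_idx - 1L) + 1L,
                          3L * (info$atom_idx - 1L) + 2L,
                          3L * info$atom_idx))
  xyz <- ens$xyz[, cols, drop = FALSE]
  mass <- .ELEMENT_MASS[info$atoms$element]
  if (anyNA(mass))
    stop("no mass for element(s): ",
         paste(unique(info$atoms$element[is.na(mass)]), collapse = ", "))
  st <- cpp_pair_stats(xyz, info$res_index, as.numeric(mass), cutoff)
  F <- nrow(ens$xyz)
  mean_d <- st$sum_d / F
  var_d <- pmax(st$sum_d2 / F - mean_d^2, 0)
  list(nodes = info$nodes, occupancy = st$contact_count / F,
       mean_d = mean_d, var_d = var_d, centers = st$centers, n_frames = F)
}

#' Per-frame residue heavy-atom centers of mass
#'
#' Nodes of the dynamical network are residues, each represented by the
#' mass-weighted mean of its heavy-atom coordinates in every frame.
#'
#' @param ens An `ensemble`.
#' @param include_hetero Include non-water heteroresidues as nodes.
#' @return List with `nodes` (data.frame: node key, chain, resno,
#'   resname) and `centers` (F x 3R matrix, bio3d column layout).
#' @export
residue_centers <- function(ens, include_hetero = FALSE) {
  st <- .pair_stats(ens, cutoff = 1e-6, include_hetero = include_hetero)
  list(nodes = st$nodes, centers = st$centers)
}

#' Residue-pair contact occupancy
#'
#' Fraction of frames in which any heavy-atom pair of two residues lies
#' within `cutoff`.
#'
#' @param ens An `ensemble`.
#' @param cutoff Contact distance (Angstrom).
#' @param include_hetero Include non-water heteroresidues.
#' @return Symmetric R x R occupancy matrix with node keys as dimnames;
#'   the diagonal is `NA`.
#' @export
contact_occupancy <- function(ens, cutoff = 4.5, include_hetero = FALSE) {
  st <- .pair_stats(ens, cutoff, include_hetero)
  occ <- st$occupancy
  diag(occ) <- NA_real_
  dimnames(occ) <- list(st$nodes$node, st$nodes$node)
  occ
}

#' Build a dynamical residue contact network from an ensemble
#'
#' Edges join residues whose heavy atoms stay within
#' `params$contact_cutoff` for at least `params$occupancy_min` of the
#' frames (excluding intra-chain sequence neighbours). Each retained
#' edge is weighted by the dispersion of the distance series between the
#' two residues' heavy-atom centers of mass: variance/mean under the
#' literal convention, sd/mean under the coefficient-of-variation
#' convention. Only internal distances enter, so no prior alignment is
#' required and the network is invariant to global rigid motion.
#'
#' @param ens An `ensemble`.
#' @param params A `network_params` object.
#' @param include_hetero Include non-water heteroresidues as nodes.
#' @return A `contact_network`: list with `nodes`, `edges` (data.frame:
#'   from, to, occupancy, mean_distance, weight, betweenness), `params`,
#'   `n_frames`.
#' @export
build_network <- function(ens, params = network_params(),
                          include_hetero = FALSE) {
  st <- .pair_stats(ens, params$contact_cutoff, include_hetero)
  nodes <- st$nodes
  if (nrow(nodes) < 2L) stop("need at least two residues to build a network")
  R <- nrow(nodes)
  ut <- which(upper.tri(st$occupancy), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  keep <- st$occupancy[ut] >= params$occupancy_min
  same_chain <- nodes$chain[i] == nodes$chain[j]
  keep <- keep & !(same_chain &
                   abs(nodes$resno[i] - nodes$resno[j]) <= params$neighbor_exclusion)
  i <- i[keep]; j <- j[keep]
  mean_d <- st$mean_d[cbind(i, j)]
  var_d <- st$var_d[cbind(i, j)]
  w <- switch(params$weight_convention,
              literal_var_over_mean = var_d / mean_d,
              sqrt_var_over_mean = sqrt(var_d) / mean_d)
  edges <- data.frame(from = nodes$node[i], to = nodes$node[j],
                      occupancy = st$occupancy[cbind(i, j)],
                      mean_distance = mean_d, weight = w,
                      betweenness = NA_real_, stringsAsFactors = FALSE)
  out <- list(nodes = nodes, edges = edges, params = params,
              n_frames = st$n_frames)
  class(out) <- "contact_network"
  out
}

#' @export
print.contact_network <- function(x, ...) {
  cat("contact_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(cutoff %.2f A, occupancy >= %.2f, weights: %s)\n",
              x$params$contact_cutoff, x$params$occupancy_min,
              x$params$weight_convention))
  invisible(x)
}

.network_igraph <- function(net) {
  if (any(net$edges$weight < 0)) stop("negative edge weight: impossible by construction")
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Weighted edge betweenness of a contact network
#'
#' Brandes edge betweenness with edge length equal to the edge weight
#' (minimum-weight paths are the optimal allosteric paths). Counts are
#' raw unordered pair counts (unnormalized); co-optimal paths split
#' counts equally. Disconnected networks are handled per component.
#'
#' @param net A `contact_network` from [build_network()].
#' @return The network with `edges$betweenness` filled.
#' @export
edge_betweenness <- function(net) {
  g <- .network_igraph(net)
  net$edges$betweenness <-
    igraph::edge_betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$weight)
  net
}

#' Critical edges of a contact network
#'
#' Edges whose betweenness exceeds the mean of the betweenness
#' distribution by at least `sigma_k` standard deviations. When the
#' distribution is degenerate (zero spread) the comparison is strict, so
#' a uniform graph yields no critical edges.
#'
#' @param net A `contact_network` with betweenness filled (see
#'   [edge_betweenness()]; it is computed here if absent).
#' @param sigma_k Criticality threshold in standard deviations; defaults
#'   to the network's `params$sigma_k`.
#' @return Edge data.frame ordered by betweenness (descending, ties by
#'   node labels), with a `threshold` attribute.
#' @export
critical_edges <- function(net, sigma_k = net$params$sigma_k) {
  if (anyNA(net$edges$betweenness)) net <- edge_betweenness(net)
  e <- net$edges
  if (nrow(e) < 2L) {
    warning("fewer than two edges; no criticality distribution")
    return(e[0, , drop = FALSE])
  }
  b <- e$betweenness
  s <- stats::sd(b)
  thr <- mean(b) + sigma_k * s
  sel <- if (s == 0) b > thr else b >= thr
  out <- e[sel, , drop = FALSE]
  out <- out[order(-out$betweenness, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Minimum-weight (optimal allosteric) path between two residues
#'
#' Dijkstra shortest path with edge length equal to the edge weight; the
#' optimal path minimises the sum of its constituent edge weights. All
#' co-optimal paths are enumerated (up to `max_paths`) and ordered
#' lexicographically by node labels; the first is reported as the path.
#'
#' @param net A `contact_network`.
#' @param source,target Node keys, e.g. `"A:62"`.
#' @param max_paths Cap on enumerated co-optimal paths.
#' @return A `path_result`: list with `nodes` (character vector, `NULL`
#'   if disconnected), `weight`, `alternates` (list of co-optimal node
#'   vectors including the primary), `reachable` flag.
#' @export
shortest_path <- function(net, source, target, max_paths = 100L) {
  for (k in c(source, target))
    if (!k %in% net$nodes$node) stop("node not in network: ", k)
  g <- .network_igraph(net)
  suppressWarnings(
    res <- igraph::all_shortest_paths(g, from = source, to = target,
                                      weights = igraph::E(g)$weight)
  )
  paths <- lapply(res$vpaths, function(p) igraph::as_ids(p))
  if (!length(paths)) {
    return(structure(list(nodes = NULL, weight = Inf, alternates = list(),
                          reachable = FALSE), class = "path_result"))
  }
  keys <- vapply(paths, paste, "", collapse = " -> ")
  paths <- paths[order(keys)]
  if (length(paths) > max_paths) paths <- paths[seq_len(max_paths)]
  w <- .path_weight(net, paths[[1]])
  structure(list(nodes = paths[[1]], weight = w, alternates = paths,
                 reachable = TRUE), class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$reachable) {
    cat("no path between the requested nodes\n")
  } else {
    cat("optimal path (weight", sprintf("%.2f", x$weight), "):\n  ",
        paste(x$nodes, collapse = " -> "), "\n")
    if (length(x$alternates) > 1L)
      cat("  (", length(x$alternates), "co-optimal paths )\n")
  }
  invisible(x)
}

.path_weight <- function(net, nodes) {
  e <- net$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- stats::setNames(e$weight, key(e$from, e$to))
  steps <- key(nodes[-length(nodes)], nodes[-1])
  if (anyNA(lut[steps])) stop("path uses a non-existent edge")
  sum(lut[steps])
}

#' Edges that cross the protomer-protomer interface
#'
#' @param net A `contact_network`.
#' @param critical_only Restrict to the critical-edge subset.
#' @return Edge data.frame (endpoints on different chains) sorted by
#'   betweenness descending.
#' @export
interprotomer_edges <- function(net, critical_only = FALSE) {
  if (length(unique(net$nodes$chain)) < 2L) {
    warning("single-chain network: no interprotomer edges")
    return(net$edges[0, , drop = FALSE])
  }
  e <- if (critical_only) critical_edges(net) else net$edges
  chain_of <- stats::setNames(net$nodes$chain, net$nodes$node)
  sel <- chain_of[e$from] != chain_of[e$to]
  out <- e[sel, , drop = FALSE]
  if (!anyNA(out$betweenness))
    out <- out[order(-out$betweenness, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a contact network as GraphML
#'
#' Node attributes: chain, resnum, resname; edge attributes: occupancy,
#' mean_distance, weight, betweenness, critical flag.
#'
#' @param net A `contact_network`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_network_graphml <- function(net, file) {
  if (anyNA(net$edges$betweenness)) net <- edge_betweenness(net)
  crit <- critical_edges(net)
  ckey <- paste(crit$from, crit$to)
  net$edges$critical <- paste(net$edges$from, net$edges$to) %in% ckey
  g <- .network_igraph(net)
  igraph::V(g)$resnum <- net$nodes$resno
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Export the edge table as TSV
#' @param net A `contact_network`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_edge_table <- function(net, file) {
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
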