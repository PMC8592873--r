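# Independent oracles and small fixture builders used across tests.

# Build a contact_network directly from node/edge tables (unit-test
# graphs that need no ensemble behind them).
make_net <- function(edges, nodes = NULL, params = network_params()) {
  if (is.null(nodes)) {
    nm <- sort(unique(c(edges$from, edges$to)))
    nodes <- data.frame(node = nm,
                        chain = sub(":.*", "", nm),
                        resno = suppressWarnings(as.integer(sub(".*:", "", nm))),
                        resname = "GLY", stringsAsFactors = FALSE)
  }
  edges$occupancy <- if (is.null(edges$occupancy)) 1 else edges$occupancy
  edges$mean_distance <- if (is.null(edges$mean_distance)) 4 else edges$mean_distance
  edges$betweenness <- NA_real_
  structure(list(nodes = nodes, edges = edges, params = params, n_frames = 1L),
            class = "contact_network")
}

# Enumerate all simple paths between two nodes of a small undirected
# weighted graph given as an edge data.frame (from, to, weight).
enumerate_paths <- function(edges, source, target) {
  adj <- list()
  adde <- function(a, b, w) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(to = b, w = w))
  }
  for (k in seq_len(nrow(edges))) {
    adde(edges$from[k], edges$to[k], edges$weight[k])
    adde(edges$to[k], edges$from[k], edges$weight[k])
  }
  out <- list()
  walk <- function(node, visited, weight) {
    if (node == target) {
      out[[length(out) + 1L]] <<- list(path = visited, weight = weight)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$to[k]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), weight + nb$w[k])
    }
  }
  walk(source, source, 0)
  out
}

# Brute-force minimum-weight paths: returns min weight and all
# co-optimal simple paths (tolerance for float ties).
brute_shortest <- function(edges, source, target, tol = 1e-9) {
  all <- enumerate_paths(edges, source, target)
  if (!length(all)) return(list(weight = Inf, paths = list()))
  w <- vapply(all, `[[`, 0, "weight")
  wmin <- min(w)
  list(weight = wmin,
       paths = lapply(all[w <= wmin + tol], `[[`, "path"))
}

# Brute-force edge betweenness: for every unordered node pair, find all
# minimum-weight simple paths and credit each traversed edge with
# 1/(number of co-optimal paths).
brute_betweenness <- function(edges, nodes = sort(unique(c(edges$from, edges$to))),
                              tol = 1e-9) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bw <- stats::setNames(numeric(nrow(edges)), key(edges$from, edges$to))
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      bs <- brute_shortest(edges, nodes[i], nodes[j], tol)
      np <- length(bs$paths)
      if (!np) next
      for (p in bs$paths) {
        ek <- key(p[-length(p)], p[-1])
        for (e in ek) bw[e] <- bw[e] + 1 / np
      }
    }
  }
  bw
}

# Random connected weighted graph on n nodes (node labels "A:i").
random_graph <- function(n, p = 0.45, seed = 1) {
  set.seed(seed)
  nm <- paste0("A:", seq_len(n))
  e <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # a spanning chain guarantees connectivity
      if (j == i + 1 || stats::runif(1) < p)
        e <- rbind(e, data.frame(from = nm[i], to = nm[j],
                                 weight = round(stats::runif(1, 0.05, 1), 3)))
    }
  }
  e
}

# Numeric superposition oracle: coarse axis-angle grid then Nelder-Mead
# refinement, independent of the closed-form Kabsch solution.
grid_superpose_rmsd <- function(mobile, fixed) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) sqrt(mean(rowSums((P %*% rot(v) - Q)^2)))
  best <- c(0, 0, 0); bval <- obj(best)
  for (ax in list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,0,1),
                  c(0,1,1), c(1,1,1), c(1,-1,0), c(0,1,-1), c(-1,0,1))) {
    for (th in seq(0, pi, length.out = 25)) {
      v <- th * ax / sqrt(sum(ax^2))
      val <- obj(v)
      if (val < bval) { bval <- val; best <- v }
    }
  }
  op <- stats::optim(best, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  op$value
}

# Minimal single-atom-per-residue structure on a line (for B-factor and
# profile tests).
line_structure <- function(b, chain = "A", resname = "ALA") {
  n <- length(b)
  structure_model(data.frame(
    name = "CA", resname = resname, chain = chain, resno = seq_len(n),
    x = 3.8 * seq_len(n), y = 0, z = 0, element = "C", b = b,
    stringsAsFactors = FALSE))
}

# Two-chain structure of single heavy-sphere "residues" for SASA and
# interface tests: chain A on the x axis, selected chain-B residues
# approached to within `close_y`, the rest far away.
sphere_dimer <- function(n = 8, close = 3:6, close_y = 4.5, far_y = 40) {
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resname = "ALA", chain = "A", resno = i,
      x = 5 * i, y = 0, z = 0, element = "C", stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resname = "ALA", chain = "B", resno = i,
      x = 5 * i, y = if (i %in% close) close_y else far_y, z = 0,
      element = "C", stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), id = "sphere_dimer")
}

# Brute-force reapplication of every screening predicate, independent of
# the ledger logic in screen_destabilizing().
brute_screen <- function(records, criteria) {
  q <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1,
         L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
         W = 0, Y = 0)
  keep <- logical(nrow(records))
  for (k in seq_len(nrow(records))) {
    r <- records[k, ]
    keep[k] <- r$position %in% criteria$interface_positions &&
      (r$ddG_F_dimer - r$ddG_F_monomer) >= criteria$ddgf_gap_min &&
      !(r$mut_aa %in% criteria$excluded_mutant_aas) &&
      (!criteria$require_charge_preserving ||
         q[[r$mut_aa]] == q[[r$wt_aa]]) &&
      !is.na(r$ddG_B) && r$ddG_B >= criteria$ddgb_min
  }
  records[keep, , drop = FALSE]
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(actual - expected)), tol))
}
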