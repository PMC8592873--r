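# Helper: ensemble whose two single-atom "residues" sit at prescribed
# center distances across frames (chains differ so no neighbor
# exclusion applies).
pair_series_ensemble <- function(distances) {
  at <- data.frame(name = c("CA", "CA"), resname = "GLY",
                   chain = c("A", "B"), resno = c(1L, 1L),
                   x = 0, y = 0, z = 0, element = "C",
                   stringsAsFactors = FALSE)
  top <- structure_model(at)
  xyz <- t(vapply(distances, function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  ensemble(top, xyz)
}

test_that("residue centers are the mass-weighted heavy-atom means", {
  at <- data.frame(name = c("N", "CA", "C", "O"), resname = "GLY",
                   chain = "A", resno = 1L,
                   x = c(0, 1, 2, 3), y = c(1, 0, 0, 2), z = c(0, 0, 4, 0),
                   element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  top <- structure_model(at)
  ens <- ensemble(top, matrix(as.numeric(t(as.matrix(at[, c("x","y","z")]))), 1))
  rc <- residue_centers(ens)
  m <- c(14.007, 12.011, 12.011, 15.999)
  byhand <- colSums(as.matrix(at[, c("x", "y", "z")]) * m) / sum(m)
  expect_close(as.numeric(rc$centers[1, ]), byhand, 1e-12)
})

test_that("centers shift exactly under rigid translation (equivariance)", {
  ens <- make_planted_ensemble(n_residues = 10, n_frames = 2, seed = 3)$ensemble
  rc1 <- residue_centers(ens)
  shifted <- ens
  shifted$xyz <- shifted$xyz +
    matrix(rep(c(1, 2, 3), ncol(ens$xyz) / 3), nrow = nrow(ens$xyz),
           ncol = ncol(ens$xyz), byrow = TRUE)
  rc2 <- residue_centers(shifted)
  delta <- rc2$centers - rc1$centers
  expect_close(delta[, seq(1, ncol(delta), 3)], 1, 1e-10)
  expect_close(delta[, seq(2, ncol(delta), 3)], 2, 1e-10)
  expect_close(delta[, seq(3, ncol(delta), 3)], 3, 1e-10)
})

test_that("contact occupancy is a sharp threshold on min heavy-atom distance", {
  expect_equal(contact_occupancy(pair_series_ensemble(4.4))["A:1", "B:1"], 1)
  expect_equal(contact_occupancy(pair_series_ensemble(4.6))["A:1", "B:1"], 0)
  occ <- contact_occupancy(pair_series_ensemble(c(4.0, 4.4, 4.6, 5.0)))
  expect_equal(occ["A:1", "B:1"], 0.5)
})

test_that("contact occupancy equals brute-force recomputation", {
  pe <- make_planted_ensemble(n_residues = 10, n_frames = 8, seed = 11)
  ens <- pe$ensemble
  occ <- contact_occupancy(ens, cutoff = 4.5)
  a <- ens$topology$atoms
  key <- paste0(a$chain, ":", a$resno)
  rid <- match(key, unique(key))
  R <- max(rid)
  count <- matrix(0, R, R)
  for (f in seq_len(n_frames(ens))) {
    xyz <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    D <- as.matrix(dist(xyz))
    for (i in seq_len(R - 1)) for (j in seq(i + 1, R)) {
      if (min(D[rid == i, rid == j]) <= 4.5)
        count[i, j] <- count[i, j] + 1
    }
  }
  for (i in seq_len(R - 1)) for (j in seq(i + 1, R))
    expect_equal(occ[i, j], count[i, j] / n_frames(ens))
})

test_that("edge weight follows the distance-series moments exactly", {
  params <- network_params(contact_cutoff = 10, occupancy_min = 0.5)
  # constant distance -> zero weight under both conventions
  net_const <- build_network(pair_series_ensemble(c(5, 5, 5)), params)
  expect_equal(net_const$edges$weight, 0)
  # series {4,6,8}: population mean 6, variance 8/3
  net_lit <- build_network(pair_series_ensemble(c(4, 6, 8)), params)
  expect_equal(net_lit$edges$weight, (8 / 3) / 6, tolerance = 1e-12)
  expect_equal(net_lit$edges$mean_distance, 6, tolerance = 1e-12)
  params_cv <- network_params(contact_cutoff = 10, occupancy_min = 0.5,
                              weight_convention = "sqrt_var_over_mean")
  net_cv <- build_network(pair_series_ensemble(c(4, 6, 8)), params_cv)
  expect_equal(net_cv$edges$weight, sqrt(8 / 3) / 6, tolerance = 1e-12)
})

test_that("network construction is invariant to global rigid motion", {
  pe <- make_planted_ensemble(n_residues = 12, n_frames = 20, seed = 4)
  net1 <- build_network(pe$ensemble)
  rot <- pe$ensemble
  a <- 1.3
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  for (f in seq_len(nrow(rot$xyz))) {
    m <- matrix(rot$xyz[f, ], ncol = 3, byrow = TRUE) %*% R
    rot$xyz[f, ] <- as.numeric(t(sweep(m, 2, c(10, -5, 3), "+")))
  }
  net2 <- build_network(rot)
  expect_identical(net1$edges[, c("from", "to")], net2$edges[, c("from", "to")])
  expect_close(net1$edges$weight, net2$edges$weight, 1e-9)
})

test_that("edge betweenness matches exhaustive enumeration on toy graphs", {
  # 3-node path a-b-c: both edges lie on 2 optimal pairs
  net <- make_net(data.frame(from = c("A:1", "A:2"), to = c("A:2", "A:3"),
                             weight = c(0.2, 0.3)))
  net <- edge_betweenness(net)
  expect_equal(sort(net$edges$betweenness), c(2, 2))
  # single edge: the unique pair
  net1 <- edge_betweenness(make_net(data.frame(from = "A:1", to = "A:2",
                                               weight = 0.5)))
  expect_equal(net1$edges$betweenness, 1)
})

test_that("betweenness and optimal paths agree with brute force on random graphs", {
  for (seed in 1:12) {
    n <- sample(4:8, 1)
    e <- random_graph(n, seed = seed)
    net <- edge_betweenness(make_net(e))
    bw <- brute_betweenness(e)
    key <- paste(pmin(net$edges$from, net$edges$to),
                 pmax(net$edges$from, net$edges$to))
    expect_close(net$edges$betweenness, unname(bw[key]), 1e-8)
    nodes <- sort(unique(c(e$from, e$to)))
    st <- sample(nodes, 2)
    bs <- brute_shortest(e, st[1], st[2])
    pr <- shortest_path(net, st[1], st[2])
    expect_equal(pr$weight, bs$weight, tolerance = 1e-9)
    oracle_paths <- sort(vapply(bs$paths, paste, "", collapse = " "))
    got_paths <- sort(vapply(pr$alternates, paste, "", collapse = " "))
    expect_identical(got_paths, oracle_paths)
  }
})

test_that("critical edges use mean + k sd, strict in the degenerate case", {
  # uniform betweenness -> nothing critical
  ring <- data.frame(from = paste0("A:", 1:4),
                     to = paste0("A:", c(2, 3, 4, 1)), weight = 1)
  net <- edge_betweenness(make_net(ring))
  expect_equal(nrow(critical_edges(net)), 0L)
  # star K_{1,5} with an appended path: the bridge edge dominates
  star <- data.frame(from = c(rep("A:1", 5), "A:6", "A:7"),
                     to = c(paste0("A:", 2:6), "A:7", "A:8"),
                     weight = 1)
  nets <- edge_betweenness(make_net(star))
  bw <- nets$edges$betweenness
  thr <- mean(bw) + 1.0 * sd(bw)
  want <- nets$edges[bw >= thr, c("from", "to")]
  got <- critical_edges(nets, sigma_k = 1.0)
  expect_setequal(paste(got$from, got$to), paste(want$from, want$to))
  bw_brute <- brute_betweenness(star)
  expect_close(sort(bw), sort(unname(bw_brute)), 1e-9)
})

test_that("shortest_path reports weight, co-optimal ties, and no-path", {
  net <- make_net(data.frame(from = "A:1", to = "B:1", weight = 0.27))
  pr <- shortest_path(net, "A:1", "B:1")
  expect_identical(pr$nodes, c("A:1", "B:1"))
  expect_equal(pr$weight, 0.27)
  # planted cheap chain beats an expensive direct edge
  e <- data.frame(from = c("A:1", "A:2", "A:3", "A:1"),
                  to = c("A:2", "A:3", "A:4", "A:4"),
                  weight = c(0.1, 0.1, 0.1, 1.0))
  pr2 <- shortest_path(make_net(e), "A:1", "A:4")
  expect_identical(pr2$nodes, paste0("A:", 1:4))
  bs <- brute_shortest(e, "A:1", "A:4")
  expect_equal(pr2$weight, bs$weight)
  # two equal-weight routes are both enumerated
  e3 <- data.frame(from = c("A:1", "A:2", "A:1", "A:3"),
                   to = c("A:2", "A:4", "A:3", "A:4"),
                   weight = 0.5)
  pr3 <- shortest_path(make_net(e3), "A:1", "A:4")
  expect_equal(length(pr3$alternates), 2L)
  # disconnected pair
  e4 <- data.frame(from = "A:1", to = "A:2", weight = 1)
  nodes4 <- data.frame(node = c("A:1", "A:2", "A:9"), chain = "A",
                       resno = c(1L, 2L, 9L), resname = "GLY")
  pr4 <- shortest_path(make_net(e4, nodes = nodes4), "A:1", "A:9")
  expect_false(pr4$reachable)
  expect_null(pr4$nodes)
})

test_that("doubling all weights doubles path weight, keeps structure", {
  e <- random_graph(7, seed = 21)
  net1 <- edge_betweenness(make_net(e))
  e2 <- e; e2$weight <- 2 * e$weight
  net2 <- edge_betweenness(make_net(e2))
  p1 <- shortest_path(net1, "A:1", "A:7")
  p2 <- shortest_path(net2, "A:1", "A:7")
  expect_identical(p1$nodes, p2$nodes)
  expect_equal(p2$weight, 2 * p1$weight, tolerance = 1e-12)
  expect_close(net2$edges$betweenness, net1$edges$betweenness, 1e-9)
  c1 <- critical_edges(net1, sigma_k = 1)
  c2 <- critical_edges(net2, sigma_k = 1)
  expect_identical(paste(c1$from, c1$to), paste(c2$from, c2$to))
})

test_that("interprotomer edges are exactly the cross-chain contacts", {
  pe <- make_planted_ensemble(n_residues = 14, n_frames = 300, seed = 8)
  net <- build_network(pe$ensemble)
  ce <- interprotomer_edges(net)
  got <- sort(paste(pmin(ce$from, ce$to), pmax(ce$from, ce$to)))
  tr <- pe$truth$cross_chain_contacts
  want <- sort(paste(pmin(tr$from, tr$to), pmax(tr$from, tr$to)))
  expect_identical(got, want)
  # single-chain network warns and returns empty
  e <- data.frame(from = "A:1", to = "A:3", weight = 1)
  expect_warning(out <- interprotomer_edges(make_net(e)), "single-chain")
  expect_equal(nrow(out), 0L)
})

test_that("neighbor exclusion removes covalent contacts but keeps cross-chain", {
  pe <- make_planted_ensemble(n_residues = 10, n_frames = 50, seed = 13)
  net <- build_network(pe$ensemble)
  same <- sub(":.*", "", net$edges$from) == sub(":.*", "", net$edges$to)
  dr <- abs(as.integer(sub(".*:", "", net$edges$from)) -
            as.integer(sub(".*:", "", net$edges$to)))
  expect_true(all(dr[same] >= 2))
  net0 <- build_network(pe$ensemble,
                        network_params(neighbor_exclusion = 0))
  expect_gt(nrow(net0$edges), nrow(net$edges))
})
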