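rigid_copy <- function(s, angle = 0.6, shift = c(3, -2, 5)) {
  R <- matrix(c(cos(angle), sin(angle), 0, -sin(angle), cos(angle), 0,
                0, 0, 1), 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

test_that("superpose recovers identity and rigid transforms", {
  s <- line_structure(b = rep(10, 8))
  s$atoms$y <- c(0, 1, 0, 2, 1, 0, 3, 1)  # break collinearity
  fit0 <- superpose(s, s)
  expect_lt(fit0$rmsd, 1e-12)
  expect_close(fit0$rotation, diag(3), 1e-10)
  m <- rigid_copy(s)
  fit <- superpose(s, m)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$n_pairs_used, 8L)
})

test_that("outlier rejection matches the numeric orientation oracle", {
  set.seed(77)
  ref <- line_structure(b = rep(10, 5))
  ref$atoms$y <- c(0, 2, 1, 3, 0.5)
  ref$atoms$z <- c(0, 1, 2, 0, 1.5)
  mob <- ref
  mob$atoms$x <- mob$atoms$x + rnorm(5, sd = 0.05)
  mob$atoms$y <- mob$atoms$y + rnorm(5, sd = 0.05)
  mob$atoms$z[5] <- mob$atoms$z[5] + 1.0  # one 1-A outlier
  fit_all <- superpose(ref, mob, mode = "all_pairs")
  oracle <- grid_superpose_rmsd(as.matrix(mob$atoms[, c("x", "y", "z")]),
                                as.matrix(ref$atoms[, c("x", "y", "z")]))
  expect_lt(abs(fit_all$rmsd - oracle), 1e-6)
  fit_rej <- superpose(ref, mob, mode = "iterative_reject")
  expect_lte(fit_rej$rmsd, fit_all$rmsd)
  if (length(fit_rej$rejected)) {
    kept <- !(paste0("A:", ref$atoms$resno) %in% fit_rej$rejected)
    oracle_kept <- grid_superpose_rmsd(
      as.matrix(mob$atoms[kept, c("x", "y", "z")]),
      as.matrix(ref$atoms[kept, c("x", "y", "z")]))
    expect_lt(abs(fit_rej$rmsd - oracle_kept), 1e-6)
  }
})

test_that("all-pairs RMSD never beats the rejected-mode RMSD", {
  for (seed in 1:5) {
    set.seed(seed)
    ref <- line_structure(b = rep(10, 12))
    ref$atoms$y <- runif(12, 0, 4)
    ref$atoms$z <- runif(12, 0, 4)
    mob <- ref
    mob$atoms$x <- mob$atoms$x + rnorm(12, sd = 0.2)
    mob$atoms$y <- mob$atoms$y + rnorm(12, sd = 0.2)
    a <- superpose(ref, mob, mode = "all_pairs")
    r <- superpose(ref, mob, mode = "iterative_reject")
    expect_lte(r$rmsd, a$rmsd + 1e-12)
  }
})

test_that("SASA reproduces analytic sphere and overlap areas", {
  iso <- structure_model(data.frame(
    name = "C1", resname = "LIG", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  sr <- sasa(iso, include_hetero = TRUE)
  expect_close(sr$atom$sasa / (4 * pi * 3.1^2), 1, 0.015)
  two <- function(d) structure_model(data.frame(
    name = c("C1", "C2"), resname = "LIG", chain = c("A", "B"),
    resno = 1:2, x = c(0, d), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE))
  # tangent spheres: no burial
  R <- 1.7 + 1.4
  st <- sasa(two(2 * R), include_hetero = TRUE)
  expect_close(st$atom$sasa / (4 * pi * R^2), 1, 0.015)
  # overlapping spheres: spherical-cap oracle (equal radii, h = R - d/2)
  d <- 3.0
  cap <- 2 * pi * R * (R - d / 2)
  so <- sasa(two(d), include_hetero = TRUE)
  expect_close(so$atom$sasa / (4 * pi * R^2 - cap), 1, 0.01)
})

test_that("SASA is invariant under rigid motion and errors on unknown radii", {
  pe <- make_planted_ensemble(n_residues = 10, n_frames = 2, seed = 3)
  top <- pe$ensemble$topology
  s1 <- sasa(top)
  s2 <- sasa(rigid_copy(top, angle = 1.1, shift = c(-4, 8, 2)))
  expect_close(s2$atom$sasa, s1$atom$sasa, 1e-9)
  odd <- structure_model(data.frame(
    name = "X1", resname = "LIG", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "XX", stringsAsFactors = FALSE))
  expect_error(sasa(odd, include_hetero = TRUE), "radius")
  ok <- sasa(odd, include_hetero = TRUE, fallback_radius = 1.7)
  expect_close(ok$atom$sasa / (4 * pi * 3.1^2), 1, 0.015)
})

test_that("interface flagging finds exactly the planted buried residues", {
  dim_far <- sphere_dimer(close = integer(0))
  rep_far <- interface_residues(dim_far, "A", "B")
  expect_equal(nrow(rep_far$interface), 0L)
  dim4 <- sphere_dimer(close = 3:6)
  rep4 <- interface_residues(dim4, "A", "B")
  got <- sort(paste0(rep4$interface$chain, ":", rep4$interface$resno))
  expect_identical(got, sort(c(paste0("A:", 3:6), paste0("B:", 3:6))))
  expect_error(interface_residues(dim4, "A", "Z"), "chain")
})

test_that("buried surface area is symmetric, zero for separated chains", {
  far <- sphere_dimer(close = integer(0))
  expect_close(buried_surface_area(far, "A", "B")$bsa, 0, 1e-9)
  dim4 <- sphere_dimer(close = 3:6)
  ab <- buried_surface_area(dim4, "A", "B")
  ba <- buried_surface_area(dim4, "B", "A")
  expect_equal(ab$bsa, ba$bsa, tolerance = 1e-12)
  expect_equal(ab$interface_area, ab$bsa / 2)
  # two overlapping spheres: BSA equals both buried caps
  two <- structure_model(data.frame(
    name = c("CA", "CA"), resname = "ALA", chain = c("A", "B"),
    resno = c(1, 1), x = c(0, 3), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE))
  R <- 3.1
  cap <- 2 * pi * R * (R - 1.5)
  bsa <- buried_surface_area(two, "A", "B")$bsa
  expect_close(bsa / (2 * cap), 1, 0.01)
})

test_that("polar contacts honor the distance criteria and classes", {
  mk <- function(d, res1 = "ARG", a1 = "NH1", res2 = "ASP", a2 = "OD1",
                 e1 = "N", e2 = "O") {
    structure_model(data.frame(
      name = c(a1, a2), resname = c(res1, res2), chain = c("A", "B"),
      resno = c(1, 1), x = c(0, d), y = 0, z = 0, element = c(e1, e2),
      stringsAsFactors = FALSE))
  }
  sb <- polar_contacts(mk(3.9))
  expect_equal(sb$class, "salt_bridge")
  expect_equal(nrow(polar_contacts(mk(4.1))), 0L)
  hb <- polar_contacts(mk(3.4, res1 = "SER", a1 = "OG", e1 = "O",
                          res2 = "THR", a2 = "OG1", e2 = "O"))
  expect_equal(hb$class, "hbond")
  # glycine backbone pair: can hydrogen-bond but never salt-bridge
  gg <- polar_contacts(mk(3.0, res1 = "GLY", a1 = "O", e1 = "O",
                          res2 = "GLY", a2 = "N", e2 = "N"))
  expect_true(all(gg$class == "hbond"))
})

test_that("atom distances resolve specs and compute Euclidean lengths", {
  s <- structure_model(data.frame(
    name = c("CA", "CA"), resname = "GLY", chain = c("A", "B"),
    resno = c(16, 16), x = c(0, 3), y = c(0, 4), z = 0, element = "C",
    stringsAsFactors = FALSE))
  expect_equal(atom_distance(s, "A:16:CA", "A:16:CA"), 0)
  expect_equal(atom_distance(s, "A:16:CA", "B:16:CA"), 5)
  expect_error(atom_distance(s, "C:1:CA", "A:16:CA"), "resolves")
})
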