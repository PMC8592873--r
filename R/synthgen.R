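# Seeded generators with planted ground truth for every input class the
# pipeline consumes: dimer ensembles with a planted minimum-weight path,
# elastic-network ensembles with analytic flexibility, ddG screening
# tables with known pass sets, and noisy biophysical curves.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Base geometry of the toy dimer: two staggered zig-zag chains of
# `n_residues` pseudo-residues (4 heavy atoms each: N, CA, C, O in a
# small tetrahedron around the residue center), approaching each other
# near the chain midpoints so that only a handful of cross-chain
# residue pairs are in contact.
.toy_dimer_geometry <- function(n_residues) {
  stopifnot(n_residues >= 10L)
  c0 <- floor(n_residues / 2)
  if (c0 %% 2L == 0L) c0 <- c0 + 1L  # keep the crossing parity fixed
  # two zig-zag chains crossing perpendicularly 3.4 A apart: only the
  # residues near the crossing point are in cross-chain contact, and no
  # residue pair falls in the contact ambiguity band (4.2-4.8 A)
  centers <- function(chain) {
    i <- seq_len(n_residues)
    if (chain == "A") {
      cbind(2.15 * i, 0.8 * (i %% 2), 0)
    } else {
      cbind(2.15 * c0 + 0.8 * (i %% 2), 2.15 * (i - c0), 3.4)
    }
  }
  offs <- rbind(c(0.3, 0.3, 0.3), c(-0.3, -0.3, 0.3),
                c(-0.3, 0.3, -0.3), c(0.3, -0.3, -0.3))
  anames <- c("N", "CA", "C", "O")
  elems <- c("N", "C", "C", "O")
  rows <- list()
  for (ch in c("A", "B")) {
    cc <- centers(ch)
    for (r in seq_len(n_residues)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = anames, resname = "GLY", chain = ch, resno = r,
        x = cc[r, 1] + offs[, 1], y = cc[r, 2] + offs[, 2],
        z = cc[r, 3] + offs[, 3], element = elems,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, id = "toy_dimer")
}

# Minimum heavy-atom distance between every residue pair of a static
# structure (used to derive the ground-truth contact set).
.static_min_dists <- function(topology) {
  a <- topology$atoms
  key <- .residue_key(a)
  rid <- match(key, unique(key))
  D <- as.matrix(stats::dist(as.matrix(a[, c("x", "y", "z")])))
  R <- max(rid)
  out <- matrix(Inf, R, R)
  for (i in seq_len(R - 1)) {
    ri <- which(rid == i)
    for (j in seq((i + 1), R)) {
      out[i, j] <- out[j, i] <- min(D[ri, which(rid == j)])
    }
  }
  dimnames(out) <- list(unique(key), unique(key))
  out
}

#' Generate a dimer ensemble with a planted minimum-weight path
#'
#' Builds a toy two-chain structure whose contact topology is a
#' step-two ladder along each chain plus a small cross-chain interface,
#' then realizes Gaussian per-residue rigid-body fluctuations: residues
#' on the planted path fluctuate little (target distance coefficient of
#' variation `cv_low`), all others a lot (`cv_high`). The minimum-weight
#' interprotomer path through the network is then the planted one by
#' construction, with the cheapest interface crossing on it.
#'
#' @param n_residues Residues per chain.
#' @param n_frames Frames to generate.
#' @param cv_low,cv_high Target distance CVs on/off the planted path
#'   (sd/mean convention); their ratio is the planted contrast.
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments.
#' @return List with `ensemble` (an [ensemble()]) and `truth`: planted
#'   `path` (node keys), `source`, `target`, `expected_weight` (under
#'   the literal variance/mean convention), `expected_weight_cv`
#'   (sd/mean), `cross_chain_contacts` (data.frame), `degenerate` flag.
#' @export
make_planted_ensemble <- function(n_residues = 30L, n_frames = 2000L,
                                  cv_low = 0.02, cv_high = 0.08,
                                  seed = 1L) {
  stopifnot(cv_low > 0, cv_high >= cv_low, n_frames >= 2L)
  top <- .toy_dimer_geometry(n_residues)
  mind <- .static_min_dists(top)
  nodes <- rownames(mind)
  # ground-truth contact set from the base geometry; demand a clear
  # margin band so occupancy cannot straddle the 75% criterion
  contact <- mind <= 4.2
  band <- mind > 4.2 & mind < 4.8
  if (any(band[upper.tri(band)]))
    stop("infeasible geometry: residue pair(s) in the contact margin band")
  chain_of <- sub(":.*", "", nodes)
  resno_of <- as.integer(sub(".*:", "", nodes))
  cross <- which(contact & outer(chain_of, chain_of, "!="), arr.ind = TRUE)
  cross <- cross[cross[, 1] < cross[, 2], , drop = FALSE]
  if (!nrow(cross)) stop("infeasible geometry: no cross-chain contacts")
  cross_df <- data.frame(from = nodes[cross[, 1]], to = nodes[cross[, 2]],
                         distance = mind[cross], stringsAsFactors = FALSE)
  cross_df <- cross_df[order(cross_df$distance), ]
  rownames(cross_df) <- NULL
  # plant the path through the geometrically closest interface pair
  pick <- cross_df[1, ]
  a_node <- if (startsWith(pick$from, "A")) pick$from else pick$to
  b_node <- if (startsWith(pick$from, "B")) pick$from else pick$to
  ia <- as.integer(sub(".*:", "", a_node))
  jb <- as.integer(sub(".*:", "", b_node))
  c0 <- floor(n_residues / 2)
  if (c0 %% 2L == 0L) c0 <- c0 + 1L
  # chain-A leg runs from the low end up to the crossing; chain-B leg
  # runs from the crossing away from the interface region, so no second
  # cross-contact can short-circuit the planted route
  sa <- 2L - (ia %% 2L)  # chain-A end residue with the parity of ia
  db <- if (jb >= c0) 1L else -1L
  tb <- if (db > 0L) jb + 2L * ((n_residues - jb) %/% 2L)
        else jb - 2L * ((jb - 1L) %/% 2L)
  path <- c(paste0("A:", seq(sa, ia, by = 2L)),
            paste0("B:", seq(jb, tb, by = db * 2L)))
  on_path <- nodes %in% path
  # per-residue displacement scales from the target CVs at the typical
  # contact distance
  d_ref <- 4.2
  s_low <- cv_low * d_ref / sqrt(2)
  s_high <- cv_high * d_ref / sqrt(2)
  sig <- ifelse(on_path, s_low, s_high)
  A <- nrow(top$atoms)
  rid <- match(.residue_key(top$atoms), nodes)
  base <- as.numeric(t(.coords(top)))
  xyz <- .with_seed(seed, {
    disp <- array(stats::rnorm(n_frames * length(nodes) * 3L),
                  dim = c(n_frames, length(nodes), 3L))
    out <- matrix(base, nrow = n_frames, ncol = 3L * A, byrow = TRUE)
    for (k in 1:3) {
      d_at <- matrix(disp[, rid, k], nrow = n_frames) *
        matrix(sig[rid], n_frames, A, byrow = TRUE)
      out[, seq(k, 3L * A, by = 3L)] <- out[, seq(k, 3L * A, by = 3L)] + d_at
    }
    out
  })
  ens <- ensemble(top, xyz)
  # analytic expected-weight graph over the base contact set; the
  # planted path is its geodesic (a sanity guarantee for any n)
  cen <- .pair_stats(ensemble(top, matrix(base, nrow = 1)), 4.5)
  pairs <- which(contact & upper.tri(contact), arr.ind = TRUE)
  excl <- chain_of[pairs[, 1]] == chain_of[pairs[, 2]] &
    abs(resno_of[pairs[, 1]] - resno_of[pairs[, 2]]) <= 1L
  pairs <- pairs[!excl, , drop = FALSE]
  w_exp <- (sig[pairs[, 1]]^2 + sig[pairs[, 2]]^2) / cen$mean_d[pairs]
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
               weight = w_exp), directed = FALSE,
    vertices = data.frame(name = nodes))
  geo <- igraph::all_shortest_paths(g, from = path[1],
                                    to = path[length(path)],
                                    weights = igraph::E(g)$weight)$vpaths
  geo <- lapply(geo, igraph::as_ids)
  geo <- geo[order(vapply(geo, paste, "", collapse = " "))]
  path <- geo[[1]]
  path_idx <- match(path, nodes)
  ij <- cbind(path_idx[-length(path_idx)], path_idx[-1])
  d0 <- cen$mean_d[ij]
  var_e <- sig[ij[, 1]]^2 + sig[ij[, 2]]^2
  truth <- list(path = path, source = path[1], target = path[length(path)],
                expected_weight = sum(var_e / d0),
                expected_weight_cv = sum(sqrt(var_e) / d0),
                cross_chain_contacts = cross_df,
                degenerate = cv_low == cv_high || length(geo) > 1L,
                cv_low = cv_low, cv_high = cv_high, seed = seed)
  list(ensemble = ens, truth = truth)
}

#' Generate an elastic-network (ENM) Gaussian ensemble
#'
#' Frames are drawn from the multivariate normal whose covariance is
#' `kT` times the pseudo-inverse of the Hookean (anisotropic
#' network model) Hessian built from `coords` with uniform spring
#' constant `k_spring` within `cutoff`. Analytic per-particle variances
#' are returned for validation of fluctuation estimators.
#'
#' @param coords n x 3 reference coordinates.
#' @param cutoff Spring cutoff (Angstrom).
#' @param k_spring Uniform spring constant (arbitrary energy/A^2).
#' @param kT Temperature scale (same energy units).
#' @param n_frames Frames to draw.
#' @param seed RNG seed.
#' @return List with `xyz` (F x 3n coordinate matrix around the
#'   reference), `variance` (analytic per-particle positional variance,
#'   summed over x,y,z), `covariance` (3n x 3n), `n_zero_modes`.
#' @export
make_enm_ensemble <- function(coords, cutoff = 8, k_spring = 1, kT = 1,
                              n_frames = 1000L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 2L, ncol(coords) == 3L)
  H <- matrix(0, 3 * n, 3 * n)
  D <- as.matrix(stats::dist(coords))
  # the spring network must be connected, else variances are infinite
  adj <- D <= cutoff & D > 0
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    nxt <- which(adj[queue[1], ] & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue[-1], nxt)
  }
  if (!all(seen))
    stop("disconnected spring network: infinite variance")
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (D[i, j] > cutoff || D[i, j] == 0) next
      e <- (coords[j, ] - coords[i, ]) / D[i, j]
      blk <- k_spring * tcrossprod(e)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
    }
  }
  eg <- eigen(H, symmetric = TRUE)
  tol <- 1e-9 * max(eg$values)
  nz <- eg$values > tol
  n_zero <- sum(!nz)
  if (n_zero > 6L)
    stop("disconnected spring network (", n_zero,
         " zero modes): infinite variance")
  V <- eg$vectors[, nz, drop = FALSE]
  lam <- eg$values[nz]
  covar <- V %*% (t(V) * (kT / lam))
  pervar <- vapply(seq_len(n), function(i)
    sum(diag(covar)[(3 * i - 2):(3 * i)]), 0)
  xyz <- .with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * length(lam)), n_frames)
    fluct <- z %*% (t(V) * sqrt(kT / lam))
    sweep(fluct, 2, as.numeric(t(coords)), "+")
  })
  list(xyz = xyz, variance = pervar, covariance = covar,
       n_zero_modes = n_zero)
}

#' Generate a ddG screening table with a known pass set
#'
#' Produces candidate point mutations such that rows at `pass_positions`
#' satisfy every screening criterion with at least `margin` kcal/mol to
#' spare, while every other row violates at least one named criterion
#' (also by a clear margin). The emitted truth ledger is sufficient for
#' downstream assertions.
#'
#' @param n_positions Number of distinct sequence positions.
#' @param pass_positions Positions whose best rows must survive the
#'   screen.
#' @param criteria A [screen_criteria()]; its interface set defaults to
#'   the pass positions plus a few decoy interface positions.
#' @param margin Safety margin (kcal/mol) applied on both sides of every
#'   threshold.
#' @param seed RNG seed.
#' @return List with `records` (a `ddg_records` table), `criteria`, and
#'   `truth` (`pass_positions`, per-row `expected_fail`).
#' @export
make_ddg_table <- function(n_positions = 50L, pass_positions = c(16, 18, 91, 135),
                           criteria = NULL, margin = 0.5, seed = 1L) {
  .with_seed(seed, {
    positions <- sort(unique(as.integer(c(
      pass_positions,
      sample(setdiff(1:150, pass_positions),
             n_positions - length(pass_positions))))))
    pass_positions <- as.integer(pass_positions)
    if (!all(pass_positions %in% positions))
      stop("pass_positions must be among the generated positions")
    if (is.null(criteria)) {
      decoys <- sample(setdiff(positions, pass_positions),
                       min(6L, length(positions) - length(pass_positions)))
      criteria <- screen_criteria(c(pass_positions, decoys))
    }
    ok_aa <- setdiff(names(.AA_CHARGE), c("G", "P", "C"))
    neutral <- names(.AA_CHARGE)[.AA_CHARGE == 0]
    neutral_ok <- setdiff(neutral, c("G", "P", "C"))
    rows <- list()
    add <- function(position, wt, mut, gap, ddgb) {
      mono <- stats::runif(1, -1, 1)
      rows[[length(rows) + 1L]] <<- data.frame(
        position = position, wt_aa = wt, mut_aa = mut,
        ddG_F_monomer = mono, ddG_F_dimer = mono + gap, ddG_B = ddgb,
        stringsAsFactors = FALSE)
    }
    for (p in positions) {
      wt <- sample(neutral_ok, 1)  # neutral wt keeps charge logic simple
      if (p %in% pass_positions) {
        for (r in 1:2)
          add(p, wt, sample(setdiff(neutral_ok, wt), 1),
              gap = 2 + margin + stats::runif(1, 0, 2),
              ddgb = 4 + margin + stats::runif(1, 0, 2))
        # plus a decoy row failing the residue-exclusion filter
        add(p, wt, sample(c("G", "P", "C"), 1),
            gap = 2 + margin + stats::runif(1, 0, 2),
            ddgb = 4 + margin + stats::runif(1, 0, 2))
      } else if (p %in% criteria$interface_positions) {
        # interface decoys: energetics or chemistry fail
        for (kind in sample(c("gap", "ddgb", "aa", "charge"), 2)) {
          if (kind == "gap")
            add(p, wt, sample(setdiff(neutral_ok, wt), 1),
                gap = 2 - margin - stats::runif(1, 0, 2),
                ddgb = 4 + margin + stats::runif(1, 0, 2))
          else if (kind == "ddgb")
            add(p, wt, sample(setdiff(neutral_ok, wt), 1),
                gap = 2 + margin + stats::runif(1, 0, 2),
                ddgb = 4 - margin - stats::runif(1, 0, 2))
          else if (kind == "aa")
            add(p, wt, sample(c("G", "P", "C"), 1),
                gap = 2 + margin + stats::runif(1, 0, 2),
                ddgb = 4 + margin + stats::runif(1, 0, 2))
          else
            add(p, wt, sample(c("D", "E", "K", "R"), 1),
                gap = 2 + margin + stats::runif(1, 0, 2),
                ddgb = 4 + margin + stats::runif(1, 0, 2))
        }
      } else {
        for (r in 1:3)
          add(p, wt, sample(setdiff(ok_aa, wt), 1),
              gap = stats::runif(1, -2, 4), ddgb = stats::runif(1, 0, 6))
      }
    }
    records <- ddg_records(do.call(rbind, rows))
    res <- screen_destabilizing(records, criteria)
    list(records = records, criteria = criteria,
         truth = list(pass_positions = sort(unique(pass_positions)),
                      expected_fail = res$ledger$fail_reason, seed = seed))
  })
}

#' Generate a noisy biophysical curve with known truth
#'
#' Evaluates the closed-form measurement model of the requested kind on
#' its standard grid and adds seeded noise: multiplicative Gaussian for
#' the diffusion decay, additive Gaussian otherwise.
#'
#' @param kind One of `"decay"`, `"dose_response"`, `"melt"`,
#'   `"exchange"`.
#' @param truth Named list of true parameters; missing entries take the
#'   kind's defaults (`decay`: I0 100, D 1e-10 m^2/s on the 40-step
#'   3.6-32.5 G/cm gradient grid; `dose_response`: bottom 0, top 100,
#'   hill 1, ec50 8.4 uM on a duplicated 1-50 uM log grid; `melt`:
#'   tm 67.8 C, width 2 C plateaus -10/-2 on a 20-80 C, 1 C grid;
#'   `exchange`: kd 0.06 uM, plateaus 1/0 on a 16-point 2-fold dilution
#'   series from 50 uM).
#' @param noise Noise scale: relative sd for `decay`, absolute sd
#'   otherwise.
#' @param seed RNG seed.
#' @param x Optional custom x grid overriding the default.
#' @return List: `kind`, `x`, `y`, `truth` (completed), `noise`,
#'   `noise_model`, plus instrument constants for `decay`.
#' @export
make_curves <- function(kind = c("decay", "dose_response", "melt", "exchange"),
                        truth = list(), noise = 0, seed = 1L, x = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    decay = list(I0 = 100, D = 1e-10, delta = 8.6e-3, Delta = 70e-3,
                 tau = 0.226e-3, gamma = .H1_GAMMA),
    dose_response = list(bottom = 0, top = 100, hill = 1, ec50 = 8.4),
    melt = list(tm = 67.8, width = 2, folded = -10, unfolded = -2),
    exchange = list(kd = 0.06, s_free = 1, s_bound = 0, labeled = 0.005))
  truth <- utils::modifyList(defaults, truth)
  if (is.null(x)) {
    x <- switch(kind,
      decay = seq(3.6, 32.5, length.out = 40),            # G/cm
      dose_response = rep(exp(seq(log(1), log(50), length.out = 8)), each = 2),
      melt = seq(20, 80, by = 1),
      exchange = truth$labeled + 50 / 2^(0:15))
  }
  y0 <- switch(kind,
    decay = {
      gT <- x * 0.01
      k <- (truth$gamma * gT * truth$delta)^2 *
        (truth$Delta - truth$delta / 3 - truth$tau / 2)
      truth$I0 * exp(-truth$D * k)
    },
    dose_response = .fourpl(log10(x), truth$bottom, truth$top, truth$hill,
                            log10(truth$ec50)),
    melt = truth$folded + (truth$unfolded - truth$folded) /
      (1 + exp(-(x - truth$tm) / truth$width)),
    exchange = truth$s_free + (truth$s_bound - truth$s_free) *
      dimer_monomer_fractions(x, truth$kd)$fraction_dimer)
  noise_model <- if (kind == "decay") "multiplicative_gaussian"
                 else "additive_gaussian"
  y <- .with_seed(seed, {
    eps <- stats::rnorm(length(y0), 0, noise)
    if (kind == "decay") y0 * (1 + eps) else y0 + eps
  })
  out <- list(kind = kind, x = x, y = y, truth = truth, noise = noise,
              noise_model = noise_model, seed = seed)
  if (kind == "decay")
    out$instrument <- truth[c("delta", "Delta", "tau", "gamma")]
  out
}
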