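#' Superpose two structures on paired C-alpha atoms
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `reference`
#' over C-alpha atoms paired by (chain, residue number, insertion
#' code). `iterative_reject` additionally runs up to `max_cycles`
#' outlier-rejection cycles, discarding pairs whose deviation exceeds
#' twice the current RMSD and refitting until the pair set is stable --
#' the behaviour of the molecular-graphics aligners usually behind
#' published RMSDs. The all-pairs RMSD is always reported alongside.
#'
#' @param reference,mobile `structure_model`s.
#' @param mode `"all_pairs"` or `"iterative_reject"`.
#' @param chains Optional chain subset used for pairing.
#' @param max_cycles Maximum rejection cycles.
#' @return A `superposition_result`: rotation (3 x 3, det +1),
#'   translation, `rmsd` (final mode RMSD), `rmsd_all_pairs`,
#'   `n_pairs_used`, `rejected` (node keys), `n_cycles`.
#' @export
superpose <- function(reference, mobile,
                      mode = c("all_pairs", "iterative_reject"),
                      chains = NULL, max_cycles = 5L) {
  mode <- match.arg(mode)
  ra <- select_atoms(reference, chain = chains, name = "CA",
                     protein_only = TRUE)$atoms
  ma <- select_atoms(mobile, chain = chains, name = "CA",
                     protein_only = TRUE)$atoms
  rk <- .residue_key(ra); mk <- .residue_key(ma)
  shared <- intersect(rk, mk)
  if (length(shared) < 3L) stop("fewer than 3 paired C-alpha atoms")
  P <- as.matrix(ma[match(shared, mk), c("x", "y", "z")])
  Q <- as.matrix(ra[match(shared, rk), c("x", "y", "z")])
  fit_all <- kabsch_fit(P, Q)
  keep <- rep(TRUE, length(shared))
  fit <- fit_all
  cycles <- 0L
  if (mode == "iterative_reject") {
    for (cyc in seq_len(max_cycles)) {
      moved <- sweep(P %*% fit$rotation, 2, fit$translation, "+")
      dev <- sqrt(rowSums((moved - Q)^2))
      new_keep <- dev <= 2 * fit$rmsd
      new_keep[!keep] <- FALSE
      if (sum(new_keep) < 3L) break
      if (identical(new_keep, keep)) break
      keep <- new_keep
      fit <- kabsch_fit(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
      cycles <- cyc
    }
  }
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, rmsd_all_pairs = fit_all$rmsd,
                 n_pairs_used = sum(keep), rejected = shared[!keep],
                 n_cycles = cycles, mode = mode),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition (%s): rmsd %.3f A over %d pairs", x$mode,
              x$rmsd, x$n_pairs_used))
  if (x$mode == "iterative_reject")
    cat(sprintf(" (all-pairs rmsd %.3f A, %d pair(s) rejected)",
                x$rmsd_all_pairs, length(x$rejected)))
  cat("\n")
  invisible(x)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA over heavy atoms with a deterministic
#' golden-spiral point set (no random numbers; the point set is anchored
#' to a local atomic frame, so areas are invariant under rigid motion of
#' the structure). Radii come from a bundled Chothia-style table
#' (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom).
#'
#' @param structure A `structure_model`; hydrogens are ignored.
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere sample points per atom.
#' @param include_hetero Include non-water heteroatoms as occluders and
#'   in the output.
#' @param fallback_radius Radius for elements missing from the table;
#'   `NULL` (default) raises an error instead.
#' @return A `sasa_result`: `atom` (data.frame with per-atom `sasa`),
#'   `residue` (chain, resno, resname, sasa, rel_acc -- fraction of the
#'   bundled theoretical maximum, `NA` for non-standard residues),
#'   `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L,
                 include_hetero = FALSE, fallback_radius = NULL) {
  s <- heavy_atoms(structure)
  keep <- !s$atoms$water
  if (!include_hetero) keep <- keep & !s$atoms$het
  a <- s$atoms[keep, , drop = FALSE]
  if (!nrow(a)) stop("no atoms selected for SASA")
  radii <- .VDW_RADIUS[a$element]
  if (anyNA(radii)) {
    if (is.null(fallback_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unique(a$element[is.na(radii)]), collapse = ", "),
           " (supply fallback_radius to override)")
    radii[is.na(radii)] <- fallback_radius
  }
  area <- cpp_sasa(as.matrix(a[, c("x", "y", "z")]), as.numeric(radii),
                   probe, as.integer(n_points))
  a$sasa <- area
  key <- .residue_key(a)
  rid <- match(key, unique(key))
  first <- !duplicated(rid)
  res <- data.frame(node = key[first], chain = a$chain[first],
                    resno = a$resno[first], resname = a$resname[first],
                    sasa = as.numeric(tapply(area, rid, sum)),
                    stringsAsFactors = FALSE)
  res$rel_acc <- res$sasa / .MAX_SASA[res$resname]
  structure(list(atom = a, residue = res, probe = probe,
                 n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' Interface residues by monomer-vs-dimer accessibility change
#'
#' For every residue of the two chains, relative accessibility is
#' computed in the isolated chain and in the dimer; residues losing more
#' than `threshold` percentage points upon dimerization are flagged as
#' interface residues -- the prioritization filter for interface
#' mutation candidates.
#'
#' @param dimer A `structure_model` containing both chains.
#' @param chain_a,chain_b Chain identifiers.
#' @param threshold Accessibility change (percentage points of relative
#'   accessibility) above which a residue is called interface.
#' @param probe,n_points Passed to [sasa()].
#' @return An `interface_report`: `residue` data.frame (node, chain,
#'   resno, resname, rel_mono, rel_dimer, delta_pp, interface flag) and
#'   `interface` (the flagged subset), plus the threshold.
#' @export
interface_residues <- function(dimer, chain_a, chain_b, threshold = 10,
                               probe = 1.4, n_points = 960L) {
  for (ch in c(chain_a, chain_b))
    if (!ch %in% dimer$atoms$chain) stop("chain not in structure: ", ch)
  both <- select_atoms(dimer, chain = c(chain_a, chain_b), protein_only = TRUE)
  sd_dimer <- sasa(both, probe = probe, n_points = n_points)
  res <- sd_dimer$residue
  res$rel_dimer <- res$rel_acc
  res$rel_mono <- NA_real_
  for (ch in c(chain_a, chain_b)) {
    mono <- sasa(select_atoms(dimer, chain = ch, protein_only = TRUE),
                 probe = probe, n_points = n_points)
    idx <- match(mono$residue$node, res$node)
    res$rel_mono[idx] <- mono$residue$rel_acc
  }
  res$delta_pp <- 100 * (res$rel_mono - res$rel_dimer)
  res$interface <- !is.na(res$delta_pp) & res$delta_pp > threshold
  res <- res[, c("node", "chain", "resno", "resname", "rel_mono",
                 "rel_dimer", "delta_pp", "interface")]
  structure(list(residue = res, interface = res[res$interface, , drop = FALSE],
                 threshold = threshold),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report:", nrow(x$interface), "interface residue(s) at >",
      x$threshold, "percentage-point accessibility change\n")
  if (nrow(x$interface))
    print(x$interface[, c("node", "resname", "delta_pp")], row.names = FALSE)
  invisible(x)
}

#' Buried surface area of a two-chain interface
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(AB); the interface area,
#' by the usual convention, is BSA/2.
#'
#' @param dimer A `structure_model`.
#' @param chain_a,chain_b Chain identifiers.
#' @param probe,n_points Passed to [sasa()].
#' @return List with `bsa` and `interface_area` (Angstrom^2).
#' @export
buried_surface_area <- function(dimer, chain_a, chain_b, probe = 1.4,
                                n_points = 960L) {
  sa <- function(ch) sum(sasa(select_atoms(dimer, chain = ch,
                                           protein_only = TRUE),
                              probe = probe, n_points = n_points)$atom$sasa)
  sab <- sum(sasa(select_atoms(dimer, chain = c(chain_a, chain_b),
                               protein_only = TRUE),
                  probe = probe, n_points = n_points)$atom$sasa)
  bsa <- sa(chain_a) + sa(chain_b) - sab
  list(bsa = bsa, interface_area = bsa / 2)
}

#' Census of polar contacts (hydrogen bonds and salt bridges)
#'
#' Distance-only criteria suited to crystal structures without
#' hydrogens: a hydrogen bond is any N/O--N/O heavy-atom pair of
#' distinct residues within `hbond_cutoff`; a salt bridge is a
#' side-chain nitrogen of Arg/Lys/His within `salt_cutoff` of a
#' side-chain carboxylate oxygen of Asp/Glu (classified in preference to
#' hbond).
#'
#' @param structure A `structure_model`.
#' @param cross_chain_only Report only contacts whose residues lie on
#'   different chains.
#' @param hbond_cutoff,salt_cutoff Distance criteria (Angstrom).
#' @return data.frame: chain1, resno1, resname1, atom1, chain2, resno2,
#'   resname2, atom2, distance, class.
#' @export
polar_contacts <- function(structure, cross_chain_only = TRUE,
                           hbond_cutoff = 3.5, salt_cutoff = 4.0) {
  s <- heavy_atoms(structure)
  a <- s$atoms[!s$atoms$water & !s$atoms$het, , drop = FALSE]
  polar <- a[a$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(chain1 = character(), resno1 = integer(),
                      resname1 = character(), atom1 = character(),
                      chain2 = character(), resno2 = integer(),
                      resname2 = character(), atom2 = character(),
                      distance = numeric(), class = character())
  if (nrow(polar) < 2L) return(empty)
  xyz <- as.matrix(polar[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  maxcut <- max(hbond_cutoff, salt_cutoff)
  idx <- which(upper.tri(d) & d <= maxcut, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  same_res <- .residue_key(polar)[i] == .residue_key(polar)[j]
  i <- i[!same_res]; j <- j[!same_res]
  if (!length(i)) return(empty)
  is_sb_pair <- function(p, q) {
    dn <- .SB_DONOR_ATOMS[[polar$resname[p]]]
    ac <- .SB_ACCEPTOR_ATOMS[[polar$resname[q]]]
    !is.null(dn) && !is.null(ac) &&
      polar$name[p] %in% dn && polar$name[q] %in% ac
  }
  dist_ij <- d[cbind(i, j)]
  cls <- character(length(i))
  for (k in seq_along(i)) {
    sb <- (is_sb_pair(i[k], j[k]) || is_sb_pair(j[k], i[k])) &&
      dist_ij[k] <= salt_cutoff
    if (sb) cls[k] <- "salt_bridge"
    else if (dist_ij[k] <= hbond_cutoff) cls[k] <- "hbond"
  }
  keep <- cls != ""
  i <- i[keep]; j <- j[keep]; cls <- cls[keep]; dist_ij <- dist_ij[keep]
  out <- data.frame(chain1 = polar$chain[i], resno1 = polar$resno[i],
                    resname1 = polar$resname[i], atom1 = polar$name[i],
                    chain2 = polar$chain[j], resno2 = polar$resno[j],
                    resname2 = polar$resname[j], atom2 = polar$name[j],
                    distance = dist_ij, class = cls,
                    stringsAsFactors = FALSE)
  if (cross_chain_only) out <- out[out$chain1 != out$chain2, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$distance), , drop = FALSE]
}

#' Distance between two named atoms
#'
#' Atom specifications have the form `"chain:resno:atom"`, e.g.
#' `"A:16:CA"`.
#'
#' @param structure A `structure_model`.
#' @param spec1,spec2 Atom specifications.
#' @return Euclidean distance (Angstrom).
#' @export
atom_distance <- function(structure, spec1, spec2) {
  get1 <- function(spec) {
    p <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(p) != 3L) stop("atom spec must be chain:resno:atom, got ", spec)
    a <- structure$atoms
    hit <- which(a$chain == p[1] & a$resno == as.integer(p[2]) &
                 a$name == p[3])
    if (length(hit) != 1L)
      stop("atom spec ", spec, " resolves to ", length(hit), " atoms")
    as.numeric(a[hit, c("x", "y", "z")])
  }
  sqrt(sum((get1(spec1) - get1(spec2))^2))
}
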