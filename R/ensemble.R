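#' Conformational ensemble bound to one topology
#'
#' An `ensemble` couples a topology (`structure_model`) to an F x 3A
#' coordinate matrix, one row per frame, ordered (x1, y1, z1, x2, ...)
#' as in bio3d.
#'
#' @param topology A `structure_model` describing every frame's atoms.
#' @param xyz Numeric matrix, frames in rows, 3 x n_atoms columns.
#' @param frame_interval Optional time per saved frame (ps); metadata only.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(topology, xyz, frame_interval = NA_real_) {
  if (!inherits(topology, "structure_model")) stop("topology must be a structure_model")
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("xyz has ", ncol(xyz) / 3, " atoms but topology has ",
         nrow(topology$atoms))
  if (nrow(xyz) < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  out <- list(topology = topology, xyz = unname(xyz),
              frame_interval = frame_interval)
  class(out) <- "ensemble"
  out
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", nrow(x$xyz), "frames x", ncol(x$xyz) / 3, "atoms\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Load a conformational ensemble from a trajectory file
#'
#' Reads a multi-model PDB or a CHARMM/NAMD-style DCD trajectory and
#' binds it to a topology. Frames are taken as
#' `first_frame, first_frame + stride, ...` (1-based).
#'
#' @param topology A `structure_model` whose atoms match the trajectory.
#' @param trajectory Path to a multi-model PDB (`.pdb`) or DCD (`.dcd`).
#' @param stride Keep every `stride`-th frame.
#' @param first_frame First frame kept (1-based).
#' @param frame_interval Optional time per saved frame (ps).
#' @return An `ensemble`.
#' @export
load_ensemble <- function(topology, trajectory, stride = 1L, first_frame = 1L,
                          frame_interval = NA_real_) {
  stopifnot(stride >= 1L, first_frame >= 1L)
  if (grepl("\\.dcd$", trajectory, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(trajectory, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("trajectory atom count (", ncol(xyz) / 3,
         ") does not match topology (", nrow(topology$atoms), ")")
  if (first_frame > nrow(xyz)) stop("empty frame selection")
  idx <- seq(from = first_frame, to = nrow(xyz), by = stride)
  ensemble(topology, xyz[idx, , drop = FALSE], frame_interval)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An `ensemble`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_ensemble_pdb <- function(ens, file) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  out <- file(file, "wt")
  on.exit(close(out), add = TRUE)
  top <- ens$topology
  for (f in seq_len(n_frames(ens))) {
    top$atoms[, c("x", "y", "z")] <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    write_pdb(top, tmp)
    lines <- readLines(tmp, warn = FALSE)
    lines <- lines[grepl("^(ATOM|HETATM|TER)", lines)]
    writeLines(sprintf("MODEL %8d", f), out)
    writeLines(lines, out)
    writeLines("ENDMDL", out)
  }
  writeLines("END", out)
  invisible(file)
}

#' Write ensemble coordinates as a DCD trajectory
#'
#' Minimal CHARMM-dialect writer (little-endian, 32-bit float
#' coordinates, no unit cell, no fixed atoms), readable by
#' [bio3d::read.dcd()] and by the usual MD analysis stacks.
#'
#' @param ens An `ensemble`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_dcd <- function(ens, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  xyz <- ens$xyz
  nf <- as.integer(nrow(xyz))
  na <- as.integer(ncol(xyz) / 3L)
  wblock <- function(writer) {
    raw <- writer()
    writeBin(length(raw), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4, endian = "little")
  }
  # header block: "CORD" + 20 control integers (CHARMM version 24)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  wblock(function() c(charToRaw("CORD"),
                      writeBin(icntrl, raw(), size = 4, endian = "little")))
  title <- formatC("Created by dimerlink::write_dcd", width = -80)
  wblock(function() c(writeBin(1L, raw(), size = 4, endian = "little"),
                      charToRaw(title)))
  wblock(function() writeBin(na, con = raw(), size = 4, endian = "little"))
  ix <- seq(1L, 3L * na, by = 3L)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (off in 0:2) {
      v <- fr[ix + off]
      wblock(function() writeBin(v, raw(), size = 4, endian = "little"))
    }
  }
  invisible(file)
}

#' Optimal rigid-body superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' of `mobile %*% R + t` to `fixed` (row-vector convention,
#' mass-unweighted).
#'
#' @param mobile,fixed n x 3 coordinate matrices, rows paired.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  stopifnot(ncol(mobile) == 3L, ncol(fixed) == 3L,
            nrow(mobile) == nrow(fixed), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  if (qr(P)$rank < 2L) stop("degenerate selection: points are collinear")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cf - as.numeric(cm %*% R)
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Align every frame of an ensemble to a reference
#'
#' Rigid-body (Kabsch) superposition of each frame onto the reference
#' over a selection of atoms (default: protein C-alpha atoms,
#' mass-unweighted). The transform computed on the selection is applied
#' to all atoms of the frame.
#'
#' @param ens An `ensemble`.
#' @param reference Either a frame index (1-based) or a numeric vector of
#'   length `3 * n_atoms` giving external reference coordinates.
#' @param selection Integer vector of atom indices used for the fit;
#'   `NULL` selects protein C-alpha atoms.
#' @return The aligned `ensemble`.
#' @export
align_frames <- function(ens, reference = 1L, selection = NULL) {
  if (is.null(selection)) selection <- ca_indices(ens$topology)
  if (!length(selection)) stop("empty alignment selection")
  if (length(selection) < 3L) stop("degenerate selection: need >= 3 atoms")
  ref <- if (length(reference) == 1L) ens$xyz[reference, ] else as.numeric(reference)
  refsel <- matrix(ref, ncol = 3, byrow = TRUE)[selection, , drop = FALSE]
  out <- ens$xyz
  for (f in seq_len(nrow(out))) {
    fr <- matrix(out[f, ], ncol = 3, byrow = TRUE)
    fit <- kabsch_fit(fr[selection, , drop = FALSE], refsel)
    moved <- fr %*% fit$rotation
    moved <- sweep(moved, 2, fit$translation, "+")
    out[f, ] <- as.numeric(t(moved))
  }
  ensemble(ens$topology, out, ens$frame_interval)
}

#' Indices of protein C-alpha atoms in a structure
#' @param structure A `structure_model`.
#' @return Integer atom indices.
#' @export
ca_indices <- function(structure) {
  a <- structure$atoms
  which(a$name == "CA" & !a$het & !a$water & a$element == "C")
}
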