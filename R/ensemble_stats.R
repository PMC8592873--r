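#' Per-residue root mean square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |x_i - <x_i>|^2) for each selected
#' atom, computed on an ensemble already aligned to a common reference
#' (see [align_frames()]).
#'
#' @param ens An aligned `ensemble`.
#' @param selection Atom indices; `NULL` selects protein C-alpha atoms.
#' @param label Source label stored with the profile.
#' @return A data.frame (`flexibility_profile`): chain, resno, value
#'   (Angstrom), source.
#' @export
rmsf <- function(ens, selection = NULL, label = "ensemble") {
  if (n_frames(ens) < 2L) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- ca_indices(ens$topology)
  cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                          3L * (selection - 1L) + 2L, 3L * selection))
  xyz <- ens$xyz[, cols, drop = FALSE]
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  percoord <- colMeans(dev2)
  val <- sqrt(percoord[seq(1, length(percoord), 3)] +
              percoord[seq(2, length(percoord), 3)] +
              percoord[seq(3, length(percoord), 3)])
  a <- ens$topology$atoms[selection, ]
  out <- data.frame(chain = a$chain, resno = a$resno, value = as.numeric(val),
                    source = label, stringsAsFactors = FALSE)
  class(out) <- c("flexibility_profile", class(out))
  out
}

#' Principal component analysis of an ensemble
#'
#' Eigendecomposition of the 3A x 3A covariance matrix of the selected
#' (mass-unweighted) coordinates. The sign of each mode is fixed so its
#' largest-magnitude component is positive.
#'
#' @param ens An aligned `ensemble`.
#' @param selection Atom indices; `NULL` selects protein C-alpha atoms.
#' @param n_modes Number of modes to return.
#' @return A `pca_modes` list: `mean` (3A), `values` (eigenvalues,
#'   Angstrom^2, non-increasing), `vectors` (3A x n_modes, orthonormal),
#'   `explained` (fractions of total variance).
#' @export
pca_modes <- function(ens, selection = NULL, n_modes = 5L) {
  if (is.null(selection)) selection <- ca_indices(ens$topology)
  cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                          3L * (selection - 1L) + 2L, 3L * selection))
  xyz <- ens$xyz[, cols, drop = FALSE]
  if (nrow(xyz) <= ncol(xyz))
    warning("fewer frames than coordinate dimensions; trailing modes are null")
  mu <- colMeans(xyz)
  xc <- sweep(xyz, 2, mu)
  cv <- crossprod(xc) / nrow(xc)
  if (max(abs(cv)) == 0) stop("zero-variance ensemble")
  eg <- eigen(cv, symmetric = TRUE)
  k <- min(n_modes, ncol(cv))
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (m in seq_len(k)) {
    peak <- which.max(abs(vec[, m]))
    if (vec[peak, m] < 0) vec[, m] <- -vec[, m]
  }
  structure(list(mean = mu, values = pmax(eg$values, 0)[seq_len(k)],
                 vectors = vec,
                 explained = pmax(eg$values, 0)[seq_len(k)] / sum(pmax(eg$values, 0)),
                 total_variance = sum(pmax(eg$values, 0))),
            class = "pca_modes")
}

#' Normalized B-factor (B') profile of a chain
#'
#' Turns raw crystallographic C-alpha B-factors into dimensionless
#' z-scores so flexibility can be compared across structures refined
#' under different conditions. `classic_z` uses (B - mean)/sd (sample
#' sd); `robust_mad` uses (B - median)/(1.4826 MAD).
#'
#' @param structure A `structure_model`.
#' @param chain Chain identifier; normalization is per chain.
#' @param method `"robust_mad"` (default) or `"classic_z"`.
#' @return A `flexibility_profile` data.frame: chain, resno, value, source.
#' @export
bprime_zscores <- function(structure, chain,
                           method = c("robust_mad", "classic_z")) {
  method <- match.arg(method)
  sel <- select_atoms(structure, chain = chain, name = "CA",
                      protein_only = TRUE)
  b <- sel$atoms$b
  val <- switch(method,
    classic_z = {
      s <- stats::sd(b)
      if (!is.finite(s) || s == 0) stop("zero spread in B-factors")
      (b - mean(b)) / s
    },
    robust_mad = {
      s <- stats::mad(b)  # includes the 1.4826 consistency constant
      if (!is.finite(s) || s == 0) stop("zero spread in B-factors")
      (b - stats::median(b)) / s
    })
  out <- data.frame(chain = sel$atoms$chain, resno = sel$atoms$resno,
                    value = val,
                    source = paste0(structure$id, ":", chain),
                    stringsAsFactors = FALSE)
  class(out) <- c("flexibility_profile", class(out))
  out
}

#' Compare two flexibility profiles over shared residues
#'
#' @param profile_a,profile_b `flexibility_profile` data.frames (e.g.
#'   from [bprime_zscores()] or [rmsf()]).
#' @param region Optional residue-number vector summarised separately
#'   (e.g. `10:15` for a loop).
#' @return List with `delta` (data.frame: resno, value_a, value_b,
#'   delta = b - a) and `region_mean` (signed mean delta over `region`,
#'   `NA` if no region given).
#' @export
compare_bprime <- function(profile_a, profile_b, region = NULL) {
  m <- merge(profile_a[, c("resno", "value")], profile_b[, c("resno", "value")],
             by = "resno", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("profiles share no residues")
  m$delta <- m$value_b - m$value_a
  region_mean <- NA_real_
  if (!is.null(region)) {
    sel <- m$resno %in% region
    if (!any(sel)) stop("region not present in shared residues")
    region_mean <- mean(m$delta[sel])
  }
  list(delta = m[order(m$resno), ], region_mean = region_mean)
}

#' Write a flexibility profile as TSV
#' @param profile A `flexibility_profile`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(profile, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
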