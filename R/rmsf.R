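#' Per-atom root mean square fluctuation of a trajectory
#'
#' Frames are first least-squares superposed onto the reference coordinates
#' using the protein backbone atoms (names N, CA, C); when fewer than three
#' backbone atoms exist (e.g. a ligand-only trajectory) frames are used as
#' stored. The fluctuation of atom i is
#' `RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2)` in Angstrom.
#'
#' Atoms with RMSF above the search cutoff (0.1 A by default over a 2 ns
#' trajectory sampled every 4 ps) are excluded from restraint-anchor
#' candidacy downstream.
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param selection Optional integer vector of atom indices to report
#'   (default: all atoms).
#' @return Named numeric vector of RMSF values (Angstrom), names are atom
#'   indices.
#' @export
compute_rmsf <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2) {
    stop("RMSF is undefined for a single frame; provide >= 2 frames")
  }
  at <- traj$system$atoms
  ref <- coords(traj$system)
  bb <- which(at$name %in% c("N", "CA", "C"))
  frames <- traj$frames
  if (length(bb) >= 3) {
    frames <- lapply(frames, function(f) {
      fit <- .kabsch(ref[bb, , drop = FALSE], f[bb, , drop = FALSE])
      .apply_fit(f, fit)
    })
  }
  arr <- simplify2array(frames) # n_atoms x 3 x n_frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  msf <- apply(dev2, 1, function(m) mean(colSums(m)))
  out <- sqrt(msf)
  names(out) <- at$index
  if (!is.null(selection)) out <- out[as.character(selection)]
  out
}
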