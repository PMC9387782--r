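# Rigid-body least-squares superposition and fluctuation profiles.

#' Optimal rigid-body (Kabsch) superposition of one frame onto a reference
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of the
#' selected atoms of `mobile` to those of `reference`, then applies the
#' transform x' = R x + t to *all* atoms of the mobile frame. The fit is
#' unweighted. Reflections are excluded: the determinant-positive branch of
#' the SVD solution is always taken.
#'
#' @param mobile n_atoms x 3 coordinate matrix (A)
#' @param reference n_atoms-compatible coordinate matrix; only the selected
#'   rows are used
#' @param sel `selection` (or integer indices) of the atoms to fit on;
#'   at least 3 non-collinear atoms
#' @return list with `rotation` (3x3, det +1), `translation` (length 3, A),
#'   `rmsd` (post-fit selected-atom RMSD, A) and `coords` (the transformed
#'   full frame)
#' @export
kabsch_fit <- function(mobile, reference, sel = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  sel <- as.integer(sel)
  if (length(sel) < 3) validation_error("degenerate fit: need at least 3 selected atoms")
  if (max(sel) > nrow(mobile) || max(sel) > nrow(reference)) {
    validation_error("selection exceeds frame size")
  }
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cm <- colMeans(P)
  cr <- colMeans(Q)
  Pc <- sweep(P, 2, cm)
  Qc <- sweep(Q, 2, cr)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-10 * max(sv_p[1], 1)) {
    validation_error("degenerate fit: selected atoms are collinear")
  }
  H <- crossprod(Pc, Qc) # t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted[sel, , drop = FALSE] - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, coords = fitted)
}

resolve_reference <- function(traj, reference) {
  if (is.matrix(reference)) return(reference)
  frame_coords(traj, reference)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj trajectory
#' @param sel selection to fit on (default all atoms)
#' @param reference reference coordinates: a frame index into `traj`
#'   (default 1, the window-start convention) or an explicit matrix
#' @return fitted trajectory; per-frame post-fit RMSD over the fit selection
#'   is stored in `$fit_rmsd`, and `$fitted` is set to `TRUE`
#' @export
fit_trajectory <- function(traj, sel = seq_len(n_atoms(traj)), reference = 1) {
  ref <- resolve_reference(traj, reference)
  coords <- traj$coords
  rmsd <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fit <- kabsch_fit(frame_coords(traj, f), ref, sel)
    coords[f, , ] <- fit$coords
    rmsd[f] <- fit$rmsd
  }
  out <- new_trajectory(traj$topology, coords, box = traj$box, times = traj$times)
  out$fitted <- TRUE
  out$fit_rmsd <- rmsd
  out
}

#' Per-frame RMSD after superposition
#'
#' Each frame is rigid-body fitted to the reference over `sel`; the reported
#' value is the post-fit RMSD over the same selection.
#'
#' @inheritParams fit_trajectory
#' @return numeric vector, one RMSD (A) per frame
#' @export
rmsd_series <- function(traj, sel = seq_len(n_atoms(traj)), reference = 1) {
  fit_trajectory(traj, sel, reference)$fit_rmsd
}

#' Root-mean-square fluctuation profile
#'
#' RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2) over the selected atoms of an
#' already-fitted trajectory. Rigid-body motion must have been removed first
#' (see [fit_trajectory()]); pass `assume_fitted = TRUE` to override the
#' check for ensembles generated without rigid contamination.
#'
#' @param traj fitted trajectory with at least 2 frames
#' @param sel selection (default all atoms)
#' @param group_by_residue average atomic RMSF within each residue
#' @param assume_fitted skip the fitted-input check
#' @return data.frame with atom (or residue) identifiers and `rmsf` (A)
#' @export
rmsf_profile <- function(traj, sel = seq_len(n_atoms(traj)),
                         group_by_residue = FALSE, assume_fitted = FALSE) {
  if (n_frames(traj) < 2) {
    validation_error("fluctuations undefined for a single frame")
  }
  if (!isTRUE(traj$fitted) && !assume_fitted) {
    validation_error(
      "trajectory not marked as fitted; run fit_trajectory() first ",
      "or pass assume_fitted = TRUE"
    )
  }
  sel <- as.integer(sel)
  sub <- traj$coords[, sel, , drop = FALSE]
  mean_xyz <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mean_xyz)^2
  msf <- apply(dev2, 2, mean) * 3 # mean over frames and xyz, times 3 dims
  rmsf <- sqrt(msf)
  atoms <- traj$topology$atoms[sel, ]
  out <- data.frame(
    serial = atoms$serial, name = atoms$name, resname = atoms$resname,
    resid = atoms$resid, chain = atoms$chain, rmsf = rmsf,
    stringsAsFactors = FALSE
  )
  if (group_by_residue) {
    agg <- stats::aggregate(rmsf ~ chain + resid + resname, data = out, FUN = mean)
    out <- agg[order(agg$chain, agg$resid), c("chain", "resid", "resname", "rmsf")]
    rownames(out) <- NULL
  }
  out
}
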