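# Essential dynamics: covariance of positional fluctuations, its eigenmodes,
# projections of trajectories onto principal components, and the Boltzmann
# free-energy landscape over two components.

#' Resolve a fractional window into frame indices
#'
#' @param traj trajectory
#' @param window `NULL` for all frames, a numeric pair of trajectory
#'   fractions (e.g. `c(0.8, 1)` for the final 20 percent), or an integer
#'   vector of frame indices
#' @return integer frame indices
#' @export
window_frames <- function(traj, window = NULL) {
  nf <- n_frames(traj)
  if (is.null(window)) return(seq_len(nf))
  if (length(window) == 2 && all(window >= 0) && all(window <= 1) &&
      !is.integer(window)) {
    from <- max(1L, floor(window[1] * nf) + 1L)
    to <- max(from, round(window[2] * nf))
    return(seq.int(from, to))
  }
  idx <- as.integer(window)
  stopifnot(all(idx >= 1), all(idx <= nf))
  idx
}

flatten_coords <- function(traj, sel, frames) {
  # n_frames x 3K matrix, coordinates stacked (x1,y1,z1,x2,...)
  sub <- traj$coords[frames, sel, , drop = FALSE]
  nf <- length(frames)
  k <- length(sel)
  X <- matrix(NA_real_, nf, 3 * k)
  for (a in seq_len(k)) X[, (3 * a - 2):(3 * a)] <- sub[, a, ]
  X
}

#' Covariance model of atomic fluctuations
#'
#' Builds the 3K x 3K covariance of the selected Cartesian coordinates over
#' a frame window and diagonalizes it. Rigid-body motion is removed by an
#' internal least-squares fit of every window frame to the window's first
#' frame over the same selection (disable with `fit = FALSE` for ensembles
#' generated without rigid contamination). The biased 1/n normalizer is the
#' default, matching the ensemble second moment that the entropy formulas
#' assume.
#'
#' @param traj trajectory
#' @param sel `selection` of atoms entering the covariance
#' @param mass_weighted if `TRUE`, the covariance is M^(1/2) C M^(1/2) with
#'   per-coordinate square-root masses (units amu A^2); required by the
#'   quantum quasi-harmonic entropy estimators
#' @param window frame window (see [window_frames()])
#' @param fit remove rigid-body motion before accumulating (default `TRUE`)
#' @param unbiased use the 1/(n-1) normalizer instead of 1/n
#' @return `covariance_model`: list with `selection`, `mean_coords` (3K, A),
#'   `covariance`, `mass_weighted`, `masses` (per coordinate, amu),
#'   `eigenvalues` (descending), `eigenvectors` (orthonormal columns),
#'   `n_frames_used`
#' @export
covariance_model <- function(traj, sel = seq_len(n_atoms(traj)),
                             mass_weighted = FALSE, window = NULL,
                             fit = TRUE, unbiased = FALSE) {
  frames <- window_frames(traj, window)
  if (length(frames) < 2) validation_error("covariance needs at least 2 frames")
  sel <- as.integer(sel)
  if (fit) {
    sub <- new_trajectory(traj$topology, traj$coords[frames, , , drop = FALSE])
    sub <- fit_trajectory(sub, sel, reference = 1)
    X <- flatten_coords(sub, sel, seq_along(frames))
  } else {
    X <- flatten_coords(traj, sel, frames)
  }
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / if (unbiased) (n - 1) else n
  masses <- rep(traj$topology$atoms$mass[sel], each = 3)
  if (mass_weighted) {
    if (any(!is.finite(masses)) || any(masses <= 0)) {
      validation_error("mass weighting requires positive atomic masses")
    }
    sm <- sqrt(masses)
    C <- C * tcrossprod(sm) # M^(1/2) C M^(1/2)
  }
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  structure(
    list(
      selection = sel, mean_coords = mu, covariance = C,
      mass_weighted = mass_weighted, masses = masses,
      eigenvalues = eig$values, eigenvectors = eig$vectors,
      n_frames_used = n
    ),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("covariance model: ", length(x$mean_coords), " coordinates, ",
      x$n_frames_used, " frames",
      if (x$mass_weighted) " (mass-weighted)", "\n",
      "leading eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Project a trajectory onto principal modes
#'
#' value\[f, c\] = v_c . W (x_f - mean), with W the square-root mass weighting
#' when the model is mass-weighted and the identity otherwise. Projections
#' of the frames the model was built from have sample variance equal to the
#' corresponding eigenvalue.
#'
#' @param traj trajectory sharing the model's selection dimensionality
#' @param model `covariance_model`
#' @param components eigenvector indices (default `c(1, 2)`)
#' @param window frame window
#' @param fit superpose frames to the model's mean before projecting
#' @return matrix `n_frames x n_components` (A, or A amu^1/2 mass-weighted)
#' @export
project_trajectory <- function(traj, model, components = c(1, 2),
                               window = NULL, fit = TRUE) {
  stopifnot(inherits(model, "covariance_model"))
  d <- length(model$mean_coords)
  if (any(components < 1) || any(components > d)) {
    validation_error("component index out of range 1..", d)
  }
  frames <- window_frames(traj, window)
  sel <- model$selection
  if (fit) {
    ref <- matrix(model$mean_coords, ncol = 3, byrow = TRUE)
    refframe <- frame_coords(traj, frames[1])
    refframe[sel, ] <- ref
    sub <- new_trajectory(traj$topology, traj$coords[frames, , , drop = FALSE])
    sub <- fit_trajectory(sub, sel, reference = refframe)
    X <- flatten_coords(sub, sel, seq_along(frames))
  } else {
    X <- flatten_coords(traj, sel, frames)
  }
  Xc <- sweep(X, 2, model$mean_coords)
  if (model$mass_weighted) Xc <- sweep(Xc, 2, sqrt(model$masses), `*`)
  vals <- Xc %*% model$eigenvectors[, components, drop = FALSE]
  colnames(vals) <- paste0("PC", components)
  vals
}

#' Free-energy landscape over two principal components
#'
#' Boltzmann inversion of the 2-D histogram of projections:
#' G(bin) = -k_B T ln(P(bin) / P_max), so the most occupied bin has G = 0
#' and unoccupied bins are +Inf.
#'
#' @param proj n x 2 projection matrix (see [project_trajectory()])
#' @param temperature kelvin
#' @param n_bins bins per axis (>= 2)
#' @return list with `axes` (bin-edge vectors), `probability` (sums to 1)
#'   and `free_energy` (kcal/mol)
#' @export
free_energy_landscape <- function(proj, temperature = 300, n_bins = 32) {
  proj <- as.matrix(proj)
  if (ncol(proj) != 2) validation_error("landscape needs exactly 2 components")
  if (nrow(proj) == 0) validation_error("no frames to histogram")
  stopifnot(n_bins >= 2)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) * c(-1e-9, 1e-9)
  xe <- seq(pad(range(proj[, 1]))[1], pad(range(proj[, 1]))[2], length.out = n_bins + 1)
  ye <- seq(pad(range(proj[, 2]))[1], pad(range(proj[, 2]))[2], length.out = n_bins + 1)
  ix <- pmin(pmax(findInterval(proj[, 1], xe, rightmost.closed = TRUE), 1), n_bins)
  iy <- pmin(pmax(findInterval(proj[, 2], ye, rightmost.closed = TRUE), 1), n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (i in seq_len(nrow(proj))) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  P <- counts / sum(counts)
  G <- matrix(Inf, n_bins, n_bins)
  occ <- P > 0
  G[occ] <- -KB_KCAL * temperature * log(P[occ] / max(P))
  list(axes = list(x = xe, y = ye), probability = P, free_energy = G)
}
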