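# Radial distribution functions, running coordination numbers, distance
# time series and geometric hydrogen-bond detection.

min_image_dist <- function(d, box) {
  # d: n x 3 displacement matrix
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d^2))
}

#' Radial distribution function around a single center
#'
#' Histogram of center-partner distances (minimum-image when a box is
#' present) normalized by exact spherical-shell volumes, the partner number
#' density and the frame count, so an ideal gas gives g(r) = 1.
#'
#' @param traj trajectory
#' @param center_sel `selection` with exactly one atom
#' @param partner_sel `selection` of partner atoms (must exclude the center)
#' @param bin_width histogram bin width, A (default 0.02, aligning the
#'   2.7 A first-shell cutoff with a bin edge)
#' @param r_max histogram range, A; at most half the smallest box length
#'   when periodic
#' @param reference_volume partner-phase volume (A^3) when the ensemble has
#'   no box; the number density is otherwise taken from the box volume
#' @return `rdf_profile`: list with `r_centers`, `g_of_r`, `rho` (A^-3),
#'   `bin_width`, `n_frames`
#' @export
rdf <- function(traj, center_sel, partner_sel, bin_width = 0.02, r_max = 6,
                reference_volume = NULL) {
  center <- as.integer(center_sel)
  partners <- as.integer(partner_sel)
  if (length(center) != 1) validation_error("center selection must contain exactly 1 atom")
  if (center %in% partners) validation_error("partner selection must exclude the center")
  if (!is.null(traj$box)) {
    if (r_max > min(traj$box) / 2) {
      validation_error("r_max ", r_max, " exceeds half the smallest box length")
    }
    volume <- prod(traj$box)
  } else {
    if (is.null(reference_volume)) {
      validation_error("non-periodic ensemble: supply reference_volume for the density")
    }
    volume <- reference_volume
  }
  rho <- length(partners) / volume
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    d <- min_image_dist(sweep(fr[partners, , drop = FALSE], 2, fr[center, ]), traj$box)
    d <- d[d < r_max]
    if (length(d) > 0) {
      bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), nb)
      tab <- tabulate(bin, nbins = nb)
      counts <- counts + tab
    }
  }
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * shell_vol * rho)
  structure(
    list(r_centers = (edges[-1] + edges[-length(edges)]) / 2, g_of_r = g,
         rho = rho, bin_width = bin_width, n_frames = nf),
    class = "rdf_profile"
  )
}

#' Running coordination number from an RDF profile
#'
#' n = integral over \[R1, R2\] of 4 pi r^2 rho g(r) dr by trapezoidal
#' quadrature on the profile's bin centers (with linear interpolation at the
#' interval endpoints). The default shell is \[0, 2.7 A\], the first-shell
#' cutoff for the catalytic zinc.
#'
#' @param profile `rdf_profile`
#' @param R1,R2 shell bounds, A (R2 > R1 >= 0)
#' @return `coordination_result`: list with `n`, `R1`, `R2`
#' @export
coordination_number <- function(profile, R1 = 0, R2 = 2.7) {
  stopifnot(inherits(profile, "rdf_profile"))
  if (R2 < R1 || R1 < 0) validation_error("shell bounds must satisfy R2 >= R1 >= 0")
  if (R2 > max(profile$r_centers) + profile$bin_width / 2) {
    validation_error("R2 beyond the profile range")
  }
  if (R2 == R1) {
    return(structure(list(n = 0, R1 = R1, R2 = R2), class = "coordination_result"))
  }
  r <- profile$r_centers
  f <- 4 * pi * r^2 * profile$rho * profile$g_of_r
  interp <- function(x) {
    if (x <= r[1]) return(f[1] * x / r[1]) # f -> 0 as r -> 0
    if (x >= r[length(r)]) return(f[length(f)])
    stats::approx(r, f, xout = x)$y
  }
  inside <- which(r > R1 & r < R2)
  xs <- c(R1, r[inside], R2)
  ys <- c(interp(R1), f[inside], interp(R2))
  n <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(list(n = n, R1 = R1, R2 = R2), class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination number n = %.3f over [%.2f, %.2f] A\n", x$n, x$R1, x$R2))
  invisible(x)
}

#' Mean partner count within a cutoff (counting oracle for the RDF integral)
#'
#' @param traj trajectory
#' @param center_sel one-atom `selection`
#' @param partner_sel partner `selection`
#' @param cutoff shell radius, A
#' @return mean per-frame count of partners within `cutoff` of the center
#' @export
count_within <- function(traj, center_sel, partner_sel, cutoff) {
  center <- as.integer(center_sel)
  partners <- as.integer(partner_sel)
  stopifnot(length(center) == 1)
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    d <- min_image_dist(sweep(fr[partners, , drop = FALSE], 2, fr[center, ]), traj$box)
    sum(d <= cutoff)
  }, numeric(1))
  mean(counts)
}

#' Distance time series between two atoms
#'
#' @param traj trajectory
#' @param atom_a,atom_b distinct atom indices
#' @return list with `values` (per-frame A, minimum-image when periodic),
#'   `mean`, `sd`
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  a <- as.integer(atom_a)
  b <- as.integer(atom_b)
  if (a == b) validation_error("atoms must be distinct")
  stopifnot(a >= 1, b >= 1, a <= n_atoms(traj), b <= n_atoms(traj))
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    min_image_dist(matrix(fr[b, ] - fr[a, ], 1, 3), traj$box)
  }, numeric(1))
  list(values = vals, mean = mean(vals), sd = stats::sd(vals))
}

#' Geometric hydrogen-bond detection
#'
#' A donor-acceptor pair counts as hydrogen bonded in a frame when the
#' donor-acceptor distance is at most `d_cut` and the hydrogen-donor-acceptor
#' angle is at most `angle_cut` (the 3.5 A / 30 degree convention).
#' Hydrogens are resolved per donor by proximity (< 1.2 A in the first
#' frame); donors without a resolvable hydrogen are skipped with a warning.
#'
#' @param traj trajectory
#' @param donors `selection` of donor heavy atoms
#' @param acceptors `selection` of acceptor heavy atoms
#' @param d_cut donor-acceptor distance cutoff, A
#' @param angle_cut H-D-A angle cutoff, degrees
#' @return data.frame of detected bonds: donor, hydrogen, acceptor (atom
#'   indices), `mean_distance` (A), `mean_angle` (deg), `occupancy` in
#'   \[0, 1\]; bonds never satisfied are omitted
#' @export
hbond_detect <- function(traj, donors, acceptors, d_cut = 3.5, angle_cut = 30) {
  dn <- as.integer(donors)
  ac <- as.integer(acceptors)
  atoms <- traj$topology$atoms
  hyd_all <- which(atoms$element == "H")
  fr1 <- frame_coords(traj, 1)
  rows <- list()
  for (d in dn) {
    if (length(hyd_all) == 0) {
      warning("donor serial ", atoms$serial[d], " has no resolvable hydrogen; skipped")
      next
    }
    dist_h <- sqrt(rowSums(sweep(fr1[hyd_all, , drop = FALSE], 2, fr1[d, ])^2))
    hs <- hyd_all[dist_h < 1.2]
    if (length(hs) == 0) {
      warning("donor serial ", atoms$serial[d], " has no resolvable hydrogen; skipped")
      next
    }
    for (h in hs) {
      for (a in setdiff(ac, d)) {
        dd <- numeric(0)
        ang <- numeric(0)
        hit <- 0
        for (f in seq_len(n_frames(traj))) {
          fr <- frame_coords(traj, f)
          rda <- sqrt(sum((fr[a, ] - fr[d, ])^2))
          v1 <- fr[h, ] - fr[d, ]
          v2 <- fr[a, ] - fr[d, ]
          ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
          theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
          if (rda <= d_cut && theta <= angle_cut) {
            hit <- hit + 1
            dd <- c(dd, rda)
            ang <- c(ang, theta)
          }
        }
        if (hit > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a,
            mean_distance = mean(dd), mean_angle = mean(ang),
            occupancy = hit / n_frames(traj)
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), mean_distance = numeric(0),
                      mean_angle = numeric(0), occupancy = numeric(0)))
  }
  do.call(rbind, rows)
}
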