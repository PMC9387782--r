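rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

test_that("a pure rigid motion is recovered exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  mob <- ref %*% t(rotation_z(37)) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  fit <- kabsch_fit(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_lt(max(abs(fit$coords - ref)), 1e-8)
  # proper orthonormal rotation
  expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("fitting a frame onto itself is the identity", {
  set.seed(2)
  ref <- matrix(rnorm(15, sd = 3), 5, 3)
  fit <- kabsch_fit(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(fit$translation)), 1e-10)
})

test_that("mirror images stay mirror images: only proper rotations are used", {
  set.seed(3)
  ref <- matrix(rnorm(24, sd = 3), 8, 3)
  mirrored <- ref
  mirrored[, 1] <- -mirrored[, 1]
  fit <- kabsch_fit(mirrored, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)
  # brute force over the two determinant branches: the unconstrained optimum
  # V U^T is improper here and fits exactly, confirming the implementation
  # deliberately rejected it for the best det = +1 rotation
  Pc <- sweep(mirrored, 2, colMeans(mirrored))
  Qc <- sweep(ref, 2, colMeans(ref))
  sv <- svd(crossprod(Pc, Qc))
  R_free <- sv$v %*% t(sv$u)
  expect_equal(det(R_free), -1, tolerance = 1e-10)
  rmsd_free <- sqrt(mean(rowSums((Pc %*% t(R_free) - Qc)^2)))
  expect_lt(rmsd_free, 1e-8) # the rejected improper branch is the mirror fit
})

test_that("degenerate selections are refused", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(kabsch_fit(ref, ref, sel = 1:2), "at least 3")
  expect_error(kabsch_fit(ref, ref), "collinear")
})

test_that("rigid-contaminated copies of one frame give zero RMSD series", {
  base <- gen_gaussian_ensemble(c(0, 0, 0, 5, 0, 0, 2, 4, 0), diag(1e-30, 9),
                                n_frames = 10, seed = 1)
  dirty <- gen_rigid_contaminated(base, 180, 8, seed = 2)
  expect_lt(max(rmsd_series(dirty)), 1e-8)
})

test_that("mean RMSD of an isotropic Gaussian cloud approaches sigma*sqrt(3)", {
  k <- 60
  set.seed(10)
  mean_xyz <- as.numeric(t(matrix(rnorm(3 * k, sd = 10), k, 3)))
  sigma <- 0.2
  tr <- gen_gaussian_ensemble(mean_xyz, diag(sigma^2, 3 * k), n_frames = 2000, seed = 20)
  ref <- matrix(mean_xyz, k, 3, byrow = TRUE)
  series <- rmsd_series(tr, reference = ref)
  # oracle: direct Monte-Carlo expectation of the RMS of iid displacements;
  # fitting absorbs 6 of the 3k dofs, hence the modest tolerance
  expect_equal(mean(series), sigma * sqrt(3), tolerance = 0.05)
})

test_that("post-fit RMSD never exceeds pre-fit RMSD", {
  tr <- gen_gaussian_ensemble(c(0, 0, 0, 5, 0, 0, 2, 4, 0, 2, 2, 4),
                              diag(0.05, 12), n_frames = 50, seed = 30)
  dirty <- gen_rigid_contaminated(tr, 30, 2, seed = 31)
  ref <- frame_coords(dirty, 1)
  post <- rmsd_series(dirty, reference = 1)
  pre <- vapply(seq_len(n_frames(dirty)), function(f) {
    sqrt(mean(rowSums((frame_coords(dirty, f) - ref)^2)))
  }, numeric(1))
  expect_true(all(post <= pre + 1e-12))
})

test_that("fitting is idempotent", {
  tr <- gen_gaussian_ensemble(c(0, 0, 0, 5, 0, 0, 2, 4, 0, 2, 2, 4),
                              diag(0.05, 12), n_frames = 30, seed = 40)
  dirty <- gen_rigid_contaminated(tr, 180, 5, seed = 41)
  once <- fit_trajectory(dirty)
  twice <- fit_trajectory(once)
  expect_lt(max(abs(once$coords - twice$coords)), 1e-10)
})

test_that("RMSF recovers isotropic fluctuation amplitudes and their ratios", {
  k <- 3
  mean_xyz <- c(0, 0, 0, 8, 0, 0, 4, 7, 0)
  sigma <- 0.3
  tr <- gen_gaussian_ensemble(mean_xyz, diag(sigma^2, 3 * k), n_frames = 50000, seed = 50)
  prof <- rmsf_profile(tr, assume_fitted = TRUE)
  expect_equal(prof$rmsf, rep(sigma * sqrt(3), k), tolerance = 0.02)

  # variance ratio 4:1 between two atoms gives RMSF ratio 2:1
  cov2 <- diag(c(rep(0.04, 3), rep(0.01, 3)))
  tr2 <- gen_gaussian_ensemble(c(0, 0, 0, 10, 0, 0), cov2, n_frames = 50000, seed = 51)
  prof2 <- rmsf_profile(tr2, assume_fitted = TRUE)
  expect_equal(prof2$rmsf[1] / prof2$rmsf[2], 2, tolerance = 0.03)
})

test_that("RMSF edge cases: identical frames, single frame, unfitted input", {
  topo <- toy_protein_topology()
  coords <- array(rep(matrix(rnorm(18), 6, 3), each = 5), dim = c(5, 6, 3))
  tr <- new_trajectory(topo, coords)
  expect_equal(rmsf_profile(tr, assume_fitted = TRUE)$rmsf, rep(0, 6))
  one <- new_trajectory(topo, coords[1, , , drop = FALSE])
  expect_error(rmsf_profile(one, assume_fitted = TRUE), "single frame")
  expect_error(rmsf_profile(tr), "not marked as fitted")
})

test_that("RMSF is invariant under a uniform global rigid motion", {
  tr <- gen_gaussian_ensemble(c(0, 0, 0, 5, 0, 0, 2, 4, 0), diag(0.04, 9),
                              n_frames = 500, seed = 60)
  R <- rotation_z(25)
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$coords[f, , ] <- frame_coords(tr, f) %*% t(R) +
      matrix(c(3, 1, -2), 3, 3, byrow = TRUE)
  }
  a <- rmsf_profile(tr, assume_fitted = TRUE)$rmsf
  b <- rmsf_profile(moved, assume_fitted = TRUE)$rmsf
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("kabsch fit agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(70)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.4), 10, 3)
  ours <- kabsch_fit(mob, ref)
  theirs <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(mob))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(theirs, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(ours$rmsd, rmsd_bio3d, tolerance = 1e-6)
})
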