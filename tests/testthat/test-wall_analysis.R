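test_that("ring averages are area-weighted means of the magnitude", {
  mesh <- two_face_mesh()
  tt <- c(0, 0.1, 0.2)
  vecs <- array(0, c(3L, 2L, 3L))
  vecs[, , 1L] <- 2  # uniform magnitude-2 field along x
  fld <- spacetime_field(mesh, tt, vecs)
  ra <- ring_average_magnitude(fld, "both")
  expect_equal(ra$values, rep(2, 3L))
  # equal areas at 1 Pa and 3 Pa average to 2 Pa
  vecs[, 1L, 1L] <- 1; vecs[, 2L, 1L] <- 3
  expect_equal(ring_average_magnitude(spacetime_field(mesh, tt, vecs),
                                      "both")$values, rep(2, 3L))
  expect_error(ring_average_magnitude(fld, "nope"), "unknown ring")
  # seeded random field against the brute-force weighted sum
  cfg <- small_cfg(seed = 21L)
  m2 <- gen_cylinder_mesh(cfg)
  f2 <- gen_wss_field(m2, cfg)
  idx <- m2$rings$ring25
  w <- m2$face_area[idx]
  mag <- sqrt(f2$vectors[, idx, 1L]^2 + f2$vectors[, idx, 2L]^2 +
                f2$vectors[, idx, 3L]^2)
  brute <- as.numeric(mag %*% w) / sum(w)
  expect_equal(ring_average_magnitude(f2, "ring25")$values, brute,
               tolerance = 1e-12)
})

test_that("compute_psd localizes tones, kills constants and satisfies Parseval", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 25 * tt)
  psd <- compute_psd(sampled_waveform(tt, x))
  expect_equal(psd$frequencies[which.max(psd$power)], 25)
  flat <- compute_psd(sampled_waveform(tt, rep(3.3, length(tt))))
  expect_true(all(flat$power < 1e-20))
  # Parseval with taper correction: integrated PSD ~ sample variance
  set.seed(99)
  xn <- rnorm(2048L)
  pn <- compute_psd(sampled_waveform(seq_along(xn) * 1e-3, xn))
  df <- pn$frequencies[2L] - pn$frequencies[1L]
  expect_equal(sum(pn$power) * df, var(xn), tolerance = 0.05)
  # magnitude symmetry under time reversal
  pr <- compute_psd(sampled_waveform(seq_along(xn) * 1e-3, rev(xn)))
  expect_equal(pr$power, pn$power, tolerance = 1e-10)
  expect_error(compute_psd(sampled_waveform((1:5) / 10, rnorm(5L))), "8 samples")
  # windowed extraction respects the window label and resolution
  wf <- sampled_waveform(1 + tt, x)
  pw <- compute_psd(wf, analysis_window("WS"))
  expect_identical(pw$window_label, "WS")
  expect_equal(pw$frequencies[1L], 1 / 0.3, tolerance = 0.02)
})

test_that("snapshot POD resolves rank, symmetry and the SVD oracle", {
  cfg <- small_cfg(seed = 31L, rank = 1L)
  mesh <- gen_cylinder_mesh(cfg)
  # rank-1: one fixed pattern times a sinusoid
  f1 <- gen_wss_field(mesh, cfg)
  p1 <- snapshot_pod(f1)
  expect_equal(sum(p1$eigenvalues > 0), 1L)
  expect_equal(p1$energy_fraction[1L], 1)
  # k equal-energy orthogonal patterns: equal eigenvalues of 1/k each
  cfgk <- small_cfg(seed = 32L, rank = 4L)
  fk <- gen_wss_field(mesh, cfgk, amplitudes = rep(2, 4L))
  pk <- snapshot_pod(fk)
  expect_equal(sum(pk$eigenvalues > 0), 4L)
  expect_equal(pk$eigenvalues[1:4] / sum(pk$eigenvalues), rep(0.25, 4L),
               tolerance = 1e-10)
})

test_that("POD eigenvalues equal the weighted SVD of the centred snapshots", {
  cfg <- small_cfg(seed = 33L)
  mesh <- gen_cylinder_mesh(cfg)
  set.seed(77)
  nt <- 40L; nf <- nrow(mesh$faces)
  vecs <- array(rnorm(nt * nf * 3L), c(nt, nf, 3L))
  fld <- spacetime_field(mesh, seq_len(nt) * 0.01, vecs)
  pod <- snapshot_pod(fld, region = "artery")
  # independent oracle: full SVD of the area-weighted, mean-centred matrix
  idx <- which(mesh$region == "artery")
  X <- cbind(matrix(vecs[, idx, 1L], nt), matrix(vecs[, idx, 2L], nt),
             matrix(vecs[, idx, 3L], nt))
  Xc <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Xc, 2L, sqrt(rep(mesh$face_area[idx], 3L)), `*`)
  lam_oracle <- svd(Y, nu = 0, nv = 0)$d^2
  nz <- lam_oracle > 1e-12 * lam_oracle[1L]
  expect_equal(pod$eigenvalues[nz], lam_oracle[nz], tolerance = 1e-8)
  # energy conservation against the weighted total variance
  expect_equal(sum(pod$eigenvalues), sum(Y^2), tolerance = 1e-10)
  # full reconstruction reproduces the fluctuation field
  rec <- pod_reconstruct(pod)
  fluct <- array(Xc, c(nt, length(idx), 3L))
  expect_lt(max(abs(rec - fluct)) / max(abs(fluct)), 1e-8)
  # orthonormality of spatial modes under the area-weighted inner product
  w <- rep(mesh$face_area[idx], 3L)
  V <- matrix(pod$spatial_modes, ncol = dim(pod$spatial_modes)[3L])
  G <- crossprod(V * sqrt(w))
  expect_equal(G, diag(ncol(V)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("POD is invariant to face reordering and rigid rotation", {
  cfg <- small_cfg(seed = 34L, rank = 3L)
  mesh <- gen_cylinder_mesh(cfg)
  fld <- gen_wss_field(mesh, cfg)
  base <- snapshot_pod(fld)$eigenvalues
  # reorder faces (and the field columns consistently)
  set.seed(5)
  perm <- sample.int(nrow(mesh$faces))
  mesh2 <- surface_mesh(mesh$vertices, mesh$faces[perm, ], mesh$region[perm])
  fld2 <- spacetime_field(mesh2, fld$times,
                          fld$vectors[, perm, , drop = FALSE])
  expect_equal(snapshot_pod(fld2)$eigenvalues, base, tolerance = 1e-10)
  # rotate all vectors by a fixed rotation
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  nt <- length(fld$times); nf <- nrow(mesh$faces)
  flat <- matrix(fld$vectors, nt * nf, 3L)
  rot <- array(flat %*% t(Rm), c(nt, nf, 3L))
  expect_equal(snapshot_pod(spacetime_field(mesh, fld$times, rot))$eigenvalues,
               base, tolerance = 1e-9)
})

test_that("modes_for_energy counts cumulative energies correctly", {
  cfg <- small_cfg(seed = 35L, rank = 1L)
  mesh <- gen_cylinder_mesh(cfg)
  pod1 <- snapshot_pod(gen_wss_field(mesh, cfg))
  expect_identical(modes_for_energy(pod1, 0.96), 1L)
  # 10 equal eigenvalues: 9 modes reach only 90%, so 0.96 needs 10
  cfg10 <- small_cfg(seed = 36L, rank = 10L)
  pod10 <- snapshot_pod(gen_wss_field(mesh, cfg10,
                                      amplitudes = rep(1, 10L)))
  expect_identical(modes_for_energy(pod10, 0.96), 10L)
  expect_identical(modes_for_energy(pod10, 1), 10L)
  # nonincreasing in threshold leniency, bounded by snapshots
  ths <- c(0.2, 0.5, 0.9, 0.99, 1)
  counts <- vapply(ths, function(th) modes_for_energy(pod10, th), integer(1L))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= pod10$snapshot_count))
  # zero-variance field is flagged
  vz <- array(1, c(3L, nrow(mesh$faces), 3L))
  pz <- snapshot_pod(spacetime_field(mesh, 1:3, vz))
  expect_true(pz$zero_variance)
  expect_equal(pz$eigenvalues, 0)
})
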