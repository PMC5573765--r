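#' Labelled triangular surface mesh
#'
#' A triangulated luminal surface with per-face region labels and optional
#' named rings (closed transverse bands of faces) from which ring-averaged
#' wall-shear-stress series are extracted. Face areas are computed from the
#' vertex coordinates.
#'
#' @param vertices Numeric `n_v x 3` matrix of coordinates, m.
#' @param faces Integer `n_f x 3` matrix of 1-based vertex indices.
#' @param region Character vector of per-face labels (e.g. "artery",
#'   "vein", "other"); recycled if length 1.
#' @param rings Named list of integer face-index vectors.
#' @return An object of class `surface_mesh` with computed `face_area`.
#' @export
surface_mesh <- function(vertices, faces, region = "artery", rings = list()) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L,
            max(faces) <= nrow(vertices), min(faces) >= 1L)
  if (length(region) == 1L) region <- rep(region, nrow(faces))
  stopifnot(length(region) == nrow(faces))
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  cc <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  face_area <- 0.5 * sqrt(rowSums(cr^2))
  if (any(face_area <= 0)) stop("degenerate faces with zero area")
  if (length(rings)) {
    stopifnot(!is.null(names(rings)), all(nzchar(names(rings))))
    for (nm in names(rings)) {
      if (length(rings[[nm]]) == 0L) stop("ring '", nm, "' is empty")
      stopifnot(all(rings[[nm]] >= 1L), all(rings[[nm]] <= nrow(faces)))
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 face_area = face_area, region = as.character(region),
                 rings = rings),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces, area %.4g m^2; regions: %s; %d ring(s)\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_area),
              paste(unique(x$region), collapse = ", "), length(x$rings)))
  invisible(x)
}

#' Space-time vector field on a surface mesh
#'
#' Per-face wall vector snapshots (typically the wall shear stress, Pa) at
#' uniformly spaced instants.
#'
#' @param mesh A [surface_mesh()].
#' @param times Snapshot instants, s (>= 2, strictly increasing).
#' @param vectors Numeric array `n_t x n_f x 3`.
#' @return An object of class `spacetime_field`.
#' @export
spacetime_field <- function(mesh, times, vectors) {
  stopifnot(inherits(mesh, "surface_mesh"), length(times) >= 2L,
            all(diff(times) > 0), length(dim(vectors)) == 3L,
            dim(vectors)[1L] == length(times),
            dim(vectors)[2L] == nrow(mesh$faces), dim(vectors)[3L] == 3L)
  structure(list(mesh = mesh, times = as.numeric(times), vectors = vectors),
            class = "spacetime_field")
}

#' @export
print.spacetime_field <- function(x, ...) {
  cat(sprintf("Space-time field: %d snapshots x %d faces over [%.4g, %.4g] s\n",
              length(x$times), nrow(x$mesh$faces), x$times[1L],
              x$times[length(x$times)]))
  invisible(x)
}

# n_t x n_f matrix of vector magnitudes
field_magnitude <- function(field) {
  sqrt(field$vectors[, , 1L]^2 + field$vectors[, , 2L]^2 +
         field$vectors[, , 3L]^2)
}

#' Ring-averaged wall-shear-stress magnitude
#'
#' Area-weighted mean of the field's vector magnitude over the faces of a
#' named ring, per snapshot: the scalar series \eqn{\bar\sigma_l(t)} used for
#' spectral unsteadiness analysis.
#'
#' @param field A [spacetime_field()].
#' @param ring Name of a ring defined on the field's mesh.
#' @return A [sampled_waveform()] (Pa).
#' @export
ring_average_magnitude <- function(field, ring) {
  stopifnot(inherits(field, "spacetime_field"))
  rings <- field$mesh$rings
  if (!ring %in% names(rings))
    stop("unknown ring '", ring, "'; available: ",
         paste(names(rings), collapse = ", "))
  idx <- rings[[ring]]
  w <- field$mesh$face_area[idx]
  mag <- field_magnitude(field)[, idx, drop = FALSE]
  sampled_waveform(field$times, as.numeric(mag %*% w) / sum(w), "Pa")
}

#' One-sided power spectral density of a windowed series
#'
#' Single-segment Hann-tapered periodogram of the mean-removed samples
#' falling inside an analysis window. The one-sided PSD is normalized so
#' that its rectangle-rule integral over frequency recovers the variance of
#' the tapered segment (up to taper correction); frequency resolution is the
#' reciprocal of the window length.
#'
#' @param series A uniformly sampled [sampled_waveform()].
#' @param window An [analysis_window()], or `NULL` for the full series.
#' @return An object of class `spectral_density`: list with `frequencies`
#'   (Hz), `power` (units^2/Hz) and `window_label`.
#' @export
compute_psd <- function(series, window = NULL) {
  stopifnot(inherits(series, "sampled_waveform"))
  tt <- series$times; xx <- series$values
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("series must be uniformly sampled")
  label <- "WT"
  if (!is.null(window)) {
    stopifnot(inherits(window, "analysis_window"))
    if (window$start < tt[1L] - 1e-9 || window$end > tt[length(tt)] + 1e-9)
      stop("window lies outside the series span")
    sel <- tt >= window$start - 1e-12 & tt <= window$end + 1e-12
    tt <- tt[sel]; xx <- xx[sel]
    label <- window$label
  }
  n <- length(xx)
  if (n < 8L) stop("fewer than 8 samples in window")
  dt <- mean(diff(tt))
  fs <- 1 / dt
  x <- xx - mean(xx)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1L) / (n - 1L)))  # Hann
  X <- fft(x * w)
  nf <- floor(n / 2)
  scale <- 2 / (fs * sum(w^2))
  power <- scale * Mod(X[1L + seq_len(nf)])^2
  if (n %% 2L == 0L) power[nf] <- power[nf] / 2  # Nyquist bin is not doubled
  structure(list(frequencies = seq_len(nf) / (n * dt), power = power,
                 window_label = label),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  ip <- x$frequencies[which.max(x$power)]
  cat(sprintf("PSD (%s): %d bins up to %.3g Hz, peak at %.3g Hz\n",
              x$window_label, length(x$frequencies),
              max(x$frequencies), ip))
  invisible(x)
}

#' Snapshot proper orthogonal decomposition of a wall vector field
#'
#' POD of the temporal fluctuation field \eqn{\sigma - \bar\sigma_t} over the
#' faces of one region, by the method of snapshots: the temporal mean field
#' is subtracted, the snapshot matrix is weighted by the square root of the
#' face areas (all three vector components share a face's weight), and its
#' singular value decomposition yields spatial modes orthonormal under the
#' area-weighted inner product, temporal coefficients, and eigenvalues equal
#' to the squared singular values. Eigenvalues below `1e-12` of the largest
#' are truncated to zero to stabilize mode counts.
#'
#' @param field A [spacetime_field()].
#' @param region Region label to restrict to, or `NULL` for all faces.
#' @param window An [analysis_window()] restricting the snapshots, or
#'   `NULL` for all.
#' @return An object of class `pod_result`: `eigenvalues` (nonincreasing),
#'   `energy_fraction` (cumulative, ends at 1), `spatial_modes`
#'   (`n_f_region x 3 x n_modes` array), `temporal_coeffs`
#'   (`n_t x n_modes`), `snapshot_count`, `face_index`, `times`,
#'   `zero_variance` flag.
#' @export
snapshot_pod <- function(field, region = NULL, window = NULL) {
  stopifnot(inherits(field, "spacetime_field"))
  fidx <- seq_len(nrow(field$mesh$faces))
  if (!is.null(region)) {
    fidx <- which(field$mesh$region == region)
    if (length(fidx) == 0L) stop("region '", region, "' has no faces")
  }
  tt <- field$times
  tsel <- rep(TRUE, length(tt))
  if (!is.null(window)) {
    stopifnot(inherits(window, "analysis_window"))
    tsel <- tt >= window$start - 1e-12 & tt <= window$end + 1e-12
  }
  if (sum(tsel) < 2L) stop("need at least 2 snapshots in window")
  tt <- tt[tsel]
  nt <- length(tt)
  nf <- length(fidx)
  # snapshot matrix: rows = time, cols = (face, component)
  X <- cbind(field$vectors[tsel, fidx, 1L, drop = TRUE],
             field$vectors[tsel, fidx, 2L, drop = TRUE],
             field$vectors[tsel, fidx, 3L, drop = TRUE])
  X <- matrix(X, nrow = nt)
  Xc <- sweep(X, 2L, colMeans(X))
  w <- rep(field$mesh$face_area[fidx], 3L)
  Y <- sweep(Xc, 2L, sqrt(w), `*`)
  if (max(abs(Y)) == 0) {
    return(structure(list(
      eigenvalues = 0, energy_fraction = 1,
      spatial_modes = array(0, c(nf, 3L, 1L)),
      temporal_coeffs = matrix(0, nt, 1L), snapshot_count = nt,
      face_index = fidx, times = tt, zero_variance = TRUE),
      class = "pod_result"))
  }
  sv <- svd(Y)
  lam <- sv$d^2
  keep <- lam > 1e-12 * lam[1L]
  lam[!keep] <- 0
  nm <- max(sum(keep), 1L)
  phi_w <- sv$v[, seq_len(nm), drop = FALSE] / sqrt(w)  # orthonormal under <,>_w
  spatial <- array(phi_w, c(nf, 3L, nm))
  coeffs <- sv$u[, seq_len(nm), drop = FALSE] %*% diag(sv$d[seq_len(nm)], nm)
  structure(list(
    eigenvalues = lam, energy_fraction = cumsum(lam) / sum(lam),
    spatial_modes = spatial, temporal_coeffs = coeffs,
    snapshot_count = nt, face_index = fidx, times = tt,
    zero_variance = FALSE),
    class = "pod_result")
}

#' @export
print.pod_result <- function(x, ...) {
  cat(sprintf("Snapshot POD: %d snapshots, %d nonzero mode(s); %d mode(s) for 96%% energy\n",
              x$snapshot_count, sum(x$eigenvalues > 0),
              modes_for_energy(x, 0.96)))
  invisible(x)
}

#' Number of POD modes needed to reach an energy fraction
#'
#' Smallest m such that the cumulative energy fraction of the leading m
#' modes reaches the threshold (0.96 being the conventional reporting
#' level for unsteadiness comparisons).
#'
#' @param pod A [snapshot_pod()] result.
#' @param threshold Energy fraction in (0, 1].
#' @return Integer mode count.
#' @export
modes_for_energy <- function(pod, threshold = 0.96) {
  stopifnot(inherits(pod, "pod_result"), threshold > 0, threshold <= 1)
  which(pod$energy_fraction >= threshold - 1e-12)[1L]
}

#' Reconstruct the fluctuation field from POD modes
#'
#' Sums `temporal_coeffs[, j] %*% spatial_modes[,, j]` over the leading
#' modes; with all modes this reproduces the mean-centred snapshot data.
#'
#' @param pod A [snapshot_pod()] result.
#' @param n_modes Number of leading modes (default: all retained).
#' @return Array `n_t x n_f_region x 3`.
#' @export
pod_reconstruct <- function(pod, n_modes = NULL) {
  stopifnot(inherits(pod, "pod_result"))
  nm <- n_modes %||% ncol(pod$temporal_coeffs)
  nf <- dim(pod$spatial_modes)[1L]
  nt <- nrow(pod$temporal_coeffs)
  flat <- matrix(pod$spatial_modes[, , seq_len(nm), drop = FALSE], ncol = nm)
  rec <- pod$temporal_coeffs[, seq_len(nm), drop = FALSE] %*% t(flat)
  array(rec, c(nt, nf, 3L))
}
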