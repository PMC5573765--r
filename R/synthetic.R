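#' Generator configuration
#'
#' Seeded configuration shared by the synthetic-data generators. Defaults
#' state the canonical conditions of the modelled setting: a 1 s pulse
#' period, 15 Fourier modes, peak inlet Reynolds number 1300 with a
#' time-averaged-to-peak ratio of 750/1300, a 5 mm brachial inlet, and the
#' canonical analysis-window sampling (full period: 1000 snapshots at
#' 0.001 s; systolic/diastolic windows: 1500 snapshots at 0.0002 s).
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_modes Harmonics in the generated inflow waveform.
#' @param period Pulse period, s.
#' @param peak_Re Peak inlet Reynolds number.
#' @param mean_to_peak Ratio of time-averaged to peak Reynolds number.
#' @param diameter Inlet diameter, m.
#' @param fluid A [fluid_properties()].
#' @param mesh_radius,mesh_length Synthetic tube dimensions, m.
#' @param mesh_n_theta,mesh_n_axial Mesh resolution (circumferential and
#'   axial vertex counts).
#' @param rank Spatial rank of generated wall fields.
#' @param noise Additive white-noise standard deviation for wall fields, Pa.
#' @param window_sampling Named list of `c(n, dt)` per window label.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_modes = 15L, period = 1,
                             peak_Re = 1300, mean_to_peak = 750 / 1300,
                             diameter = 5e-3, fluid = fluid_properties(),
                             mesh_radius = 2.5e-3, mesh_length = 0.05,
                             mesh_n_theta = 24L, mesh_n_axial = 40L,
                             rank = 5L, noise = 0,
                             window_sampling = list(
                               WT = c(n = 1000, dt = 0.001),
                               WS = c(n = 1500, dt = 2e-4),
                               WD = c(n = 1500, dt = 2e-4))) {
  structure(list(seed = as.integer(seed), n_modes = as.integer(n_modes),
                 period = period, peak_Re = peak_Re,
                 mean_to_peak = mean_to_peak, diameter = diameter,
                 fluid = fluid, mesh_radius = mesh_radius,
                 mesh_length = mesh_length,
                 mesh_n_theta = as.integer(mesh_n_theta),
                 mesh_n_axial = as.integer(mesh_n_axial),
                 rank = as.integer(rank), noise = noise,
                 window_sampling = window_sampling),
            class = "generator_config")
}

#' Generate a pulsatile inflow waveform
#'
#' Synthesizes a smooth, strictly positive pulsatile waveform of the stated
#' family: a raised-cosine systolic peak superposed on a constant base,
#' band-limited to `n_modes` harmonics and scaled so that the peak Reynolds
#' number at the stated inlet diameter equals `peak_Re` exactly. The pulse
#' amplitude is chosen (after band-limiting) so that the time-averaged to
#' peak Reynolds ratio equals `mean_to_peak`.
#'
#' @param cfg A [generator_config()].
#' @param systole_start,systole_width Timing of the raised-cosine systolic
#'   pulse as fractions of the period.
#' @return A [fourier_waveform()] in SI units (m^3/s).
#' @export
gen_inflow_waveform <- function(cfg = generator_config(),
                                systole_start = 0.08, systole_width = 0.30) {
  T <- cfg$period
  n <- 4096L
  tt <- seq(0, T, length.out = n + 1L)[-(n + 1L)]
  # zero-mean raised-cosine pulse
  ph <- (tt / T - systole_start) / systole_width
  g <- ifelse(ph >= 0 & ph <= 1, 0.5 * (1 - cos(2 * pi * ph)), 0)
  g <- g - mean(g)
  gw <- fourier_fit(sampled_waveform(tt, g), cfg$n_modes)
  gmax <- max(eval_waveform(gw, tt))
  r <- cfg$mean_to_peak
  stopifnot(r > 0, r < 1)
  A <- (1 / r - 1) / gmax
  wf <- fourier_waveform(T, 1, A * gw$harmonics, flow_units = "m3_s")
  scale_to_peak_reynolds(wf, cfg$peak_Re, cfg$diameter, cfg$fluid,
                         n_eval = n)
}

#' Generate a labelled cylindrical test mesh
#'
#' Open tube of the configured radius and length, triangulated from an
#' `n_axial x n_theta` vertex grid, with the upstream axial half labelled
#' "artery" and the downstream half "vein", and three closed transverse
#' rings of faces ("ring25", "ring50", "ring75") at 25/50/75% of the
#' length. Total face area matches `2*pi*R*L` up to faceting error.
#'
#' @param cfg A [generator_config()].
#' @return A [surface_mesh()].
#' @export
gen_cylinder_mesh <- function(cfg = generator_config()) {
  R <- cfg$mesh_radius; L <- cfg$mesh_length
  nth <- cfg$mesh_n_theta; nax <- cfg$mesh_n_axial
  if (R <= 0 || L <= 0 || nth < 3L || nax < 2L)
    stop("degenerate cylinder dimensions")
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  z <- seq(0, L, length.out = nax)
  verts <- cbind(R * cos(rep(th, times = nax)),
                 R * sin(rep(th, times = nax)),
                 rep(z, each = nth))
  vid <- function(i, j) (j - 1L) * nth + ((i - 1L) %% nth) + 1L  # i: theta, j: axial
  faces <- matrix(0L, 2L * nth * (nax - 1L), 3L)
  band <- integer(nrow(faces))
  k <- 0L
  for (j in seq_len(nax - 1L)) {
    for (i in seq_len(nth)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      cup <- vid(i, j + 1L); dup <- vid(i + 1L, j + 1L)
      faces[k + 1L, ] <- c(a, b, dup)
      faces[k + 2L, ] <- c(a, dup, cup)
      band[k + 1L] <- band[k + 2L] <- j
      k <- k + 2L
    }
  }
  zc <- (z[band] + z[band + 1L]) / 2
  region <- ifelse(zc < L / 2, "artery", "vein")
  ring_at <- function(frac) which(band == pmax(1L, round(frac * (nax - 1L))))
  rings <- list(ring25 = ring_at(0.25), ring50 = ring_at(0.5),
                ring75 = ring_at(0.75))
  surface_mesh(verts, faces, region, rings)
}

# area-orthonormal spatial patterns over (face, component) entries:
# columns orthonormal under the weighted inner product sum(w * u * v)
orthonormal_patterns <- function(n_entries, k, w) {
  M <- matrix(rnorm(n_entries * k), n_entries, k)
  Q <- qr.Q(qr(sqrt(w) * M))[, seq_len(k), drop = FALSE]
  Q / sqrt(w)
}

#' Generate a synthetic space-time WSS field
#'
#' Sum of `rank` area-orthonormal spatial patterns times zero-mean temporal
#' sinusoids at prescribed integer harmonics of the window (mutually
#' orthogonal on the discrete grid), superposed on a constant mean field,
#' plus optional white noise. With zero noise the snapshot POD of the field
#' has exactly `rank` nonzero eigenvalues with energies proportional to
#' `amplitudes^2`.
#'
#' @param mesh A [surface_mesh()].
#' @param cfg A [generator_config()]; `cfg$rank` and `cfg$noise` are used.
#' @param window Label of the sampling spec in `cfg$window_sampling`.
#' @param amplitudes Per-mode temporal amplitudes, Pa (default all 1).
#' @param freq_harmonics Integer harmonics of `1/(n*dt)` for the temporal
#'   signals (default `1:rank`).
#' @param mean_wss Constant mean WSS vector magnitude, Pa.
#' @return A [spacetime_field()] with attribute `truth` (list with
#'   `patterns`, `amplitudes`, `freqs`).
#' @export
gen_wss_field <- function(mesh, cfg = generator_config(), window = "WT",
                          amplitudes = NULL, freq_harmonics = NULL,
                          mean_wss = 2) {
  stopifnot(inherits(mesh, "surface_mesh"))
  k <- cfg$rank
  nf <- nrow(mesh$faces)
  if (k > 3L * nf) stop("rank exceeds the number of field degrees of freedom")
  ws <- cfg$window_sampling[[window]]
  n <- as.integer(ws[["n"]]); dt <- ws[["dt"]]
  # spatial patterns are orthonormal under the area-weighted inner product,
  # so a temporal amplitude of sqrt(total area) gives an area-mean-square
  # fluctuation of 1 Pa^2; default to a quarter of the mean WSS per mode
  amplitudes <- amplitudes %||%
    rep(0.25 * mean_wss * sqrt(sum(mesh$face_area)), k)
  freq_harmonics <- freq_harmonics %||% seq_len(k)
  stopifnot(length(amplitudes) == k, length(freq_harmonics) == k,
            all(freq_harmonics >= 1), all(freq_harmonics < n / 2),
            !anyDuplicated(freq_harmonics))
  set.seed(cfg$seed)
  w3 <- rep(mesh$face_area, 3L)
  pat <- orthonormal_patterns(3L * nf, k, w3)
  tt <- seq(0, by = dt, length.out = n)
  span <- n * dt
  temp <- vapply(seq_len(k), function(j)
    amplitudes[j] * sqrt(2) * sin(2 * pi * freq_harmonics[j] * tt / span),
    numeric(n))
  flat <- temp %*% t(pat)  # n x (3 nf)
  mean_vec <- c(rep(0, nf), rep(0, nf), rep(mean_wss, nf))
  flat <- sweep(flat, 2L, mean_vec, `+`)
  if (cfg$noise > 0) flat <- flat + rnorm(length(flat), 0, cfg$noise)
  vecs <- array(flat, c(n, nf, 3L))
  fld <- spacetime_field(mesh, tt, vecs)
  attr(fld, "truth") <- list(patterns = pat, amplitudes = amplitudes,
                             freqs = freq_harmonics / span)
  fld
}

#' Generate synthetic near-wall oxygen gradients
#'
#' Draws per-face wall-normal concentration gradients such that a target
#' area fraction of faces has lumen-to-wall normal oxygen flux below the
#' hypoxia threshold (uniformly in 20-80% of it) and the remainder lies
#' safely above (1.5-5x). The achieved below-threshold area fraction is
#' recorded as ground truth.
#'
#' @param mesh A [surface_mesh()].
#' @param cfg A [generator_config()].
#' @param target_fraction Target below-threshold area fraction in [0, 1].
#' @param props A [transport_properties()].
#' @param threshold Flux threshold, mol.m^-2.s^-1.
#' @return Numeric per-face `n . grad(C)` (mol/m^4) with attribute `truth`
#'   (list with `below_mask`, `area_fraction`, `threshold`).
#' @export
gen_oxygen_walldata <- function(mesh, cfg = generator_config(),
                                target_fraction = 0.25,
                                props = transport_properties(),
                                threshold = hypoxia_flux_threshold()) {
  stopifnot(inherits(mesh, "surface_mesh"),
            target_fraction >= 0, target_fraction <= 1)
  nf <- nrow(mesh$faces)
  set.seed(cfg$seed + 1L)
  ord <- sample.int(nf)
  area <- mesh$face_area
  cum <- cumsum(area[ord]) / sum(area)
  n_below <- sum(cum <= target_fraction)
  below <- logical(nf)
  if (n_below > 0L) below[ord[seq_len(n_below)]] <- TRUE
  flux <- numeric(nf)
  flux[below] <- runif(sum(below), 0.2, 0.8) * threshold
  flux[!below] <- runif(sum(!below), 1.5, 5) * threshold
  grad <- -flux / (2 * props$diffusivity)  # invert J = -2 kappa n.grad(C)
  attr(grad, "truth") <- list(below_mask = below,
                              area_fraction = sum(area[below]) / sum(area),
                              threshold = threshold)
  grad
}

#' Generate a self-consistent synthetic calibration problem
#'
#' Draws a ground-truth Windkessel set (RAO/UAO tied) uniformly within
#' +/- `spread` of the packaged P1-IN values and internal elements within
#' the same spread of their defaults, runs the 0D network to periodic
#' steady state, and derives calibration references from the truth run:
#' systolic/diastolic targets from the inlet-pressure extrema and the
#' reference venous outflow from the truth venous trace. The returned
#' surrogate is the 0D network itself with (optionally perturbed) truth
#' internal elements, honouring the high-fidelity trace contract.
#'
#' @param cfg A [generator_config()].
#' @param spread Relative half-width of the uniform truth draw.
#' @param perturb_internal Multiplicative factor applied to the surrogate's
#'   internal elements (1 = exact 0D fixed point).
#' @param dt Time step for the truth run, s.
#' @param n_ref Number of samples kept in the reference flow waveform.
#' @return List with `windkessel`, `internal`, `refs`
#'   ([calibration_refs()]), `surrogate` (function), `inflow`
#'   ([fourier_waveform()], mL/s) and `truth_solution`.
#' @export
gen_truth_network <- function(cfg = generator_config(), spread = 0.5,
                              perturb_internal = 1, dt = 1e-3,
                              n_ref = 201L) {
  set.seed(cfg$seed + 2L)
  base <- table1_windkessel("P1-IN")
  draw <- function(x) x * runif(1L, 1 - spread, 1 + spread)
  wk <- windkessel_set(
    rao = windkessel_terminal(draw(base$rao$R1), draw(base$rao$R2),
                              draw(base$rao$C)),
    vo = windkessel_terminal(draw(base$vo$R1), draw(base$vo$R2),
                             draw(base$vo$C)),
    tie_rao_uao = TRUE)
  d0 <- internal_elements()
  internal <- internal_elements(L1A = draw(d0$L1A), L2A = draw(d0$L2A),
                                L1V = draw(d0$L1V), R1A = draw(d0$R1A),
                                R2A = draw(d0$R2A), R1V = draw(d0$R1V))
  inflow <- gen_inflow_waveform(cfg)
  inflow <- fourier_waveform(inflow$period, inflow$mean_flow * 1e6,
                             inflow$harmonics * 1e6, flow_units = "ml_s")
  # run the truth through the same stability-aware evaluator used during
  # optimization, so the references are an exact fixed point of the model
  sol <- zero_d_evaluator(inflow, internal, dt = dt, max_cycles = 30L,
                          tol = 1e-5)(wk)$sol
  keep <- unique(round(seq(1L, length(sol$times), length.out = n_ref)))
  refs <- calibration_refs(
    Q_R = sampled_waveform(sol$times[keep], sol$branch_flows$Q_VO[keep],
                           "ml_s"),
    P_RS = max(sol$node_pressures$P_BAI),
    P_RD = min(sol$node_pressures$P_BAI))
  internal_sur <- internal_elements(
    L1A = internal$L1A * perturb_internal, L2A = internal$L2A * perturb_internal,
    L1V = internal$L1V * perturb_internal, R1A = internal$R1A * perturb_internal,
    R2A = internal$R2A * perturb_internal, R1V = internal$R1V * perturb_internal)
  surrogate <- function(wk_try) {
    zero_d_evaluator(inflow, internal_sur, dt = dt, max_cycles = 30L,
                     tol = 1e-5)(wk_try)$sol
  }
  list(windkessel = wk, internal = internal, refs = refs,
       surrogate = surrogate, inflow = inflow, truth_solution = sol)
}

#' Generate synthetic volumetric shear-rate histories
#'
#' Equal-volume cells with half-sine shear-rate histories whose peaks are
#' placed so that configured fractions of the blood volume exceed each
#' exposure threshold at some stage during the pulse. The default fractions
#' (1.00, 0.99, 0.93 above 10, 100, 250 1/s) state the canonical exposure
#' pattern used as a demonstration fixture.
#'
#' @param cfg A [generator_config()].
#' @param fractions Nonincreasing target volume fractions per threshold.
#' @param thresholds Ascending shear-rate thresholds, 1/s.
#' @param n_cells Number of cells (fractions are realized exactly when
#'   `fractions * n_cells` are integers).
#' @param n_t Samples per history.
#' @return List with `volumes` (m^3), `shear` (`n_t x n_cells` matrix, 1/s)
#'   and `truth` (achieved fractions).
#' @export
gen_shear_volume <- function(cfg = generator_config(),
                             fractions = c(1, 0.99, 0.93),
                             thresholds = c(10, 100, 250),
                             n_cells = 100L, n_t = 51L) {
  stopifnot(length(fractions) == length(thresholds),
            all(diff(fractions) <= 0), all(diff(thresholds) > 0))
  set.seed(cfg$seed + 3L)
  counts <- round(fractions * n_cells)
  peaks <- numeric(n_cells)
  hi <- c(thresholds[-1L], 2 * thresholds[length(thresholds)])
  assigned <- 0L
  for (j in rev(seq_along(thresholds))) {
    n_here <- counts[j] - assigned
    if (n_here > 0L) {
      lo <- thresholds[j]
      peaks[assigned + seq_len(n_here)] <-
        runif(n_here, 1.05 * lo, 0.95 * hi[j])
      assigned <- assigned + n_here
    }
  }
  if (assigned < n_cells)
    peaks[(assigned + 1L):n_cells] <- runif(n_cells - assigned,
                                            0.2 * thresholds[1L],
                                            0.95 * thresholds[1L])
  peaks <- peaks[sample.int(n_cells)]
  tt <- seq(0, 1, length.out = n_t)
  shear <- outer(sin(pi * tt), peaks)
  volumes <- rep(1e-9, n_cells)
  truth <- vapply(thresholds, function(th) mean(peaks > th), numeric(1L))
  names(truth) <- paste0(">", thresholds)
  list(volumes = volumes, shear = shear, truth = truth)
}
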