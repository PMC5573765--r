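#' Blood fluid properties
#'
#' Newtonian blood properties. Defaults are the values conventionally used for
#' human blood in large-vessel haemodynamics: dynamic viscosity
#' 3.5e-3 Pa.s and density 1060 kg/m^3.
#'
#' @param viscosity Dynamic viscosity, Pa.s. Must be > 0.
#' @param density Mass density, kg/m^3. Must be > 0.
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()
fluid_properties <- function(viscosity = 3.5e-3, density = 1060) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L, viscosity > 0,
            is.numeric(density), length(density) == 1L, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid: mu =", x$viscosity, "Pa.s, rho =", x$density, "kg/m^3\n")
  invisible(x)
}

#' Periodic flow waveform as mean plus complex harmonics
#'
#' Represents a T-periodic waveform
#' \deqn{Q(t) = \bar Q + \sum_{k=1}^{N} \mathrm{Re}\{c_k e^{i k \omega t}\},
#'   \quad \omega = 2\pi/T,}
#' the form in which pulsatile inlet boundary conditions are prescribed
#' (a physiological waveform truncated to its first N Fourier modes;
#' N = 15 for the canonical inflow).
#'
#' @param period Period T, s. Must be > 0.
#' @param mean_flow Mean (zeroth-mode) flow.
#' @param harmonics Complex vector of coefficients for harmonics 1..N.
#' @param flow_units Unit tag carried as metadata: "m3_s" (SI, default) or
#'   "ml_s" (clinical).
#' @return An object of class `fourier_waveform`.
#' @seealso [eval_waveform()], [fourier_fit()], [scale_to_peak_reynolds()]
#' @export
fourier_waveform <- function(period, mean_flow, harmonics = complex(0),
                             flow_units = c("m3_s", "ml_s")) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0,
            is.numeric(mean_flow), length(mean_flow) == 1L)
  flow_units <- match.arg(flow_units)
  harmonics <- as.complex(harmonics)
  structure(list(period = period, mean_flow = mean_flow,
                 harmonics = harmonics, flow_units = flow_units),
            class = "fourier_waveform")
}

#' @export
print.fourier_waveform <- function(x, ...) {
  cat("Fourier waveform: period", x$period, "s, mean", x$mean_flow,
      x$flow_units, ",", length(x$harmonics), "harmonics\n")
  invisible(x)
}

#' Evaluate a Fourier waveform at given times
#'
#' @param waveform A [fourier_waveform()].
#' @param t Numeric vector of times, s.
#' @param derivative If `TRUE`, return dQ/dt instead of Q.
#' @return Numeric vector of flow values (or rates of change).
#' @export
eval_waveform <- function(waveform, t, derivative = FALSE) {
  stopifnot(inherits(waveform, "fourier_waveform"), is.numeric(t))
  w <- 2 * pi / waveform$period
  n <- length(waveform$harmonics)
  out <- if (derivative) numeric(length(t)) else rep(waveform$mean_flow, length(t))
  if (n > 0L) {
    for (k in seq_len(n)) {
      ck <- waveform$harmonics[k]
      if (derivative) ck <- 1i * k * w * ck
      out <- out + Re(ck * exp(1i * k * w * t))
    }
  }
  out
}

#' Sampled waveform (time series carrier)
#'
#' A plain sampled time series with strictly increasing times; the carrier
#' used for pressure/flow traces (e.g. reference venous outflow) and
#' ring-averaged wall-shear-stress series.
#'
#' @param times Strictly increasing instants, s.
#' @param values Samples, same length as `times`.
#' @param units Optional unit string carried as metadata.
#' @return An object of class `sampled_waveform`.
#' @export
sampled_waveform <- function(times, values, units = NULL) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 units = units),
            class = "sampled_waveform")
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat("Sampled waveform:", length(x$times), "samples over [",
      x$times[1L], ",", x$times[length(x$times)], "] s",
      if (!is.null(x$units)) paste0(" (", x$units, ")"), "\n")
  invisible(x)
}

#' Fit a truncated Fourier series to one period of samples
#'
#' Extracts the mean and the first `n_modes` harmonics of a uniformly sampled
#' periodic signal by discrete Fourier transform. The sampled span is
#' interpreted as exactly one period: if the final sample lies one sampling
#' interval short of closing the period the grid is endpoint-exclusive; a
#' duplicated endpoint (value at t0 + T equal to the value at t0) is dropped.
#' The mean is preserved exactly.
#'
#' @param samples A [sampled_waveform()] covering one full period.
#' @param n_modes Number of harmonics to retain (>= 1), at most the Nyquist
#'   limit `floor((N-1)/2)` for N retained samples.
#' @param resample If `TRUE`, non-uniformly sampled input is linearly
#'   interpolated onto a uniform grid of the same size first; if `FALSE`
#'   (default) non-uniform sampling is an error.
#' @return A [fourier_waveform()] with period equal to the sampled span.
#' @export
fourier_fit <- function(samples, n_modes, resample = FALSE) {
  stopifnot(inherits(samples, "sampled_waveform"),
            is.numeric(n_modes), length(n_modes) == 1L, n_modes >= 1)
  n_modes <- as.integer(n_modes)
  tt <- samples$times
  xx <- samples$values
  dts <- diff(tt)
  uniform <- max(dts) - min(dts) <= 1e-9 * mean(dts)
  if (!uniform) {
    if (!resample) stop("non-uniform sampling; set resample = TRUE to interpolate")
    tu <- seq(tt[1L], tt[length(tt)], length.out = length(tt))
    xx <- approx(tt, xx, xout = tu)$y
    tt <- tu
    dts <- diff(tt)
  }
  dt <- mean(dts)
  # drop a duplicated closing endpoint so the DFT sees one open period
  if (abs(xx[length(xx)] - xx[1L]) <= 1e-9 * (max(abs(xx)) + 1e-300) &&
      length(xx) > 3L) {
    xx <- xx[-length(xx)]
  }
  n <- length(xx)
  period <- n * dt
  if (n_modes > floor((n - 1) / 2))
    stop("n_modes exceeds the Nyquist limit for ", n, " samples")
  X <- fft(xx) / n
  harmonics <- 2 * X[1L + seq_len(n_modes)]
  # phase-reference coefficients to t = times[1]
  w <- 2 * pi / period
  harmonics <- harmonics * exp(-1i * seq_len(n_modes) * w * tt[1L])
  units <- samples$units %||% "m3_s"
  if (!units %in% c("m3_s", "ml_s")) units <- "m3_s"
  fourier_waveform(period, mean(xx), harmonics, flow_units = units)
}

#' Reynolds number of pipe flow (mean-velocity convention)
#'
#' \deqn{Re = \frac{4 \rho |Q|}{\pi \mu D}} the convention under which the
#' canonical AVF inflow is scaled to a peak Reynolds number of 1300 at the
#' brachial artery inlet.
#'
#' @param flow Volumetric flow, m^3/s (may be a vector).
#' @param diameter Lumen diameter, m. Must be > 0.
#' @param fluid A [fluid_properties()].
#' @return Nonnegative dimensionless Reynolds number(s).
#' @export
reynolds_number <- function(flow, diameter, fluid = fluid_properties()) {
  stopifnot(is.numeric(flow), is.numeric(diameter), length(diameter) == 1L)
  if (diameter <= 0) stop("diameter must be strictly positive")
  4 * fluid$density * abs(flow) / (pi * fluid$viscosity * diameter)
}

#' Peak Reynolds number of a periodic waveform
#'
#' Maximum of [reynolds_number()] over one period, evaluated on a dense grid.
#'
#' @inheritParams reynolds_number
#' @param waveform A [fourier_waveform()] in SI flow units (m^3/s).
#' @param n_eval Grid size for the peak search.
#' @return The peak Reynolds number over one period.
#' @export
peak_reynolds <- function(waveform, diameter, fluid = fluid_properties(),
                          n_eval = 4096L) {
  tt <- seq(0, waveform$period, length.out = n_eval + 1L)[-(n_eval + 1L)]
  max(reynolds_number(eval_waveform(waveform, tt), diameter, fluid))
}

#' Scale a waveform to a prescribed peak Reynolds number
#'
#' Multiplies a waveform by the single positive scalar that brings its peak
#' Reynolds number over one period to `target_Re` (e.g. 1300 for the
#' canonical brachial-artery inflow).
#'
#' @inheritParams peak_reynolds
#' @param target_Re Target peak Reynolds number, > 0.
#' @return The scaled [fourier_waveform()].
#' @export
scale_to_peak_reynolds <- function(waveform, target_Re, diameter,
                                   fluid = fluid_properties(),
                                   n_eval = 4096L) {
  stopifnot(target_Re > 0)
  pk <- peak_reynolds(waveform, diameter, fluid, n_eval)
  if (pk == 0) stop("waveform is identically zero; cannot scale")
  s <- target_Re / pk
  fourier_waveform(waveform$period, s * waveform$mean_flow,
                   s * waveform$harmonics, flow_units = waveform$flow_units)
}

#' Womersley number
#'
#' \deqn{\alpha = \frac{D}{2}\sqrt{\omega \rho / \mu}} governing the shape of
#' oscillatory pipe-flow velocity profiles.
#'
#' @param diameter Lumen diameter, m (> 0).
#' @param angular_frequency Angular frequency omega, rad/s (>= 0).
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(diameter, angular_frequency,
                             fluid = fluid_properties()) {
  stopifnot(diameter > 0, angular_frequency >= 0)
  (diameter / 2) * sqrt(angular_frequency * fluid$density / fluid$viscosity)
}

# Complex Bessel J0/J1 by power series. Adequate to ~1e-9 for |z| <~ 20,
# the range reached by harmonic 15 of a 1 Hz waveform in a brachial-scale
# vessel (alpha ~ 13).
bessel_j0_c <- function(z) {
  term <- rep(1 + 0i, length(z))
  out <- term
  q <- -(z * z) / 4
  for (k in 1:80) {
    term <- term * q / (k * k)
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1e-300))) break
  }
  out
}

bessel_j1_c <- function(z) {
  term <- rep(1 + 0i, length(z))
  out <- term
  q <- -(z * z) / 4
  for (k in 1:80) {
    term <- term * q / (k * (k + 1))
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1e-300))) break
  }
  out * z / 2
}

#' Womersley velocity field in a circular pipe
#'
#' Bundles the lumen radius, driving flow waveform and fluid properties that
#' define the classical fully developed oscillatory pipe-flow solution. Each
#' harmonic of the waveform drives the per-harmonic Womersley profile,
#' normalized so that the cross-sectional integral of velocity reproduces the
#' waveform flow at every instant; the mean flow drives a Poiseuille profile.
#'
#' @param radius Lumen radius, m (> 0).
#' @param waveform A [fourier_waveform()] in SI units (m^3/s).
#' @param fluid A [fluid_properties()].
#' @return An object of class `womersley_field`.
#' @export
womersley_field <- function(radius, waveform, fluid = fluid_properties()) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            inherits(waveform, "fourier_waveform"))
  if (waveform$flow_units != "m3_s")
    stop("womersley_field requires SI flow units (m3_s)")
  structure(list(radius = radius, waveform = waveform, fluid = fluid),
            class = "womersley_field")
}

#' Evaluate the Womersley axial velocity
#'
#' Axial velocity u(r, t) of the field. The per-harmonic profile is
#' \deqn{u_k(r,t) = \mathrm{Re}\left\{\frac{Q_k}{\pi R^2}
#'   \frac{1 - J_0(\beta_k r/R)/J_0(\beta_k)}
#'        {1 - 2 J_1(\beta_k)/(\beta_k J_0(\beta_k))} e^{i k \omega t}\right\},
#'   \quad \beta_k = i^{3/2} \alpha_k,}
#' with \eqn{\alpha_k} the harmonic's Womersley number; for
#' \eqn{\alpha_k < 0.1} the quasi-steady parabolic limit is used to avoid
#' cancellation. The mean flow contributes the Poiseuille profile
#' \eqn{2\bar Q/(\pi R^2) (1 - (r/R)^2)}.
#'
#' @param field A [womersley_field()].
#' @param r Radial positions, m, each in [0, radius].
#' @param t Times, s.
#' @return A `length(r) x length(t)` matrix of axial velocities (m/s);
#'   dimensions of extent one are dropped.
#' @export
womersley_velocity <- function(field, r, t) {
  stopifnot(inherits(field, "womersley_field"), is.numeric(r), is.numeric(t))
  R <- field$radius
  if (any(r < 0 | r > R)) stop("r must lie within [0, radius]")
  wf <- field$waveform
  w <- 2 * pi / wf$period
  eta <- r / R
  # Poiseuille contribution of the mean flow
  u <- outer(2 * wf$mean_flow / (pi * R^2) * (1 - eta^2), rep(1, length(t)))
  nh <- length(wf$harmonics)
  if (nh > 0L) {
    for (k in seq_len(nh)) {
      Qk <- wf$harmonics[k]
      if (Mod(Qk) == 0) next
      alpha <- womersley_number(2 * R, k * w, field$fluid)
      osc <- exp(1i * k * w * t)
      if (alpha < 0.1) {
        prof <- 2 * Qk / (pi * R^2) * (1 - eta^2)
      } else {
        beta <- complex(modulus = alpha, argument = 3 * pi / 4) # i^{3/2} alpha
        j0b <- bessel_j0_c(beta)
        denom <- 1 - 2 * bessel_j1_c(beta) / (beta * j0b)
        prof <- Qk / (pi * R^2) * (1 - bessel_j0_c(beta * eta) / j0b) / denom
      }
      u <- u + Re(outer(prof, osc))
    }
  }
  drop(u)
}

#' Cross-sectional flow of a Womersley field by quadrature
#'
#' Numerically integrates `2*pi*r*u(r,t)` over the lumen; used to verify
#' flow consistency of [womersley_velocity()] against the driving waveform.
#'
#' @param field A [womersley_field()].
#' @param t Times, s.
#' @param n_r Number of radial quadrature points (made odd; composite
#'   Simpson rule).
#' @return Numeric vector of flows (m^3/s) at `t`.
#' @export
womersley_flow <- function(field, t, n_r = 401L) {
  R <- field$radius
  if (n_r %% 2L == 0L) n_r <- n_r + 1L
  rr <- seq(0, R, length.out = n_r)
  h <- rr[2L] - rr[1L]
  wts <- c(1, rep(c(4, 2), length.out = n_r - 2L), 1)
  wts[n_r] <- 1
  u <- womersley_velocity(field, rr, t)
  if (is.null(dim(u))) u <- matrix(u, nrow = n_r)
  as.numeric(crossprod(wts * 2 * pi * rr, u) * h / 3)
}
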