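#' Oxygen transport properties
#'
#' Diffusivity of oxygen in plasma and the Henry's-law solubility constant
#' linking dissolved concentration to partial pressure. Defaults are the
#' standard literature values kappa = 1.2e-9 m^2/s and
#' H = 1.74e-3 mol.m^-3.mmHg^-1.
#'
#' @param diffusivity Oxygen diffusivity in plasma, m^2/s (> 0).
#' @param henry_constant Henry's-law constant, mol.m^-3.mmHg^-1 (> 0).
#' @return An object of class `transport_properties`.
#' @export
transport_properties <- function(diffusivity = 1.2e-9,
                                 henry_constant = 1.74e-3) {
  stopifnot(diffusivity > 0, henry_constant > 0)
  structure(list(diffusivity = diffusivity, henry_constant = henry_constant),
            class = "transport_properties")
}

#' Henry's-law oxygen concentration
#'
#' `C = H * pO2`. With the default constant, a luminal partial pressure of
#' 75 mmHg gives the inlet concentration 1.305e-1 mol/m^3 and a wall partial
#' pressure of 60 mmHg gives the wall-sink concentration 1.044e-1 mol/m^3.
#'
#' @param pO2 Oxygen partial pressure, mmHg (>= 0; may be a vector).
#' @param props A [transport_properties()].
#' @return Concentration(s), mol/m^3.
#' @export
henry_concentration <- function(pO2, props = transport_properties()) {
  stopifnot(all(pO2 >= 0))
  props$henry_constant * pO2
}

#' Hypoxia flux threshold
#'
#' Minimum lumen-to-wall oxygen flux needed to keep an avascular wall layer
#' of the given thickness above its consumption rate:
#' `threshold = consumption_rate * wall_thickness`. With the literature
#' values 8.55e-3 mol.m^-3.s^-1 and 5e-5 m this is 4.275e-7 mol.m^-2.s^-1.
#'
#' @param consumption_rate Wall oxygen consumption, mol.m^-3.s^-1 (> 0).
#' @param wall_thickness Avascular wall layer thickness, m (> 0).
#' @return Flux threshold, mol.m^-2.s^-1.
#' @export
hypoxia_flux_threshold <- function(consumption_rate = 8.55e-3,
                                   wall_thickness = 5e-5) {
  stopifnot(consumption_rate > 0, wall_thickness > 0)
  consumption_rate * wall_thickness
}

#' Lumen-to-wall normal oxygen flux (LWNOF)
#'
#' \deqn{J = -2 \kappa\, \mathbf{n}\cdot\nabla C,} with `n` the outward
#' wall normal; the factor two accounts for the augmentation of oxygen
#' transport by haemoglobin. Positive flux means oxygen delivered from
#' lumen to wall (concentration decreasing outward).
#'
#' @param wall_normal_gradient Per-face `n . grad(C)`, mol/m^4.
#' @param props A [transport_properties()].
#' @return Per-face flux, mol.m^-2.s^-1.
#' @export
lwnof <- function(wall_normal_gradient, props = transport_properties()) {
  -2 * props$diffusivity * wall_normal_gradient
}

#' Wall classification thresholds
#'
#' Threshold triple for pathological wall exposure: time-averaged WSS
#' magnitude below `wss_low` ("WSS-"), above `wss_high` ("WSS+") and
#' time-averaged LWNOF below `flux_low` ("LWNOF-"). Defaults are the
#' literature-derived 0.5 Pa, 30 Pa, and 4.275e-7 mol.m^-2.s^-1.
#'
#' @param wss_low,wss_high WSS thresholds, Pa; `wss_low < wss_high`.
#' @param flux_low Oxygen flux threshold, mol.m^-2.s^-1.
#' @return An object of class `wall_map_thresholds`.
#' @export
wall_map_thresholds <- function(wss_low = 0.5, wss_high = 30,
                                flux_low = hypoxia_flux_threshold()) {
  stopifnot(wss_low > 0, wss_high > wss_low, flux_low > 0)
  structure(list(wss_low = wss_low, wss_high = wss_high,
                 flux_low = flux_low),
            class = "wall_map_thresholds")
}

#' Per-face time average of a field
#'
#' Trapezoidal time average over the snapshots. For vector fields the
#' magnitude is taken first, then averaged (the time-averaged WSS magnitude
#' convention), so an alternating field of constant magnitude averages to
#' that magnitude, not zero.
#'
#' @param field A [spacetime_field()], or a numeric `n_t x n_f` matrix of a
#'   scalar quantity.
#' @param times Required when `field` is a matrix: snapshot instants, s.
#' @return Numeric vector of per-face time averages.
#' @export
time_average_field <- function(field, times = NULL) {
  if (inherits(field, "spacetime_field")) {
    vals <- field_magnitude(field)
    times <- field$times
  } else {
    vals <- as.matrix(field)
    if (is.null(times)) stop("times required for matrix input")
  }
  stopifnot(nrow(vals) == length(times), length(times) >= 2L)
  span <- times[length(times)] - times[1L]
  apply(vals, 2L, function(col) trapz(times, col)) / span
}

#' Classify wall faces into pathology masks
#'
#' Builds the quad-colour map: per-face logical masks for pathologically low
#' WSS (`wss_low`, strict `<`), pathologically high WSS (`wss_high`, strict
#' `>`), pathologically low oxygen flux (`flux_low`, strict `<`) and the
#' overlap of low WSS with low flux. Faces exactly at a threshold are left
#' unclassified. Display labels use the precedence
#' yellow (overlap) > blue (low WSS) > red (high WSS) > green (low flux),
#' with "none" elsewhere.
#'
#' @param avg_wss Per-face time-averaged WSS magnitude, Pa.
#' @param avg_flux Per-face time-averaged LWNOF, mol.m^-2.s^-1.
#' @param thr A [wall_map_thresholds()].
#' @return An object of class `quad_map`: logical masks `wss_low`,
#'   `wss_high`, `flux_low`, `overlap` and character `label`.
#' @export
classify_wall <- function(avg_wss, avg_flux, thr = wall_map_thresholds()) {
  stopifnot(length(avg_wss) == length(avg_flux),
            inherits(thr, "wall_map_thresholds"))
  lo <- avg_wss < thr$wss_low
  hi <- avg_wss > thr$wss_high
  fl <- avg_flux < thr$flux_low
  ov <- lo & fl
  label <- rep("none", length(avg_wss))
  label[fl] <- "green"
  label[hi] <- "red"
  label[lo] <- "blue"
  label[ov] <- "yellow"
  structure(list(wss_low = lo, wss_high = hi, flux_low = fl, overlap = ov,
                 label = label, thresholds = thr),
            class = "quad_map")
}

#' @export
print.quad_map <- function(x, ...) {
  cat(sprintf("Quad map over %d faces: %d WSS-, %d WSS+, %d LWNOF-, %d overlap\n",
              length(x$label), sum(x$wss_low), sum(x$wss_high),
              sum(x$flux_low), sum(x$overlap)))
  invisible(x)
}

#' Percentage areas of pathology masks per region
#'
#' Area-weighted percentage of each region's surface covered by each mask of
#' a quad map (the bar-chart statistics of wall pathology exposure).
#'
#' @param map A [classify_wall()] quad map aligned with `mesh` faces.
#' @param mesh The [surface_mesh()] carrying face areas and region labels.
#' @param regions Regions to report; default all present.
#' @return A data.frame with one row per region and columns `region`,
#'   `wss_low`, `wss_high`, `flux_low`, `overlap` (percent of region area).
#' @export
percentage_areas <- function(map, mesh, regions = NULL) {
  stopifnot(inherits(map, "quad_map"), inherits(mesh, "surface_mesh"),
            length(map$label) == nrow(mesh$faces))
  regions <- regions %||% unique(mesh$region)
  out <- lapply(regions, function(rg) {
    sel <- mesh$region == rg
    if (!any(sel)) stop("region '", rg, "' has no faces")
    A <- sum(mesh$face_area[sel])
    pct <- function(mask) 100 * sum(mesh$face_area[sel & mask]) / A
    data.frame(region = rg, wss_low = pct(map$wss_low),
               wss_high = pct(map$wss_high), flux_low = pct(map$flux_low),
               overlap = pct(map$overlap))
  })
  do.call(rbind, out)
}

#' Volume fractions exposed to shear rates above thresholds
#'
#' For each threshold, the fraction of total blood volume whose shear rate
#' exceeds it at some stage during the pulse (maximum over the history),
#' volume-weighted. Fractions are nonincreasing in the threshold.
#'
#' @param volumes Per-cell volumes, m^3 (> 0).
#' @param shear_histories Numeric `n_t x n_cells` matrix of shear-rate
#'   samples, 1/s.
#' @param thresholds Positive ascending shear-rate thresholds, 1/s
#'   (default the conventional 10, 100, 250).
#' @return Named numeric vector of volume fractions in [0, 1].
#' @export
shear_rate_exposure <- function(volumes, shear_histories,
                                thresholds = c(10, 100, 250)) {
  stopifnot(all(volumes > 0), all(diff(thresholds) > 0), all(thresholds > 0))
  shear_histories <- as.matrix(shear_histories)
  stopifnot(ncol(shear_histories) == length(volumes))
  peaks <- apply(shear_histories, 2L, max)
  vt <- sum(volumes)
  out <- vapply(thresholds, function(th) sum(volumes[peaks > th]) / vt,
                numeric(1L))
  names(out) <- paste0(">", thresholds)
  out
}
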