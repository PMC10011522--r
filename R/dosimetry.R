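#' Sonication pulsing parameters
#'
#' Bundle a pulsed focused-ultrasound (FUS) scheme: fundamental frequency,
#' spatial-peak pulse-average intensity, pulse duration and repetition
#' frequency. The duty cycle is derived, never supplied.
#'
#' @param f0 Fundamental frequency in MHz (default 0.6).
#' @param isppa Spatial-peak pulse-average intensity \eqn{I_{SPPA}} in W/cm^2.
#' @param pd_ms Pulse duration in ms.
#' @param prf_hz Pulse repetition frequency in Hz.
#' @param duration_min Sonication duration in minutes (metadata only).
#' @return An object of class `sonication_params`.
#' @examples
#' sonication_params(0.6, 5, 50, 10) # the in vivo scheme: 50% duty cycle
#' @export
sonication_params <- function(f0 = 0.6, isppa = 5, pd_ms = 50, prf_hz = 10,
                              duration_min = 30) {
  assert_scalar_num(f0, "f0", lower = 0, strict_lower = TRUE)
  assert_scalar_num(isppa, "isppa", lower = 0)
  dc <- duty_cycle(pd_ms, prf_hz)
  structure(list(f0 = f0, isppa = isppa, pd_ms = pd_ms, prf_hz = prf_hz,
                 dc = dc, duration_min = duration_min),
            class = "sonication_params")
}

#' Acoustic medium and coupling properties
#'
#' Constants used to convert intensity to pressure and to propagate pressure
#' to the target. Defaults are degassed water (`density` 1000 kg/m^3,
#' `sound_speed` 1480 m/s) with 17% pressure attenuation through rat
#' skull/scalp at 600 kHz, 20% acoustic absorption at the protein surface,
#' and half of the surface area exposed to the incident wave.
#'
#' @param density Mass density in kg/m^3.
#' @param sound_speed Speed of sound in m/s.
#' @param pressure_attenuation Fractional peak-pressure loss through the
#'   skull/scalp, in `[0, 1]`.
#' @param absorption_fraction Fraction of incident momentum absorbed at the
#'   complex surface, in `[0, 1]`.
#' @param exposed_area_fraction Fraction of the complex surface area facing
#'   the incident wave, in `[0, 1]`.
#' @return An object of class `medium_props`.
#' @export
medium_props <- function(density = 1000, sound_speed = 1480,
                         pressure_attenuation = 0.17,
                         absorption_fraction = 0.2,
                         exposed_area_fraction = 0.5) {
  assert_scalar_num(density, "density", lower = 0, strict_lower = TRUE)
  assert_scalar_num(sound_speed, "sound_speed", lower = 0, strict_lower = TRUE)
  assert_scalar_num(pressure_attenuation, "pressure_attenuation", 0, 1)
  assert_scalar_num(absorption_fraction, "absorption_fraction", 0, 1)
  assert_scalar_num(exposed_area_fraction, "exposed_area_fraction", 0, 1)
  structure(list(density = density, sound_speed = sound_speed,
                 pressure_attenuation = pressure_attenuation,
                 absorption_fraction = absorption_fraction,
                 exposed_area_fraction = exposed_area_fraction),
            class = "medium_props")
}

#' Duty cycle of a pulsed scheme
#'
#' @param pd_ms Pulse duration in ms.
#' @param prf_hz Pulse repetition frequency in Hz.
#' @return Duty cycle as a fraction in `(0, 1]`: `pd_ms/1000 * prf_hz`.
#' @examples
#' duty_cycle(50, 10) # 0.5, the scheme carried into the in vivo study
#' duty_cycle(50, 5)  # 0.25
#' @export
duty_cycle <- function(pd_ms, prf_hz) {
  assert_scalar_num(pd_ms, "pd_ms", lower = 0, strict_lower = TRUE)
  assert_scalar_num(prf_hz, "prf_hz", lower = 0, strict_lower = TRUE)
  dc <- pd_ms / 1000 * prf_hz
  if (dc > 1 + 1e-12)
    stop_invalid("pulse duration x PRF gives duty cycle %g > 1", dc)
  min(dc, 1)
}

#' Spatial-peak temporal-average intensity
#'
#' @param isppa Spatial-peak pulse-average intensity, W/cm^2.
#' @param dc Duty cycle fraction in `(0, 1]`.
#' @return \eqn{I_{SPTA} = I_{SPPA} \times DC}, W/cm^2.
#' @examples
#' ispta(5, 0.25) # 1.25 W/cm^2
#' ispta(5, 0.50) # 2.50 W/cm^2
#' @export
ispta <- function(isppa, dc) {
  assert_scalar_num(isppa, "isppa", lower = 0)
  assert_scalar_num(dc, "dc", lower = 0, upper = 1, strict_lower = TRUE)
  isppa * dc
}

#' Peak rarefactional pressure from pulse-average intensity
#'
#' Plane-wave relation \eqn{P = \sqrt{2 \rho c I}} with `isppa` given in
#' W/cm^2 and the result in MPa.
#'
#' @param isppa Intensity in W/cm^2.
#' @param medium A [medium_props()] object (density and sound speed used).
#' @return Peak rarefactional pressure in MPa.
#' @examples
#' pr_from_isppa(5) # ~0.38 MPa in water
#' @export
pr_from_isppa <- function(isppa, medium = medium_props()) {
  assert_scalar_num(isppa, "isppa", lower = 0)
  sqrt(2 * medium$density * medium$sound_speed * isppa * 1e4) / 1e6
}

#' @rdname pr_from_isppa
#' @param pr Peak rarefactional pressure in MPa.
#' @export
isppa_from_pr <- function(pr, medium = medium_props()) {
  assert_scalar_num(pr, "pr", lower = 0)
  (pr * 1e6)^2 / (2 * medium$density * medium$sound_speed) / 1e4
}

#' Mechanical index
#'
#' @param pr Peak rarefactional pressure in MPa.
#' @param f0 Fundamental frequency in MHz.
#' @return \eqn{MI = P_r / \sqrt{f_0}} (dimensionless).
#' @examples
#' mechanical_index(0.38, 0.6) # ~0.49
#' @export
mechanical_index <- function(pr, f0) {
  assert_scalar_num(pr, "pr", lower = 0)
  assert_scalar_num(f0, "f0", lower = 0, strict_lower = TRUE)
  pr / sqrt(f0)
}

#' In situ pressure behind an attenuating layer
#'
#' @param pr Incident peak rarefactional pressure, MPa.
#' @param attenuation Fractional pressure loss in `[0, 1]`.
#' @return `pr * (1 - attenuation)` in MPa.
#' @examples
#' in_situ_pressure(0.38, 0.17) # ~0.32 MPa at the target through rat skull
#' @export
in_situ_pressure <- function(pr, attenuation) {
  assert_scalar_num(pr, "pr", lower = 0)
  assert_scalar_num(attenuation, "attenuation", 0, 1)
  pr * (1 - attenuation)
}

#' Ellipsoid model of the albumin molecule
#'
#' Serum albumin is approximated as a prolate ellipsoid with a ~14 nm long
#' axis and ~3 nm short axes, i.e. semi-axes (7, 1.5, 1.5) nm.
#'
#' @param semi_axes_nm Numeric vector of three semi-axes in nm.
#' @return An object of class `ellipsoid`.
#' @export
albumin_ellipsoid <- function(semi_axes_nm = c(7, 1.5, 1.5)) {
  if (length(semi_axes_nm) != 3L || any(!is.finite(semi_axes_nm)) ||
      any(semi_axes_nm <= 0))
    stop_invalid("semi_axes_nm must be three positive finite values")
  structure(list(semi_axes_nm = as.numeric(semi_axes_nm)), class = "ellipsoid")
}

#' Ellipsoid surface area
#'
#' Thomsen's approximation
#' \eqn{S \approx 4\pi \left[ (a^p b^p + a^p c^p + b^p c^p)/3 \right]^{1/p}}
#' with `p = 1.6075` (exact in the sphere limit, within ~1% for all shapes).
#' The exact prolate-spheroid closed form is available with
#' `method = "prolate"` when two semi-axes are equal.
#'
#' @param ellipsoid An [albumin_ellipsoid()] object or a length-3 numeric
#'   vector of semi-axes in nm.
#' @param method `"thomsen"` (default) or `"prolate"`.
#' @return Surface area in units of 1e-18 m^2 (numerically equal to nm^2).
#' @examples
#' ellipsoid_surface_area(albumin_ellipsoid()) # ~105.2 x 1e-18 m^2
#' @export
ellipsoid_surface_area <- function(ellipsoid = albumin_ellipsoid(),
                                   method = c("thomsen", "prolate")) {
  method <- match.arg(method)
  ax <- if (inherits(ellipsoid, "ellipsoid")) ellipsoid$semi_axes_nm
        else albumin_ellipsoid(ellipsoid)$semi_axes_nm
  ax <- sort(ax, decreasing = TRUE)
  a <- ax[1]; b <- ax[2]; c0 <- ax[3]
  if (method == "prolate") {
    if (abs(b - c0) > 1e-9 * b)
      stop_invalid("prolate closed form needs two equal short semi-axes")
    if (abs(a - b) < 1e-12 * a) return(4 * pi * a^2)
    e <- sqrt(1 - (b / a)^2)
    return(2 * pi * b^2 * (1 + a / (b * e) * asin(e)))
  }
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c0)^p + (b * c0)^p) / 3)^(1 / p)
}

#' Acoustic radiation force on a drug-protein complex
#'
#' Momentum-absorption estimate: the absorbed fraction of the in situ peak
#' rarefactional pressure acting on the exposed part of the complex surface,
#' \eqn{F = \alpha \, P_r \, (S \times f_{exposed})}.
#'
#' @param pr_insitu In situ peak rarefactional pressure, MPa.
#' @param surface_area Complex surface area in units of 1e-18 m^2.
#' @param medium A [medium_props()] object (absorption and exposed-area
#'   fractions used).
#' @return Radiation force in units of 1e-12 N (pN).
#' @examples
#' radiation_force(0.32, ellipsoid_surface_area()) # ~3.4 pN
#' @export
radiation_force <- function(pr_insitu, surface_area, medium = medium_props()) {
  assert_scalar_num(pr_insitu, "pr_insitu", lower = 0)
  assert_scalar_num(surface_area, "surface_area", lower = 0)
  pa <- pr_insitu * 1e6                       # MPa -> N/m^2
  area_m2 <- surface_area * 1e-18 * medium$exposed_area_fraction
  medium$absorption_fraction * pa * area_m2 / 1e-12
}

#' Full-width at half-maximum of a beam intensity map
#'
#' Along each principal axis through the global intensity maximum, the width
#' between the two half-maximum crossings, found by linear interpolation
#' between grid points.
#'
#' @param x,y Regular axis coordinates in mm (ascending).
#' @param intensity Matrix of intensities (W/cm^2), `length(x)` rows and
#'   `length(y)` columns, with a single interior global maximum.
#' @return Named numeric vector `c(fwhm_x, fwhm_y)` in mm.
#' @export
beam_fwhm <- function(x, y, intensity) {
  if (!is.matrix(intensity) || nrow(intensity) != length(x) ||
      ncol(intensity) != length(y))
    stop_invalid("intensity must be a length(x) x length(y) matrix")
  if (any(intensity < 0)) stop_invalid("intensities must be >= 0")
  peak <- which(intensity == max(intensity), arr.ind = TRUE)[1, ]
  c(fwhm_x = profile_fwhm(x, intensity[, peak[2]]),
    fwhm_y = profile_fwhm(y, intensity[peak[1], ]))
}

# width between half-maximum crossings of a 1-d profile, linear interpolation
profile_fwhm <- function(coord, prof) {
  imax <- which.max(prof)
  half <- prof[imax] / 2
  if (imax == 1 || imax == length(prof))
    stop_invalid("intensity peak sits on the map edge (beam truncated)")
  if (prof[imax - 1] <= half && prof[imax + 1] <= half)
    stop_invalid("peak undersampled: both neighbours of the maximum fall below half-maximum")
  left <- which(prof[seq_len(imax)] <= half)
  right <- which(prof[imax:length(prof)] <= half)
  if (length(left) == 0 || length(right) == 0)
    stop_invalid("half-maximum not bracketed within the map (beam truncated or undersampled)")
  il <- max(left)                       # last point <= half on the left
  cross_l <- coord[il] + (coord[il + 1] - coord[il]) *
    (half - prof[il]) / (prof[il + 1] - prof[il])
  ir <- imax - 1 + min(right)           # first point <= half on the right
  cross_r <- coord[ir - 1] + (coord[ir] - coord[ir - 1]) *
    (half - prof[ir - 1]) / (prof[ir] - prof[ir - 1])
  cross_r - cross_l
}

#' Acoustic dose report with regulatory checks
#'
#' Derives the full dose chain for a pulsing scheme: duty cycle,
#' \eqn{I_{SPTA}}, peak rarefactional pressure, mechanical index, in situ
#' pressure behind the skull, and the radiation force on the drug-albumin
#' complex, plus FDA (MI < 1.9) and IEC 60601-2 (\eqn{I_{SPTA} \le} 3 W/cm^2)
#' flags. Pressures entering the MI, in situ and force steps are first
#' rounded to two decimals so the report reproduces the conventional printed
#' chain (5 W/cm^2 -> 0.38 MPa -> MI 0.49 -> 0.32 MPa); full-precision
#' intermediates are kept in the `exact` field.
#'
#' @param params A [sonication_params()] object.
#' @param medium A [medium_props()] object.
#' @param ellipsoid An [albumin_ellipsoid()] object.
#' @return An object of class `dosimetry_report`: list with `ispta`, `pr`,
#'   `mi`, `pr_insitu`, `surface_area`, `radiation_force`, `fda_mi_ok`,
#'   `iec_ispta_ok` and full-precision `exact` values.
#' @examples
#' dose_report(sonication_params(0.6, 5, 50, 10))
#' @export
dose_report <- function(params = sonication_params(),
                        medium = medium_props(),
                        ellipsoid = albumin_ellipsoid()) {
  stopifnot(inherits(params, "sonication_params"),
            inherits(medium, "medium_props"),
            inherits(ellipsoid, "ellipsoid"))
  isp <- ispta_or_zero(params)
  pr_exact <- pr_from_isppa(params$isppa, medium)
  pr <- round(pr_exact, 2)
  mi <- mechanical_index(pr, params$f0)
  pr_insitu_exact <- in_situ_pressure(pr, medium$pressure_attenuation)
  pr_insitu <- round(pr_insitu_exact, 2)
  sa <- ellipsoid_surface_area(ellipsoid)
  force <- radiation_force(pr_insitu, sa, medium)
  structure(list(
    params = params,
    ispta = isp,
    pr = pr,
    mi = round(mi, 2),
    pr_insitu = pr_insitu,
    surface_area = sa,
    radiation_force = signif(force, 2),
    fda_mi_ok = mi < 1.9,
    iec_ispta_ok = isp <= 3,
    exact = list(pr = pr_exact, mi = mechanical_index(pr_exact, params$f0),
                 pr_insitu = in_situ_pressure(pr_exact,
                                              medium$pressure_attenuation),
                 radiation_force = force)
  ), class = "dosimetry_report")
}

ispta_or_zero <- function(params) {
  if (params$isppa == 0) 0 else ispta(params$isppa, params$dc)
}

#' @export
print.dosimetry_report <- function(x, ...) {
  p <- x$params
  cat(sprintf("FUS dose report: f0 = %.2g MHz, I_SPPA = %.3g W/cm^2, PD = %g ms, PRF = %g Hz\n",
              p$f0, p$isppa, p$pd_ms, p$prf_hz))
  cat(sprintf("  duty cycle      %.2f\n", p$dc))
  cat(sprintf("  I_SPTA          %.2f W/cm^2  [IEC <= 3: %s]\n",
              x$ispta, ifelse(x$iec_ispta_ok, "pass", "FAIL")))
  cat(sprintf("  P_r             %.2f MPa\n", x$pr))
  cat(sprintf("  MI              %.2f  [FDA < 1.9: %s]\n",
              x$mi, ifelse(x$fda_mi_ok, "pass", "FAIL")))
  cat(sprintf("  in situ P_r     %.2f MPa\n", x$pr_insitu))
  cat(sprintf("  complex surface %.5g x 1e-18 m^2\n", x$surface_area))
  cat(sprintf("  radiation force %.2g x 1e-12 N\n", x$radiation_force))
  invisible(x)
}
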