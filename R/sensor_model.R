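#' Physical description of the flexible hydrogel sensor array
#'
#' Geometry and elastic constants of the 6x6 flexible hydrogel sensor array
#' (FHSA). Each sensing unit is a 50 mm x 50 mm hydrogel square; the array
#' material has a Young's modulus of 209 kPa and a Poisson ratio of 0.42.
#' The film thickness is not uniquely fixed by the design and defaults to
#' 1 mm.
#'
#' @param rows,cols Number of sensing-unit rows and columns.
#' @param length_mm,width_mm,thickness_mm Sensing-unit dimensions in mm.
#' @param poisson Poisson ratio, in (0, 0.5).
#' @param youngs_modulus_kpa Young's modulus in kPa.
#'
#' @return A list of class `"fhsa_spec"`.
#' @examples
#' fhsa_spec()
#' @export
fhsa_spec <- function(rows = 6L, cols = 6L, length_mm = 50, width_mm = 50,
                      thickness_mm = 1, poisson = 0.42,
                      youngs_modulus_kpa = 209) {
  stopifnot(rows >= 1, cols >= 1)
  if (length_mm <= 0 || width_mm <= 0 || thickness_mm <= 0) {
    stop_domain("sensor dimensions must be positive")
  }
  if (poisson <= 0 || poisson >= 0.5) {
    stop_domain("poisson ratio must lie in (0, 0.5)")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         length_mm = length_mm, width_mm = width_mm,
         thickness_mm = thickness_mm, poisson = poisson,
         youngs_modulus_kpa = youngs_modulus_kpa,
         n_units = as.integer(rows) * as.integer(cols)),
    class = "fhsa_spec"
  )
}

#' @export
print.fhsa_spec <- function(x, ...) {
  cat(sprintf("FHSA: %dx%d units of %g x %g x %g mm (E = %g kPa, v = %g)\n",
              x$rows, x$cols, x$length_mm, x$width_mm, x$thickness_mm,
              x$youngs_modulus_kpa, x$poisson))
  invisible(x)
}

#' Convert resistance to conductance
#'
#' The calibration table records the sensing units' resistance in kOhm; the
#' calibration curve is parameterized in conductance, its reciprocal, in mS.
#'
#' @param resistance_kohm Resistance in kOhm; must be positive.
#' @return Conductance in mS (= 1/kOhm).
#' @examples
#' resistance_to_conductance(1.11) # ~0.90 mS
#' @export
resistance_to_conductance <- function(resistance_kohm) {
  if (any(!is.finite(resistance_kohm)) || any(resistance_kohm <= 0)) {
    stop_domain("resistance must be finite and positive")
  }
  1 / resistance_kohm
}

#' Quadratic conductance-to-pressure calibration curve
#'
#' The calibrated pressure response of the sensing units is a quadratic in
#' conductance through the origin, p = a G^2 + b G, with p in kg cm^-2 and
#' G in mS. The fitted array calibration is a = 0.022, b = 0.106.
#'
#' @param a Quadratic coefficient (kg cm^-2 mS^-2).
#' @param b Linear coefficient (kg cm^-2 mS^-1).
#' @return An object of class `"calibration_curve"`.
#' @examples
#' calibration_curve(0.022, 0.106)
#' @export
calibration_curve <- function(a = 0.022, b = 0.106) {
  stopifnot(is.finite(a), is.finite(b))
  if (a < 0 || b < 0) {
    warning("calibration coefficients are usually non-negative")
  }
  structure(list(a = a, b = b), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: p = %.4g G^2 + %.4g G  (kg cm^-2, G in mS)\n",
              x$a, x$b))
  invisible(x)
}

#' Evaluate the calibration curve
#'
#' @param g Conductance in mS; must be non-negative.
#' @param curve A [calibration_curve()].
#' @return Pressure in kg cm^-2.
#' @examples
#' pressure_from_conductance(0.9, calibration_curve(0.022, 0.106))
#' @export
pressure_from_conductance <- function(g, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(g)) || any(g < 0)) {
    stop_domain("conductance must be finite and non-negative")
  }
  curve$a * g^2 + curve$b * g
}

#' Invert the calibration curve
#'
#' Returns the unique non-negative conductance root of a G^2 + b G - p = 0.
#' Used by the simulator to map target pressures back to sensor conductance.
#'
#' @param p Pressure in kg cm^-2; must be non-negative.
#' @inheritParams pressure_from_conductance
#' @return Conductance in mS.
#' @examples
#' conductance_from_pressure(0.1132, calibration_curve(0.022, 0.106)) # ~0.9
#' @export
conductance_from_pressure <- function(p, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_domain("pressure must be finite and non-negative")
  }
  a <- curve$a
  b <- curve$b
  if (a == 0 && b == 0) {
    stop_domain("degenerate calibration curve: a = b = 0")
  }
  if (a == 0) {
    return(p / b)
  }
  (-b + sqrt(b^2 + 4 * a * p)) / (2 * a)
}

#' Fit the conductance-pressure calibration
#'
#' Ordinary least squares of pressure on (G^2, G) with zero intercept,
#' matching the curve family of [calibration_curve()]. The zero intercept
#' reflects the unloaded baseline, where conductance and pressure are both
#' zero.
#'
#' @param table A calibration table: a data frame with columns `pressure`
#'   (kg cm^-2) and `conductance` (mS), or `resistance_kohm` from which
#'   conductance is derived (infinite/NA resistance rows are treated as the
#'   unloaded zero-conductance baseline). At least two records with distinct
#'   conductances are required.
#' @return A [calibration_curve()] with the fitted coefficients.
#' @examples
#' fit_calibration(fhsa_calibration())
#' @export
fit_calibration <- function(table) {
  table <- as.data.frame(table)
  if (!"conductance" %in% names(table)) {
    if (!"resistance_kohm" %in% names(table)) {
      stop_domain("table needs a 'conductance' or 'resistance_kohm' column")
    }
    r <- table$resistance_kohm
    table$conductance <- ifelse(is.finite(r) & r > 0, 1 / r, 0)
  }
  if (!"pressure" %in% names(table)) {
    stop_domain("table needs a 'pressure' column")
  }
  g <- table$conductance
  p <- table$pressure
  keep <- is.finite(g) & is.finite(p)
  g <- g[keep]
  p <- p[keep]
  if (length(g) < 2 || length(unique(g)) < 2) {
    stop_domain("calibration fit needs at least two records with distinct conductances")
  }
  fit <- lm(p ~ 0 + I(g^2) + g)
  co <- unname(coef(fit))
  suppressWarnings(calibration_curve(a = co[1], b = co[2]))
}

#' Packaged FHSA calibration table
#'
#' The twelve-point pressure/resistance/conductance calibration of the
#' fabricated array (average over six randomly chosen unit locations). The
#' first row is the unloaded baseline, whose conductance is zeroed.
#'
#' @return A data frame with columns `pressure` (kg cm^-2),
#'   `resistance_kohm` and `conductance` (mS).
#' @examples
#' head(fhsa_calibration())
#' @export
fhsa_calibration <- function() {
  path <- system.file("extdata", "fhsa_calibration.tsv", package = "gaitwrf",
                      mustWork = TRUE)
  read_calibration_table(path)
}

#' Piezoresistive relative resistance change
#'
#' Relative resistance change dR/R of a sensing unit under in-plane load:
#' pi_x Fx + pi_y Fy, with pi_x and pi_y the transverse and longitudinal
#' piezoresistive coefficients (per N).
#'
#' @param fx,fy Horizontal transverse and longitudinal force components (N).
#' @param pi_x,pi_y Piezoresistive coefficients (N^-1).
#' @return Dimensionless relative resistance change.
#' @examples
#' relative_resistance_change(10, 5, pi_x = 0.01, pi_y = 0.02)
#' @export
relative_resistance_change <- function(fx, fy, pi_x, pi_y) {
  vals <- c(fx, fy, pi_x, pi_y)
  if (any(!is.finite(vals))) stop_domain("all inputs must be finite")
  pi_x * fx + pi_y * fy
}

#' Surface stress components under in-plane point load
#'
#' Elasticity-theory stress components at position (x, y) on the array
#' surface: sigma_x = 2 x^2 / (pi (x^2+y^2)^2) (x Fx + y Fy), and sigma_y
#' with 2 y^2 in place of 2 x^2. Undefined at the load point itself.
#'
#' @param x,y Position relative to the load point (mm); not both zero.
#' @param fx,fy In-plane force components (N).
#' @return A list with elements `sigma_x` and `sigma_y`.
#' @examples
#' surface_stress(1, 0, fx = 1, fy = 0) # sigma_x = 2/pi
#' @export
surface_stress <- function(x, y, fx, fy) {
  if (any(!is.finite(c(x, y, fx, fy)))) stop_domain("all inputs must be finite")
  r2 <- x^2 + y^2
  if (any(r2 == 0)) stop_domain("surface stress is singular at the origin")
  load <- (x * fx + y * fy) / (pi * r2^2)
  list(sigma_x = 2 * x^2 * load, sigma_y = 2 * y^2 * load)
}

#' Geometric design rule for the relative resistance change
#'
#' Dimensioning rule tying the unit's relative resistance change to its
#' strain and geometry: (1 + 2v) eps + l / (w t). The second term is taken
#' literally as length over cross-section (mm^-1 against the dimensionless
#' first term); it is isolated here so an alternative nondimensionalization
#' can be swapped in.
#'
#' @param poisson Poisson ratio v.
#' @param strain Strain eps (dimensionless).
#' @param length_mm,width_mm,thickness_mm Unit geometry (mm); `width_mm *
#'   thickness_mm` must be positive.
#' @return Relative resistance change.
#' @examples
#' geometric_resistance_change(0.42, 0.1, 50, 50, 1)
#' @export
geometric_resistance_change <- function(poisson, strain, length_mm, width_mm,
                                        thickness_mm) {
  if (any(!is.finite(c(poisson, strain, length_mm, width_mm, thickness_mm)))) {
    stop_domain("all inputs must be finite")
  }
  if (any(width_mm * thickness_mm <= 0)) {
    stop_domain("width and thickness must be positive")
  }
  (1 + 2 * poisson) * strain + length_mm / (width_mm * thickness_mm)
}

#' Strain-check stress at a position on the array
#'
#' Point-load stress used to check the designed geometry against the
#' material strain threshold: (3 / (4 pi)) t^3 (l^2 w^2 + t^2)^(-5/2) Fy.
#' The inverse-5/2-power reading is adopted (classical point-load decay:
#' stress falls off as the footprint grows); the whole expression lives in
#' this one function so the alternative reading can be substituted.
#'
#' @param length_mm,width_mm Footprint dimensions (mm).
#' @param thickness_mm Film thickness (mm); must be positive.
#' @param fy Longitudinal force (N).
#' @return Stress value, linear in `fy`.
#' @examples
#' strain_at_position(0, 0, 1, 1) # 3/(4*pi)
#' @export
strain_at_position <- function(length_mm, width_mm, thickness_mm, fy) {
  if (any(!is.finite(c(length_mm, width_mm, thickness_mm, fy)))) {
    stop_domain("all inputs must be finite")
  }
  if (any(thickness_mm <= 0)) stop_domain("thickness must be positive")
  (3 / (4 * pi)) * thickness_mm^3 *
    (length_mm^2 * width_mm^2 + thickness_mm^2)^(-5 / 2) * fy
}

#' Convert force on one sensing unit to pressure
#'
#' Helper converting a normal force in newton to the calibration's pressure
#' unit (kg cm^-2) over the 50 mm x 50 mm unit footprint (25 cm^2).
#'
#' @param force_n Force in N.
#' @param area_cm2 Loaded area in cm^2 (default one sensing unit).
#' @return Pressure in kg cm^-2.
#' @seealso [pressure_to_force()]
#' @export
force_to_pressure <- function(force_n, area_cm2 = 25) {
  stopifnot(area_cm2 > 0)
  force_n / 9.80665 / area_cm2
}

#' @rdname force_to_pressure
#' @param pressure Pressure in kg cm^-2.
#' @export
pressure_to_force <- function(pressure, area_cm2 = 25) {
  stopifnot(area_cm2 > 0)
  pressure * 9.80665 * area_cm2
}
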