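#' Stress-strain test record
#'
#' Container for one uniaxial tension or pure shear test of a legging fabric.
#' `direction` selects which constant the record estimates: `"x"` (course)
#' and `"y"` (wale) give Young's moduli, `"shear"` gives the in-plane shear
#' modulus. Strains are engineering strains (dimensionless); stresses in Pa.
#'
#' @param direction one of `"x"`, `"y"`, `"shear"`.
#' @param stress numeric vector of normal stress sigma (or shear stress tau)
#'   in Pa.
#' @param strain numeric vector of axial strain epsilon (or shear strain
#'   gamma), non-decreasing, same length as `stress`.
#' @param transverse_strain optional numeric vector of strain in the
#'   perpendicular in-plane direction; required by
#'   [estimate_poisson_ratio()].
#' @param label optional label used in error messages.
#' @return an object of class `stress_strain_record`.
#' @export
#' @examples
#' rec <- stress_strain_record("x", stress = c(0, 100, 200),
#'                             strain = c(0, 0.05, 0.10))
#' estimate_modulus(rec)
stress_strain_record <- function(direction = c("x", "y", "shear"),
                                 stress, strain, transverse_strain = NULL,
                                 label = "record") {
  direction <- match.arg(direction)
  stress <- as.numeric(stress)
  strain <- as.numeric(strain)
  if (length(stress) != length(strain) || length(strain) < 2L)
    stopf("'%s': stress and strain must have equal length >= 2", label)
  if (!all(is.finite(strain)) || !all(is.finite(stress)))
    stopf("'%s': non-finite stress or strain values", label)
  if (any(diff(strain) < 0))
    stopf("'%s': strain must be non-decreasing", label)
  if (!is.null(transverse_strain)) {
    transverse_strain <- as.numeric(transverse_strain)
    if (length(transverse_strain) != length(strain))
      stopf("'%s': transverse_strain length must match strain", label)
  }
  structure(
    list(direction = direction, stress = stress, strain = strain,
         transverse_strain = transverse_strain, label = label),
    class = "stress_strain_record")
}

#' @export
print.stress_strain_record <- function(x, ...) {
  cat(sprintf("<stress_strain_record '%s'> direction=%s, n=%d, strain [%g, %g]\n",
              x$label, x$direction, length(x$strain),
              min(x$strain), max(x$strain)))
  invisible(x)
}

# OLS slope with intercept; the slope is the modulus estimate.  A fitted line
# rather than a two-point ratio: robust to load-cell offset, and the fabrics
# are linear to Pearson r ~ 0.99 over the tested range.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Estimate a fabric modulus from a stress-strain record
#'
#' Least-squares slope of stress against strain (line fitted with an
#' intercept; the slope is reported). For `direction = "shear"` the result
#' is the shear modulus Gxy; otherwise the Young's modulus Ex or Ey.
#'
#' @param record a [stress_strain_record()].
#' @return modulus in Pa.
#' @export
estimate_modulus <- function(record) {
  if (!inherits(record, "stress_strain_record"))
    stopf("`record` must be a stress_strain_record")
  if (diff(range(record$strain)) <= 0)
    stopf("'%s': degenerate record, zero strain range", record$label)
  ols_slope(record$strain, record$stress)
}

#' Estimate the in-plane Poisson's ratio from a tension record
#'
#' Fits the transverse strain against the axial strain by least squares and
#' returns the negated slope, i.e. v = -eps_transverse / eps_axial for a
#' linear-elastic record. Values outside `[0, 0.5)` raise a warning (not an
#' error): they are physically suspect for a knit but can arise from noise.
#'
#' @param record a [stress_strain_record()] with `transverse_strain`.
#' @return Poisson's ratio, dimensionless.
#' @export
estimate_poisson_ratio <- function(record) {
  if (!inherits(record, "stress_strain_record"))
    stopf("`record` must be a stress_strain_record")
  if (is.null(record$transverse_strain))
    stopf("'%s': transverse_strain is required to estimate Poisson's ratio",
          record$label)
  if (diff(range(record$strain)) <= 0)
    stopf("'%s': degenerate record, zero strain range", record$label)
  v <- -ols_slope(record$strain, record$transverse_strain)
  if (v < 0 || v >= 0.5)
    warnf("'%s': estimated Poisson's ratio %.4f outside [0, 0.5)",
          record$label, v)
  v
}

#' Orthotropic fabric constants
#'
#' @param Ex,Ey Young's moduli along the course (x) and wale (y) directions,
#'   Pa.
#' @param Gxy in-plane shear modulus, Pa.
#' @param vxy in-plane Poisson's ratio (contraction in y per extension in x).
#' @param mass garment section mass in kg, used by the dynamic model.
#' @param label sample label.
#' @return an object of class `fabric_properties`.
#' @export
fabric_properties <- function(Ex, Ey, Gxy, vxy, mass = 0, label = "fabric") {
  assert_scalar_num(Ex, "Ex", 0, strict_lower = TRUE)
  assert_scalar_num(Ey, "Ey", 0, strict_lower = TRUE)
  assert_scalar_num(Gxy, "Gxy", 0, strict_lower = TRUE)
  assert_scalar_num(vxy, "vxy", 0)
  if (vxy >= 0.5) stopf("`vxy` must be < 0.5 (got %g)", vxy)
  assert_scalar_num(mass, "mass", 0)
  structure(list(Ex = Ex, Ey = Ey, Gxy = Gxy, vxy = vxy, mass = mass,
                 label = label),
            class = "fabric_properties")
}

#' @export
print.fabric_properties <- function(x, ...) {
  cat(sprintf(
    "<fabric_properties '%s'> Ex=%.4g Pa, Ey=%.4g Pa, Gxy=%.4g Pa, vxy=%.3f, mass=%.3g kg\n",
    x$label, x$Ex, x$Ey, x$Gxy, x$vxy, x$mass))
  invisible(x)
}

#' Fit fabric constants from a set of stress-strain records
#'
#' Convenience wrapper: takes one record per direction (`x`, `y`, `shear`),
#' estimates Ex, Ey, Gxy and vxy (from the x-direction record's transverse
#' strain) and assembles a [fabric_properties()] object.
#'
#' @param records list of [stress_strain_record()]s containing at least one
#'   record per direction `x`, `y` and `shear`.
#' @param mass garment mass in kg.
#' @param label sample label.
#' @return a [fabric_properties()] object.
#' @export
fit_fabric <- function(records, mass = 0, label = "fabric") {
  dirs <- vapply(records, function(r) r$direction, character(1))
  pick <- function(d) {
    i <- which(dirs == d)
    if (length(i) == 0L) stopf("no '%s'-direction record supplied", d)
    records[[i[1L]]]
  }
  rx <- pick("x")
  fabric_properties(
    Ex = estimate_modulus(rx),
    Ey = estimate_modulus(pick("y")),
    Gxy = estimate_modulus(pick("shear")),
    vxy = estimate_poisson_ratio(rx),
    mass = mass, label = label)
}

#' Orthotropic compliance matrix
#'
#' Builds the 3x3 plane-stress compliance matrix S mapping the stress vector
#' (sigma_x, sigma_y, tau_xy) to the strain vector (eps_x, eps_y, gamma_xy):
#' S11 = 1/Ex, S22 = 1/Ey, S66 = 1/Gxy and S12 = S21 = -vxy/Ex. Orthotropic
#' reciprocity (vxy/Ex = vyx/Ey) is imposed so that only vxy is needed; the
#' shear row/column is uncoupled (S16 = S26 = 0).
#'
#' @param props a [fabric_properties()] object.
#' @return matrix of class `compliance_matrix`, entries in 1/Pa.
#' @export
build_compliance <- function(props) {
  if (!inherits(props, "fabric_properties"))
    stopf("`props` must be a fabric_properties object")
  S <- matrix(0, 3, 3,
              dimnames = list(c("eps_x", "eps_y", "gamma_xy"),
                              c("sigma_x", "sigma_y", "tau_xy")))
  S[1, 1] <- 1 / props$Ex
  S[2, 2] <- 1 / props$Ey
  S[3, 3] <- 1 / props$Gxy
  S[1, 2] <- S[2, 1] <- -props$vxy / props$Ex
  class(S) <- c("compliance_matrix", class(S))
  S
}

#' Strain from stress through a compliance matrix
#'
#' @param S a [build_compliance()] matrix.
#' @param stress length-3 numeric vector (sigma_x, sigma_y, tau_xy) in Pa.
#' @return length-3 strain vector (eps_x, eps_y, gamma_xy), dimensionless.
#' @export
strain_from_stress <- function(S, stress) {
  if (!inherits(S, "compliance_matrix"))
    stopf("`S` must be a compliance_matrix")
  stress <- as.numeric(stress)
  if (length(stress) != 3L) stopf("`stress` must have length 3")
  drop(unclass(S) %*% stress)
}

#' Read stress-strain records from CSV
#'
#' Expects columns `direction,stress_pa,strain,transverse_strain` (header
#' required, UTF-8, '.' decimal separator). `transverse_strain` may be empty
#' for y/shear rows. One record is built per distinct direction value.
#'
#' @param path CSV file path.
#' @return named list of [stress_strain_record()]s, one per direction.
#' @export
read_stress_strain_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("direction", "stress_pa", "strain")
  if (!all(need %in% names(df)))
    stopf("%s: missing required columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (d in unique(df$direction)) {
    sub <- df[df$direction == d, , drop = FALSE]
    tv <- sub$transverse_strain
    if (is.null(tv) || all(is.na(tv))) tv <- NULL
    out[[d]] <- stress_strain_record(
      direction = d, stress = sub$stress_pa, strain = sub$strain,
      transverse_strain = tv, label = sprintf("%s[%s]", basename(path), d))
  }
  out
}

#' Reference fabric constants for the five legging samples
#'
#' Orthotropic constants of the five commercial legging fabrics measured by
#' uniaxial tension (Instron) and pure shear (KES-FB1): Young's moduli along
#' course (Ex) and wale (Ey), shear modulus Gxy and Poisson's ratio vxy.
#' Bundled as a machine-readable fixture.
#'
#' @return data.frame with columns `sample`, `Ex_pa`, `Ey_pa`, `Gxy_pa`,
#'   `vxy`.
#' @export
legging_fabrics <- function() {
  read_fixture("legging_fabrics.csv")
}

#' Garment geometry of the five legging samples
#'
#' Circumference of each legging at the six measurement sections (high hip,
#' low hip, mid-thigh, thigh, knee, calf) together with the vertical extent
#' of each section.
#'
#' @return data.frame with columns `sample`, `section`, `circumference_mm`,
#'   `section_height_mm`.
#' @export
legging_sections <- function() {
  read_fixture("legging_sections.csv")
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "limbdeform")
  if (!nzchar(path)) stopf("bundled fixture %s not found", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
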