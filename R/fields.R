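#' Scalar field specifications on articular surfaces
#'
#' Thickness (mm) and compressive-strain (dimensionless) fields on the
#' phantom's articular surfaces are specified as smooth or piecewise-constant
#' functions of normalized anatomical coordinates `(ap_n, si_n)`:
#' anteroposterior and superoinferior position scaled so the cartilage
#' footprint spans roughly \[-1, 1\] (anterior and superior positive).
#'
#' Available types:
#' * `field_constant(value)` — spatially uniform.
#' * `field_linear_ap(value, slope)` — `value + slope * ap_n`, a linear
#'   anteroposterior ramp.
#' * `field_radial_glenoid(center, periphery, peak_angle)` — the glenoid's
#'   characteristic center-thin / periphery-thick pattern:
#'   `center + (periphery - center) * r^2 * (1 + cos(psi - peak_angle)) / 2`
#'   with `r` the elliptical radius and `psi = atan2(si_n, ap_n)`; the
#'   default `peak_angle = -pi/4` puts the maximum at the anteroinferior
#'   periphery.
#' * `field_regional(values)` — piecewise-constant over anatomical thirds:
#'   `values` is a 3x3 matrix with `rownames` from
#'   `c("superior", "central", "inferior")` and `colnames` from
#'   `c("anterior", "central", "posterior")`. Third boundaries are the
#'   area-weighted terciles of the footprint coordinates, so sampling
#'   regions placed at the 20/50/80% footprint quantiles fall strictly
#'   inside their third.
#' * `field_regional_bands(superior, inferior)` — humeral variant: one 3x3
#'   regional matrix per superoinferior band (bands split at the footprint's
#'   median `si_n`).
#'
#' @param value,slope,center,periphery,peak_angle numeric parameters (mm for
#'   thickness fields, dimensionless fraction for strain fields; angles in
#'   radians).
#' @param values 3x3 labeled matrix of per-third values.
#' @param superior,inferior 3x3 labeled matrices (humeral bands).
#' @return object of class `field_spec`.
#' @export
field_constant <- function(value) {
  new_field("constant", value = value)
}

#' @rdname field_constant
#' @export
field_linear_ap <- function(value, slope) {
  new_field("linear_ap", value = value, slope = slope)
}

#' @rdname field_constant
#' @export
field_radial_glenoid <- function(center = 1.2, periphery = 1.5,
                                 peak_angle = -pi / 4) {
  new_field("radial_glenoid", center = center, periphery = periphery,
            peak_angle = peak_angle)
}

#' @rdname field_constant
#' @export
field_regional <- function(values) {
  values <- check_regional_matrix(values)
  new_field("regional", values = values)
}

#' @rdname field_constant
#' @export
field_regional_bands <- function(superior, inferior) {
  new_field("regional_bands",
            superior = check_regional_matrix(superior),
            inferior = check_regional_matrix(inferior))
}

#' Per-third regional matrix from anteroposterior values
#'
#' Convenience for fields that vary only along the anteroposterior axis:
#' builds the 3x3 matrix [field_regional()] expects with each
#' superoinferior row identical.
#'
#' @param anterior,central,posterior per-third values.
#' @export
ap_regional_values <- function(anterior, central, posterior) {
  m <- matrix(rep(c(anterior, central, posterior), each = 3), 3, 3)
  dimnames(m) <- list(c("superior", "central", "inferior"),
                      c("anterior", "central", "posterior"))
  m
}

new_field <- function(type, ...) {
  structure(list(type = type, ...), class = "field_spec")
}

check_regional_matrix <- function(values) {
  values <- as.matrix(values)
  si <- c("superior", "central", "inferior")
  ap <- c("anterior", "central", "posterior")
  if (is.null(dimnames(values)) && all(dim(values) == 3)) {
    dimnames(values) <- list(si, ap)
  }
  if (!setequal(rownames(values), si) || !setequal(colnames(values), ap)) {
    stop("regional matrix needs rownames {superior, central, inferior} and ",
         "colnames {anterior, central, posterior}")
  }
  values[si, ap]
}

is_field <- function(x) inherits(x, "field_spec")

# Evaluate a field at normalized anatomical coordinates.
# ctx carries the frozen footprint quantile boundaries of the phantom:
#   ap_terciles, si_terciles: length-2 boundaries in normalized coords;
#   si_split: band boundary; band_si_terciles: list(superior=, inferior=).
eval_field <- function(field, ap_n, si_n, ctx = NULL) {
  stopifnot(is_field(field))
  switch(field$type,
    constant = rep(field$value, length(ap_n)),
    linear_ap = field$value + field$slope * ap_n,
    radial_glenoid = {
      r2 <- pmin(1, ap_n^2 + si_n^2)
      psi <- atan2(si_n, ap_n)
      field$center + (field$periphery - field$center) * r2 *
        (1 + cos(psi - field$peak_angle)) / 2
    },
    regional = {
      apl <- bucket3(ap_n, ctx$ap_terciles,
                     c("posterior", "central", "anterior"))
      sil <- bucket3(si_n, ctx$si_terciles,
                     c("inferior", "central", "superior"))
      field$values[cbind(sil, apl)]
    },
    regional_bands = {
      upper <- si_n >= ctx$si_split
      out <- numeric(length(ap_n))
      for (band in c("superior", "inferior")) {
        sel <- if (band == "superior") upper else !upper
        if (!any(sel)) next
        apl <- bucket3(ap_n[sel], ctx$ap_terciles,
                       c("posterior", "central", "anterior"))
        sil <- bucket3(si_n[sel], ctx$band_si_terciles[[band]],
                       c("inferior", "central", "superior"))
        out[sel] <- field[[band]][cbind(sil, apl)]
      }
      out
    },
    stop("unknown field type: ", field$type)
  )
}

bucket3 <- function(x, breaks, labels) {
  labels[1L + (x >= breaks[1]) + (x >= breaks[2])]
}
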