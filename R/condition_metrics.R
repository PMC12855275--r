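#' Estimate body mass from axillary girth and body length
#'
#' Predicts polar bear body mass (kg) from axillary girth and dorsal body
#' length using the allometric regression
#' \deqn{W = 0.00003377 \, G^{1.7515} \, BL^{1.3678}}
#' where \eqn{G} is axillary girth (chest circumference at the axilla) in cm
#' and \eqn{BL} is dorsal straight-line body length in cm. The constants are
#' unit-bound: inputs must be centimetres, the result is kilograms.
#'
#' Values outside the plausible field ranges (girth 50--220 cm, length
#' 100--280 cm by default) trigger a warning but are still evaluated; field
#' data contain genuine extremes. Non-positive inputs are an error.
#'
#' @param girth_cm axillary girth in cm (vectorised).
#' @param length_cm body length in cm (vectorised).
#' @param girth_range,length_range numeric length-2 plausibility bounds used
#'   only for warnings.
#' @return estimated body mass in kg.
#' @examples
#' estimate_weight(100, 100)   # ~58.5 kg
#' @export
estimate_weight <- function(girth_cm, length_cm,
                            girth_range = c(50, 220),
                            length_range = c(100, 280)) {
  check_positive(girth_cm, "girth_cm")
  check_positive(length_cm, "length_cm")
  warn_outside(girth_cm, girth_range, "girth_cm")
  warn_outside(length_cm, length_range, "length_cm")
  0.00003377 * girth_cm^1.7515 * length_cm^1.3678
}

#' Body condition index (BCI)
#'
#' Standardised index of fat reserves computed from (estimated) body mass and
#' body length:
#' \deqn{BCI = \frac{\ln W - 3.07 \ln BL + 10.76}{0.17 + 0.009 \ln BL}}
#' with natural logarithms throughout. The index is dimensionless, strictly
#' increasing in mass at fixed length, and zero when
#' \eqn{\ln W = 3.07 \ln BL - 10.76}.
#'
#' @param weight_kg body mass in kg (typically from [estimate_weight()]).
#' @param length_cm body length in cm.
#' @return dimensionless condition index.
#' @examples
#' w <- estimate_weight(140, 190)
#' body_condition_index(w, 190)
#' @export
body_condition_index <- function(weight_kg, length_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(length_cm, "length_cm")
  lbl <- log(length_cm)
  (log(weight_kg) - 3.07 * lbl + 10.76) / (0.17 + 0.009 * lbl)
}

#' Quetelet's index
#'
#' Mass divided by length squared, \eqn{W / BL^2} in kg/cm^2; an alternative
#' condition measure that correlates tightly with the BCI.
#'
#' @inheritParams body_condition_index
#' @return Quetelet's index in kg/cm^2.
#' @export
quetelet_index <- function(weight_kg, length_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(length_cm, "length_cm")
  weight_kg / length_cm^2
}

#' Invert the BCI formula: mass giving a target BCI at a given length
#'
#' Solves the body-condition-index equation for mass. Used by the synthetic
#' data generator to back-solve morphometrics from a target index so that the
#' whole metric chain can be checked end to end.
#'
#' @param bci target condition index.
#' @param length_cm body length in cm.
#' @return mass in kg such that `body_condition_index(mass, length_cm) == bci`.
#' @export
weight_for_bci <- function(bci, length_cm) {
  check_positive(length_cm, "length_cm")
  lbl <- log(length_cm)
  exp(bci * (0.17 + 0.009 * lbl) + 3.07 * lbl - 10.76)
}

#' Invert the mass regression: girth giving a target mass at a given length
#'
#' @param weight_kg target mass in kg.
#' @param length_cm body length in cm.
#' @return axillary girth in cm such that
#'   `estimate_weight(girth, length_cm) == weight_kg`.
#' @export
girth_for_weight <- function(weight_kg, length_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(length_cm, "length_cm")
  (weight_kg / (0.00003377 * length_cm^1.3678))^(1 / 1.7515)
}

#' Append condition scores to a capture table
#'
#' Computes `weight_kg`, `bci` and `quetelet` from the `girth_cm` and
#' `length_cm` columns of a capture table and appends them.
#'
#' @param captures data frame with numeric `girth_cm` and `length_cm` columns.
#' @return the input with three columns appended.
#' @export
add_condition_scores <- function(captures) {
  stopifnot(is.data.frame(captures),
            all(c("girth_cm", "length_cm") %in% names(captures)))
  captures$weight_kg <- estimate_weight(captures$girth_cm, captures$length_cm)
  captures$bci <- body_condition_index(captures$weight_kg, captures$length_cm)
  captures$quetelet <- quetelet_index(captures$weight_kg, captures$length_cm)
  captures
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

warn_outside <- function(x, range, name) {
  n_out <- sum(x < range[1] | x > range[2])
  if (n_out > 0) {
    warning(sprintf("%d value(s) of '%s' outside plausible range [%g, %g]",
                    n_out, name, range[1], range[2]), call. = FALSE)
  }
  invisible(x)
}
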