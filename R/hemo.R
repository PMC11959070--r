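#' Derive cardiac output and stroke volume from pressure, resistance and rate
#'
#' Implements the Ohmic closure used to set the proximal boundary condition:
#' `CO = MAP / TPR` (mL/s when MAP is in mmHg and TPR in mmHg s/mL) and
#' `SV = CO * 60 / HR` (mL). Vectorized.
#'
#' @param map_mmhg mean arterial pressure (mmHg), > 0.
#' @param tpr total peripheral resistance (mmHg s/mL), > 0.
#' @param hr_bpm heart rate (bpm), > 0.
#' @return tibble with `co_ml_s`, `co_l_min`, `sv_ml`.
#' @export
#' @examples
#' derive_flow(89, 1.15, 64) # ~77.4 mL/s, ~72.6 mL
derive_flow <- function(map_mmhg, tpr, hr_bpm) {
  if (any(!is.finite(map_mmhg)) || any(map_mmhg <= 0)) abort("`map_mmhg` must be > 0")
  if (any(!is.finite(tpr)) || any(tpr <= 0)) abort("`tpr` must be > 0")
  if (any(!is.finite(hr_bpm)) || any(hr_bpm <= 0)) abort("`hr_bpm` must be > 0")
  co <- map_mmhg / tpr
  tibble(co_ml_s = co, co_l_min = co * 0.06, sv_ml = co * 60 / hr_bpm)
}

#' Left-ventricular ejection time (Weissler regression)
#'
#' `ET = 0.266 + 0.0011 (SV - 82) - 0.0009 (HR - 73)` seconds. Results are
#' clamped to (0.05 s, 0.95 period) with a warning, so the ejection always
#' fits inside the cardiac cycle.
#'
#' @param sv_ml stroke volume (mL), > 0.
#' @param hr_bpm heart rate (bpm), > 0.
#' @return ejection time (s), vectorized.
#' @export
#' @examples
#' weissler_et(82, 73) # 0.266
weissler_et <- function(sv_ml, hr_bpm) {
  if (any(!is.finite(sv_ml)) || any(sv_ml <= 0)) abort("`sv_ml` must be > 0")
  if (any(!is.finite(hr_bpm)) || any(hr_bpm <= 0)) abort("`hr_bpm` must be > 0")
  et <- 0.266 + 0.0011 * (sv_ml - 82) - 0.0009 * (hr_bpm - 73)
  hi <- 0.95 * 60 / hr_bpm
  clamped <- et < 0.05 | et > hi
  if (any(clamped)) {
    warn(paste0(sum(clamped), " ejection time(s) clamped into (0.05 s, ",
                "0.95 period)"))
    et <- pmin(pmax(et, 0.05), hi)
  }
  et
}

#' Segment-length scaling factor from body height
#'
#' The tree geometry is standardized for a height of 180 cm; all segment
#' lengths are multiplied by `height / 180` (e.g. 170 cm gives 0.94).
#'
#' @param height_cm body height (cm), > 0.
#' @param reference_cm reference height (cm).
#' @return dimensionless factor, vectorized.
#' @export
length_scale_factor <- function(height_cm, reference_cm = 180) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    abort("`height_cm` must be > 0")
  }
  height_cm / reference_cm
}

#' Body surface area (Du Bois)
#'
#' `BSA = 0.007184 * W^0.425 * H^0.725` (m^2).
#'
#' @param weight_kg body weight (kg).
#' @param height_cm body height (cm).
#' @return BSA in m^2, vectorized.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    abort("weight and height must be > 0")
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Default aortic-diameter model coefficients
#'
#' Linear model `diameter = intercept(gender) + age_slope * age +
#' bsa_slope * BSA` for the ascending aortic diameter (cm). The shipped
#' coefficients are package defaults calibrated to give ~3.1 cm for the
#' reference subject (male, 45 years, 180 cm, 75 kg); replace them to use
#' published regression coefficients.
#'
#' @param intercept_male,intercept_female intercepts (cm).
#' @param age_slope cm per year.
#' @param bsa_slope cm per m^2.
#' @param reference list giving the reference subject (`age`, `gender`,
#'   `weight`, `height`) whose modelled diameter defines scale factor 1.
#' @return a list of class `aortic_diameter_coeffs`.
#' @export
aortic_diameter_coeffs <- function(intercept_male = 1.80,
                                   intercept_female = 1.65,
                                   age_slope = 0.009, bsa_slope = 0.45,
                                   reference = list(age = 45, gender = "M",
                                                    weight = 75, height = 180)) {
  structure(
    list(intercept_male = intercept_male, intercept_female = intercept_female,
         age_slope = age_slope, bsa_slope = bsa_slope, reference = reference),
    class = "aortic_diameter_coeffs"
  )
}

aortic_diameter_cm <- function(age, gender, weight, height, coeffs) {
  icpt <- ifelse(gender == "F", coeffs$intercept_female, coeffs$intercept_male)
  icpt + coeffs$age_slope * age + coeffs$bsa_slope * bsa_dubois(weight, height)
}

#' Diameter scaling factor from age, gender and body size
#'
#' Evaluates the aortic-diameter model for the subject and divides by the
#' modelled diameter of the reference subject; the resulting factor is
#' applied uniformly to all arterial inlet/outlet diameters.
#'
#' @param age_group stratum label (`"20-29"` ... `">70"`) or numeric age in
#'   years.
#' @param gender `"M"` or `"F"`.
#' @param weight_kg body weight (kg).
#' @param height_cm body height (cm).
#' @param coeffs an [aortic_diameter_coeffs()] object.
#' @return dimensionless factor, vectorized.
#' @export
diameter_scale_factor <- function(age_group, gender, weight_kg, height_cm,
                                  coeffs = aortic_diameter_coeffs()) {
  if (!inherits(coeffs, "aortic_diameter_coeffs")) {
    abort("`coeffs` must be an `aortic_diameter_coeffs` object")
  }
  for (f in c("intercept_male", "intercept_female", "age_slope", "bsa_slope")) {
    if (is.null(coeffs[[f]]) || !is.finite(coeffs[[f]])) {
      abort(paste0("missing diameter-model coefficient: ", f))
    }
  }
  age <- if (is.numeric(age_group)) age_group else age_group_midpoint(age_group)
  if (!all(gender %in% c("M", "F"))) abort("`gender` must be 'M' or 'F'")
  ref <- coeffs$reference
  d_ref <- aortic_diameter_cm(ref$age, ref$gender, ref$weight, ref$height, coeffs)
  aortic_diameter_cm(age, gender, weight_kg, height_cm, coeffs) / d_ref
}
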