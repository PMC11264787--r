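# Derived cardiovascular traits from raw per-sample measurements.
#
# All formulas operate on per-sample summary measurements (oscillometric blood
# pressures, impedance-cardiography stroke volume and heart rate, pulse-wave
# transit distance/time, laser-Doppler skin flux, MRI volumes); no waveform
# processing happens here.

#' Mean arterial pressure
#'
#' MAP = (SBP + 2 DBP) / 3, the usual weighting reflecting the relative
#' duration of diastole over the cardiac cycle.
#'
#' @param sbp systolic blood pressure (mmHg), > 0.
#' @param dbp diastolic blood pressure (mmHg), > 0 and <= `sbp`.
#' @return mean arterial pressure (mmHg).
#' @examples
#' mean_arterial_pressure(127, 76.2)
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  check_numeric(sbp, "sbp", positive = TRUE)
  check_numeric(dbp, "dbp", positive = TRUE)
  if (any(dbp > sbp, na.rm = TRUE))
    stop_mv("diastolic pressure exceeds systolic pressure")
  (sbp + 2 * dbp) / 3
}

#' Body surface area (Du Bois)
#'
#' Classic Du Bois & Du Bois formula:
#' BSA = 0.007184 * weight^0.425 * height^0.725, height in cm, weight in kg.
#'
#' @param height_cm standing height in cm, > 0.
#' @param weight_kg body weight in kg, > 0.
#' @return body surface area in m^2.
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  check_numeric(height_cm, "height_cm", positive = TRUE)
  check_numeric(weight_kg, "weight_kg", positive = TRUE)
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Hemodynamic indices from stroke volume, heart rate and MAP
#'
#' Cardiac output CO = SV * HR / 1000 (L/min); systemic vascular resistance
#' SVR = MAP / CO * 80 (dynes.s.cm^-5); stroke index, cardiac index and SVR
#' index divide by body surface area.
#'
#' @param sv stroke volume (mL), > 0.
#' @param hr heart rate (beats per minute), > 0.
#' @param map mean arterial pressure (mmHg), > 0.
#' @param bsa body surface area (m^2), > 0.
#' @return data.frame with columns `si`, `co`, `ci`, `svr`, `svri`.
#' @export
hemodynamic_indices <- function(sv, hr, map, bsa) {
  for (nm in c("sv", "hr", "map", "bsa"))
    check_numeric(get(nm), nm, positive = TRUE)
  co <- sv * hr / 1000
  data.frame(
    si = sv / bsa,
    co = co,
    ci = co / bsa,
    svr = map / co * 80,
    svri = map / co * 80 / bsa
  )
}

#' Arterial stiffness measures
#'
#' Pulse pressure PP = SBP - DBP; total arterial compliance TAC = SV / PP
#' (mL/mmHg) with indexed TACI = TAC / BSA; aorta-femoral pulse wave velocity
#' PWV = transit distance / transit time (m/s).
#'
#' @param sv stroke volume (mL).
#' @param sbp,dbp systolic/diastolic pressure (mmHg), `sbp > dbp`.
#' @param bsa body surface area (m^2).
#' @param distance_m pulse transit distance, supra-sternal notch to
#'   mid-femoral cuff (m).
#' @param transit_time_s pulse propagation time (s), > 0.
#' @return data.frame with columns `pp`, `tac`, `taci`, `pwv`.
#' @export
arterial_stiffness <- function(sv, sbp, dbp, bsa, distance_m, transit_time_s) {
  if (any(sbp - dbp <= 0, na.rm = TRUE))
    stop_mv("pulse pressure must be positive (sbp > dbp)")
  if (any(transit_time_s <= 0, na.rm = TRUE))
    stop_mv("transit time must be positive")
  pp <- sbp - dbp
  data.frame(
    pp = pp,
    tac = sv / pp,
    taci = sv / pp / bsa,
    pwv = distance_m / transit_time_s
  )
}

#' Reactive skin hyperemia and white-matter hyperintensity burden
#'
#' RSH is the percentage increase of skin blood flow from baseline to the
#' heating plateau; WMH burden is hyperintensity volume relative to white
#' matter volume (a brain-size-free small-vessel-disease marker).
#'
#' @param flux_base baseline skin flux (arbitrary units), > 0.
#' @param flux_plateau plateau skin flux (arbitrary units).
#' @param wmh_vol white-matter hyperintensity volume (mL), >= 0.
#' @param wm_vol white matter volume (mL), > `wmh_vol`.
#' @return data.frame with columns `rsh` (percent) and `wmh_burden` (ratio in
#'   \[0, 1)).
#' @export
derived_ratios <- function(flux_base, flux_plateau, wmh_vol, wm_vol) {
  if (any(flux_base <= 0, na.rm = TRUE))
    stop_mv("baseline flux must be positive")
  if (any(wm_vol <= 0, na.rm = TRUE)) stop_mv("white matter volume must be positive")
  if (any(wmh_vol < 0 | wmh_vol >= wm_vol, na.rm = TRUE))
    stop_mv("WMH volume must lie in [0, white matter volume)")
  data.frame(
    rsh = 100 * (flux_plateau - flux_base) / flux_base,
    wmh_burden = wmh_vol / wm_vol
  )
}

# Trait columns entering association models, with their variance-stabilising
# transformation ("log", "logit" or identity).
trait_transforms <- c(
  taci = "id", si = "id", ci = "id", svri = "id",
  pwv = "log", rsh = "log", wmh_burden = "logit",
  tac = "id", sv = "id", co = "id", svr = "id"
)

#' Build the full derived-trait table from raw measurements
#'
#' @param samples data.frame with columns `sample_id`, `height`, `weight`,
#'   `sbp`, `dbp`, `sv`, `hr`, `distance`, `transit_time`, `flux_base`,
#'   `flux_plateau`, and optionally `wmh_vol`, `wm_vol`.
#' @return data.frame keyed by `sample_id` with MAP, BSA, BMI, pulse pressure,
#'   indexed and non-indexed hemodynamic and stiffness traits, RSH and (when
#'   volumes are present) WMH burden.
#' @export
build_trait_table <- function(samples) {
  need <- c("sample_id", "height", "weight", "sbp", "dbp", "sv", "hr",
            "distance", "transit_time", "flux_base", "flux_plateau")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_mv("missing raw measurement columns: %s",
                            paste(miss, collapse = ", "))
  map <- mean_arterial_pressure(samples$sbp, samples$dbp)
  bsa <- bsa_du_bois(samples$height, samples$weight)
  hemo <- hemodynamic_indices(samples$sv, samples$hr, map, bsa)
  stiff <- arterial_stiffness(samples$sv, samples$sbp, samples$dbp, bsa,
                              samples$distance, samples$transit_time)
  out <- data.frame(
    sample_id = samples$sample_id,
    map = map, bsa = bsa,
    bmi = samples$weight / (samples$height / 100)^2,
    sv = samples$sv, pp = stiff$pp,
    hemo[c("si", "co", "ci", "svr", "svri")],
    stiff[c("tac", "taci", "pwv")],
    rsh = 100 * (samples$flux_plateau - samples$flux_base) / samples$flux_base,
    stringsAsFactors = FALSE
  )
  if (any(out$rsh <= -100)) stop_mv("baseline flux must be positive")
  if (all(c("wmh_vol", "wm_vol") %in% names(samples))) {
    out$wmh_burden <- derived_ratios(samples$flux_base, samples$flux_plateau,
                                     samples$wmh_vol, samples$wm_vol)$wmh_burden
  }
  out
}

#' Transform and standardize analysis traits
#'
#' Applies a natural-log transform to the right-skewed traits (pulse wave
#' velocity, reactive skin hyperemia), a logit transform to WMH burden, and
#' z-standardizes every analysis trait to mean 0, sd 1 over non-missing
#' samples. Zero burdens are replaced by half the smallest positive observed
#' burden before the logit so the transform stays finite and monotone.
#'
#' @param traits trait table from [build_trait_table()].
#' @return the table with added `<trait>_z` columns; the per-column means and
#'   sds used are stored in `attr(, "scaling")`.
#' @export
transform_traits <- function(traits) {
  present <- intersect(names(trait_transforms), names(traits))
  scaling <- list()
  for (tr in present) {
    x <- traits[[tr]]
    kind <- trait_transforms[[tr]]
    if (kind == "log") {
      if (any(x <= 0, na.rm = TRUE))
        stop_mv("trait '%s' must be positive for log transform", tr)
      x <- log(x)
    } else if (kind == "logit") {
      if (any(x < 0 | x >= 1, na.rm = TRUE))
        stop_mv("trait '%s' must lie in [0, 1) for logit transform", tr)
      if (any(x == 0, na.rm = TRUE)) {
        pos <- min(x[x > 0], na.rm = TRUE)
        x[x == 0] <- pos / 2
      }
      x <- stats::qlogis(x)
    }
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop_mv("trait '%s' has zero variance", tr)
    traits[[paste0(tr, "_z")]] <- (x - m) / s
    scaling[[tr]] <- c(mean = m, sd = s)
  }
  attr(traits, "scaling") <- scaling
  traits
}
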