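#' Intravenous bolus dose event
#'
#' @param species species name receiving the dose
#' @param amount dose amount (nmol), >= 0
#' @param time dosing time (min), >= 0
#' @param route only `"iv_bolus"` (into plasma) is supported
#' @return an object of class `dose_event`
#' @export
dose_event <- function(species, amount, time = 0, route = "iv_bolus") {
  route <- match.arg(route, "iv_bolus")
  if (!is.finite(amount) || amount < 0) stop("dose amount must be >= 0", call. = FALSE)
  if (!is.finite(time) || time < 0) stop("dose time must be >= 0", call. = FALSE)
  structure(list(species = species, amount = as.numeric(amount),
                 time = as.numeric(time), route = route),
            class = "dose_event")
}

#' Convert a weight-normalised dose to nanomoles
#'
#' nmol = dose (mg/kg) * body weight (kg) * 1e6 / molecular weight (g/mol).
#'
#' @param dose_mg_per_kg dose in mg/kg, > 0
#' @param body_weight_kg body weight in kg, > 0
#' @param mw molecular weight in g/mol, > 0
#' @return dose in nmol
#' @examples
#' mgkg_to_nmol(2, 0.025, 325.77)  # midazolam bolus in a 25 g mouse
#' @export
mgkg_to_nmol <- function(dose_mg_per_kg, body_weight_kg, mw) {
  if (!is.finite(dose_mg_per_kg) || dose_mg_per_kg <= 0)
    stop("dose must be > 0", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be > 0", call. = FALSE)
  if (!is.finite(mw) || mw <= 0)
    stop("molecular weight must be > 0", call. = FALSE)
  dose_mg_per_kg * body_weight_kg * 1e6 / mw
}
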