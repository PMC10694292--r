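#' Physiological context for a reduced PBPK model
#'
#' A minimal whole-body representation with five volumetric compartments
#' (plasma, liver blood, hepatocyte, kidney, rest of body), organ blood
#' flows, a glomerular filtration rate and a bile flow. Units follow the
#' package convention: volumes in L, flows in L/min, body weight in kg.
#'
#' @param body_weight body weight (kg), > 0
#' @param compartment_volumes named numeric vector of volumes (L) with
#'   entries `plasma`, `liver_blood`, `hepatocyte`, `kidney`, `rest_of_body`
#' @param blood_flows named numeric vector of flows (L/min) with entries
#'   `liver`, `kidney`, `rest_of_body`
#' @param gfr glomerular filtration rate (L/min), >= 0
#' @param bile_flow bile flow (L/min), >= 0
#' @return an object of class `physiology`
#' @seealso [mouse_physiology()] for shipped rodent defaults
#' @export
physiology <- function(body_weight, compartment_volumes, blood_flows, gfr, bile_flow) {
  vol_names <- c("plasma", "liver_blood", "hepatocyte", "kidney", "rest_of_body")
  flow_names <- c("liver", "kidney", "rest_of_body")
  stopifnot(is.numeric(body_weight), length(body_weight) == 1L)
  if (!(body_weight > 0)) stop("body_weight must be > 0", call. = FALSE)
  if (!all(vol_names %in% names(compartment_volumes)))
    stop("compartment_volumes must name: ", paste(vol_names, collapse = ", "), call. = FALSE)
  if (!all(flow_names %in% names(blood_flows)))
    stop("blood_flows must name: ", paste(flow_names, collapse = ", "), call. = FALSE)
  v <- compartment_volumes[vol_names]
  q <- blood_flows[flow_names]
  if (any(!is.finite(v)) || any(v <= 0)) stop("all compartment volumes must be > 0", call. = FALSE)
  if (any(!is.finite(q)) || any(q < 0)) stop("all blood flows must be >= 0", call. = FALSE)
  if (!is.finite(gfr) || gfr < 0) stop("gfr must be >= 0", call. = FALSE)
  if (!is.finite(bile_flow) || bile_flow < 0) stop("bile_flow must be >= 0", call. = FALSE)
  structure(
    list(
      body_weight = as.numeric(body_weight),
      compartment_volumes = v,
      blood_flows = q,
      gfr = as.numeric(gfr),
      bile_flow = as.numeric(bile_flow)
    ),
    class = "physiology"
  )
}

#' Default mouse physiology
#'
#' Standard rodent physiology for a 25 g mouse. These are generic literature
#' placeholder values for a reduced model, editable by the caller; they are
#' not estimates from any particular experiment.
#'
#' @param body_weight body weight in kg (default 0.025)
#' @return a [physiology()] object scaled linearly with body weight
#' @export
mouse_physiology <- function(body_weight = 0.025) {
  f <- body_weight / 0.025
  physiology(
    body_weight = body_weight,
    compartment_volumes = c(
      plasma = 0.0010, liver_blood = 0.0003, hepatocyte = 0.0010,
      kidney = 0.0004, rest_of_body = 0.0190
    ) * f,
    blood_flows = c(liver = 0.0018, kidney = 0.0013, rest_of_body = 0.0080) * f,
    gfr = 0.00028 * f,
    bile_flow = 2.5e-6 * f
  )
}

#' @export
print.physiology <- function(x, ...) {
  cat("<physiology> body weight", x$body_weight, "kg\n")
  cat("  volumes (L):", paste(names(x$compartment_volumes),
    signif(x$compartment_volumes, 3), sep = "=", collapse = ", "), "\n")
  cat("  flows (L/min):", paste(names(x$blood_flows),
    signif(x$blood_flows, 3), sep = "=", collapse = ", "), "\n")
  cat("  gfr:", signif(x$gfr, 3), "L/min; bile flow:", signif(x$bile_flow, 3), "L/min\n")
  invisible(x)
}
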