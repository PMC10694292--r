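#' Chemical species (parent drug or metabolite)
#'
#' @param name species identifier (e.g. "MDZ", "OH-MDZ-G")
#' @param molecular_weight g/mol, > 0
#' @param fraction_unbound unbound fraction in plasma/tissue water, in (0, 1];
#'   all clearance and transport rates act on the unbound concentration
#' @param partition named tissue-to-plasma partition coefficients (Kp, > 0)
#'   for `kidney` and `rest_of_body`; distribution to these organs is
#'   flow-limited with venous equilibration at C_tissue / Kp
#' @param passive_exchange_cl passive bidirectional diffusion clearance
#'   (L/min, >= 0) across the liver_blood/hepatocyte interface. Glucuronides
#'   must have 0 here: carriers are their only way across hepatocyte
#'   membranes, which keeps basolateral and canalicular export mechanistically
#'   distinct.
#' @param is_glucuronide logical; marks phase-II glucuronide conjugates
#'   (targets of the biliary- and sinusoidal-export hypothesis selectors)
#' @return an object of class `chem_species`
#' @export
chem_species <- function(name, molecular_weight, fraction_unbound,
                         partition = c(kidney = 1, rest_of_body = 1),
                         passive_exchange_cl = 0,
                         is_glucuronide = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("species name must be a non-empty string", call. = FALSE)
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be > 0", call. = FALSE)
  if (!is.finite(fraction_unbound) || fraction_unbound <= 0 || fraction_unbound > 1)
    stop("fraction_unbound must be in (0, 1]", call. = FALSE)
  if (!all(c("kidney", "rest_of_body") %in% names(partition)))
    stop("partition must name kidney and rest_of_body", call. = FALSE)
  partition <- partition[c("kidney", "rest_of_body")]
  if (any(!is.finite(partition)) || any(partition <= 0))
    stop("all partition coefficients must be > 0", call. = FALSE)
  if (!is.finite(passive_exchange_cl) || passive_exchange_cl < 0)
    stop("passive_exchange_cl must be >= 0", call. = FALSE)
  if (isTRUE(is_glucuronide) && passive_exchange_cl != 0)
    stop("glucuronide species must have passive_exchange_cl = 0 (carrier-only membranes)",
         call. = FALSE)
  structure(
    list(
      name = name,
      molecular_weight = as.numeric(molecular_weight),
      fraction_unbound = as.numeric(fraction_unbound),
      partition = partition,
      passive_exchange_cl = as.numeric(passive_exchange_cl),
      is_glucuronide = isTRUE(is_glucuronide)
    ),
    class = "chem_species"
  )
}
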