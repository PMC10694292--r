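#' @name cocktail
#' @title The six-drug phenotyping cocktail
#'
#' @description
#' The package ships reduced PBPK models for the six probe drugs of the
#' cocktail and their quantified metabolites:
#' caffeine -> paraxanthine (Cyp1a2); codeine -> morphine (Cyp2d22),
#' norcodeine (Cyp3a11) and codeine-6-glucuronide (Ugt), with morphine
#' further conjugated to morphine-3-glucuronide (Ugt); midazolam ->
#' 1-hydroxymidazolam (Cyp3a11) -> 1-hydroxymidazolam glucuronide (Ugt);
#' torsemide -> hydroxy torsemide (Cyp2c29, a modelling assumption) with
#' Slco1b2-mediated hepatic uptake; pravastatin with Slco1b2 uptake; and
#' talinolol with Abcb1a canalicular export. Every glucuronide is exported
#' from hepatocytes by the sinusoidal carriers Abcc3/Abcc4 and the
#' canalicular carrier Abcc2, and crosses no membrane passively.
#'
#' Drug-specific rate constants and physicochemical values shipped here are
#' synthetic placeholders from standard reference ranges, chosen so each
#' family shows a realistic disposition regime in the mouse (biliary-dominant
#' glucuronide efflux in health, export carriers operating near their Km).
#' They are configuration, not measurements, and are expected to be refit to
#' data via [fit_reference()].
NULL

.COCKTAIL_MW <- c(caffeine = 194.19, codeine = 299.36, midazolam = 325.77,
                  torsemide = 348.42, pravastatin = 424.53, talinolol = 363.49)
.COCKTAIL_DOSE_MGKG <- c(caffeine = 5, codeine = 2, midazolam = 2,
                         pravastatin = 20, talinolol = 1, torsemide = 2)
.COCKTAIL_PARENT <- c(caffeine = "CAF", codeine = "COD", midazolam = "MDZ",
                      pravastatin = "PRS", talinolol = "TAL", torsemide = "TRS")

# shared placeholder export capacities for glucuronide carriers (nmol/min):
# canalicular export dominates in health (~2% sinusoidal share) and the
# carriers run near Km, i.e. biliary-dominant, mildly saturable efflux
.GLUC_EXPORT <- list(abcc3 = 2e-3, abcc4 = 2e-3, abcc2 = 0.15)

gluc_processes <- function(sp, abcc2_vmax = .GLUC_EXPORT$abcc2) {
  list(
    p_mm_transport("Abcc3", sp, "sinusoidal_out", vmax = .GLUC_EXPORT$abcc3),
    p_mm_transport("Abcc4", sp, "sinusoidal_out", vmax = .GLUC_EXPORT$abcc4),
    p_mm_transport("Abcc2", sp, "canalicular", vmax = abcc2_vmax)
  )
}

.COCKTAIL_BUILDERS <- list(
  caffeine = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("CAF", 194.19, 0.70, c(kidney = 0.8, rest_of_body = 0.7), 0.02),
        chem_species("PX", 180.16, 0.70, c(kidney = 0.7, rest_of_body = 0.6), 0.02)
      ),
      processes = list(
        p_enzymatic("Cyp1a2", "CAF", "PX", cl = 3e-4),
        p_total_clearance("CAF", cl = 2e-4),
        p_total_clearance("PX", cl = 4e-4),
        p_glomerular_filtration("CAF", gfr),
        p_glomerular_filtration("PX", gfr)
      ),
      name = "caffeine"
    )
  },
  codeine = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("COD", 299.36, 0.75, c(kidney = 2, rest_of_body = 4), 0.02),
        chem_species("MRP", 285.34, 0.65, c(kidney = 2, rest_of_body = 3), 0.015),
        chem_species("NCD", 285.34, 0.70, c(kidney = 1.5, rest_of_body = 2), 0.015),
        chem_species("C6G", 475.50, 0.90, c(kidney = 0.3, rest_of_body = 0.3), 0,
                     is_glucuronide = TRUE),
        chem_species("M3G", 461.46, 0.90, c(kidney = 0.3, rest_of_body = 0.3), 0,
                     is_glucuronide = TRUE)
      ),
      processes = c(list(
        p_enzymatic("Cyp2d22", "COD", "MRP", cl = 4e-3),
        p_enzymatic("Cyp3a11", "COD", "NCD", cl = 4e-3),
        p_enzymatic("Ugt", "COD", "C6G", cl = 8e-4),
        p_enzymatic("Ugt", "MRP", "M3G", cl = 1e-3),
        p_total_clearance("COD", cl = 6e-3),
        p_total_clearance("MRP", cl = 4e-3),
        p_total_clearance("NCD", cl = 3e-3),
        p_glomerular_filtration("COD", gfr),
        p_glomerular_filtration("MRP", gfr),
        p_glomerular_filtration("NCD", gfr),
        p_glomerular_filtration("C6G", gfr),
        p_glomerular_filtration("M3G", gfr)
      ), gluc_processes("C6G", 0.12), gluc_processes("M3G", 0.12)),
      name = "codeine"
    )
  },
  midazolam = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("MDZ", 325.77, 0.02, c(kidney = 3, rest_of_body = 4), 0.05),
        chem_species("OH-MDZ", 341.77, 0.03, c(kidney = 2.5, rest_of_body = 3), 0.05),
        chem_species("OH-MDZ-G", 517.93, 0.90, c(kidney = 0.3, rest_of_body = 0.3), 0,
                     is_glucuronide = TRUE)
      ),
      processes = c(list(
        p_enzymatic("Cyp3a11", "MDZ", "OH-MDZ", cl = 0.10),
        p_enzymatic("Ugt", "OH-MDZ", "OH-MDZ-G", cl = 4e-3),
        p_total_clearance("MDZ", cl = 0.04),
        p_total_clearance("OH-MDZ", cl = 0.06),
        p_glomerular_filtration("MDZ", gfr),
        p_glomerular_filtration("OH-MDZ", gfr),
        p_glomerular_filtration("OH-MDZ-G", gfr)
      ), gluc_processes("OH-MDZ-G")),
      name = "midazolam"
    )
  },
  torsemide = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("TRS", 348.42, 0.05, c(kidney = 0.5, rest_of_body = 0.3), 0),
        chem_species("OH-TRS", 364.42, 0.10, c(kidney = 0.5, rest_of_body = 0.5), 0.01)
      ),
      processes = list(
        p_mm_transport("Slco1b2", "TRS", "sinusoidal_in", vmax = 1.0),
        p_enzymatic("Cyp2c29", "TRS", "OH-TRS", cl = 0.01),
        p_total_clearance("TRS", cl = 5e-3),
        p_total_clearance("OH-TRS", cl = 0.01),
        p_glomerular_filtration("TRS", gfr),
        p_glomerular_filtration("OH-TRS", gfr)
      ),
      name = "torsemide"
    )
  },
  pravastatin = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("PRS", 424.53, 0.55, c(kidney = 0.5, rest_of_body = 0.3), 0)
      ),
      processes = list(
        p_mm_transport("Slco1b2", "PRS", "sinusoidal_in", vmax = 2.0),
        p_total_clearance("PRS", cl = 0.01),
        p_biliary_clearance("PRS", cl = 0.02),
        p_glomerular_filtration("PRS", gfr)
      ),
      name = "pravastatin"
    )
  },
  talinolol = function(phys) {
    gfr <- phys$gfr
    model_definition(
      phys,
      species = list(
        chem_species("TAL", 363.49, 0.90, c(kidney = 2, rest_of_body = 3), 0.008)
      ),
      processes = list(
        p_mm_transport("Abcb1a", "TAL", "canalicular", vmax = 1.5),
        p_total_clearance("TAL", cl = 1e-3),
        p_glomerular_filtration("TAL", gfr)
      ),
      name = "talinolol"
    )
  }
)

#' Names of the cocktail drugs
#' @return character vector of the six drug names
#' @export
cocktail_drugs <- function() names(.COCKTAIL_BUILDERS)

#' Reduced PBPK model for one cocktail drug family
#'
#' @param name one of `cocktail_drugs()`
#' @param physiology a [physiology()]; defaults to [mouse_physiology()]
#' @return a [model_definition()] for the family (parent drug plus its
#'   quantified metabolites)
#' @export
get_family_model <- function(name, physiology = mouse_physiology()) {
  if (!is.character(name) || length(name) != 1L || !name %in% cocktail_drugs())
    stop("unknown drug '", paste(name, collapse = ","), "'; valid names: ",
         paste(cocktail_drugs(), collapse = ", "), call. = FALSE)
  .COCKTAIL_BUILDERS[[name]](physiology)
}

#' Metabolic and transporter network of a drug family
#'
#' @param name one of `cocktail_drugs()`
#' @return list with a `metabolism` data frame (substrate, product, gene)
#'   and a `transporters` data frame (species, gene, membrane)
#' @export
cocktail_network <- function(name) {
  m <- get_family_model(name)
  met <- do.call(rbind, lapply(m$processes, function(p)
    if (p$kind == "enzymatic_first_order")
      data.frame(substrate = p$substrate, product = p$product, gene = p$gene,
                 stringsAsFactors = FALSE)))
  tr <- do.call(rbind, lapply(m$processes, function(p)
    if (p$kind == "mm_transport")
      data.frame(species = p$substrate, gene = p$gene, membrane = p$membrane,
                 stringsAsFactors = FALSE)))
  list(metabolism = met, transporters = tr)
}

#' The cocktail dosing scheme
#'
#' Six simultaneous i.v. bolus events at t = 0 into plasma: caffeine
#' 5 mg/kg, codeine 2, midazolam 2, pravastatin 20, talinolol 1, torsemide
#' 2 mg/kg, converted to nmol via [mgkg_to_nmol()] with the configured
#' molecular weights.
#'
#' @param body_weight body weight (kg), > 0
#' @return named list of [dose_event()]s, one per drug (named by drug)
#' @export
default_dose_table <- function(body_weight) {
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body weight must be > 0", call. = FALSE)
  out <- lapply(names(.COCKTAIL_DOSE_MGKG), function(d)
    dose_event(.COCKTAIL_PARENT[[d]],
               mgkg_to_nmol(.COCKTAIL_DOSE_MGKG[[d]], body_weight, .COCKTAIL_MW[[d]]),
               time = 0))
  names(out) <- names(.COCKTAIL_DOSE_MGKG)
  out
}

#' Dose event for a single cocktail drug
#'
#' @param name one of `cocktail_drugs()`
#' @param body_weight body weight (kg)
#' @return a [dose_event()] for the family's parent species at t = 0
#' @export
family_dose <- function(name, body_weight) {
  default_dose_table(body_weight)[[match.arg(name, cocktail_drugs())]]
}
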