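#' Gene-wise transporter scaling map
#'
#' Multipliers applied to transporter capacities when transforming a healthy
#' reference model into its cirrhosis variant, typically derived from
#' RNA-seq fold changes via [derive_scaling_map()]. Provenance records
#' whether a multiplier is a fixed configuration value or computed as
#' 2^log2FC from a differential-expression table.
#'
#' @param multipliers named numeric vector gene -> multiplier (> 0);
#'   may be empty
#' @param provenance named character vector gene -> provenance string
#'   (defaults to "fixed" for every gene)
#' @return an object of class `scaling_map`
#' @export
scaling_map <- function(multipliers = numeric(), provenance = NULL) {
  if (length(multipliers)) {
    if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
      stop("multipliers must be named by gene", call. = FALSE)
    if (anyDuplicated(names(multipliers)))
      stop("a gene appears more than once in the scaling map", call. = FALSE)
    if (any(!is.finite(multipliers)) || any(multipliers <= 0))
      stop("all multipliers must be > 0", call. = FALSE)
  }
  if (is.null(provenance))
    provenance <- stats::setNames(rep("fixed", length(multipliers)), names(multipliers))
  structure(list(multipliers = multipliers, provenance = provenance),
            class = "scaling_map")
}

#' Structural hypothesis for altered glucuronide disposition
#'
#' Three alternative mechanisms for elevated blood glucuronides in
#' cirrhosis: H1 scales UGT conjugation activity, H2 scales the
#' biliary (canalicular) export of glucuronides, H3 scales their
#' sinusoidal (basolateral) export. `theta` is the fold change applied to
#' the matched rate constants.
#'
#' @param id "H1", "H2" or "H3"
#' @param theta fold change, > 0
#' @param bounds positive (lo, hi) search bounds for fitting, lo <= theta <= hi
#' @return an object of class `hypothesis_spec`
#' @export
hypothesis_spec <- function(id, theta = 1, bounds = c(1e-3, 1e3)) {
  id <- match.arg(id, c("H1", "H2", "H3"))
  if (!(bounds[1] > 0) || !(bounds[1] <= theta) || !(theta <= bounds[2]))
    stop("require 0 < lo <= theta <= hi", call. = FALSE)
  structure(list(id = id, theta = as.numeric(theta), bounds = as.numeric(bounds)),
            class = "hypothesis_spec")
}

#' Cirrhosis scenario
#'
#' Bundles the global perturbation rules that turn a healthy reference model
#' into its cirrhotic counterpart: cytochrome-P450 metabolic activity scaled
#' to `cyp_fraction` (default 0.11, i.e. reduced to 11 percent), and
#' transporter capacities scaled gene-wise by a [scaling_map()].
#'
#' @param cyp_fraction fraction of healthy CYP activity retained, in (0, 1]
#' @param scaling a [scaling_map()]
#' @return an object of class `cirrhosis_scenario`
#' @export
cirrhosis_scenario <- function(cyp_fraction = 0.11, scaling = scaling_map()) {
  if (!is.finite(cyp_fraction) || cyp_fraction <= 0 || cyp_fraction > 1)
    stop("cyp_fraction must be in (0, 1]", call. = FALSE)
  stopifnot(inherits(scaling, "scaling_map"))
  structure(list(cyp_fraction = cyp_fraction, scaling = scaling),
            class = "cirrhosis_scenario")
}

#' Transform a healthy model into its cirrhosis variant
#'
#' Every CYP-attributed enzymatic clearance and every lumped
#' total-hepatic clearance is multiplied by `cyp_fraction`; UGT
#' conjugation is left unchanged (so the reference cirrhosis simulation
#' deliberately under-predicts glucuronides, which is what makes the
#' H1/H2/H3 hypotheses meaningful). Transporter capacities whose gene
#' appears in the scaling map are multiplied by their entry; genes in the
#' map but absent from the model produce a warning, not an error. The
#' input model is not mutated.
#'
#' @param model healthy reference [model_definition()]
#' @param scaling a [scaling_map()] for transporter genes
#' @param cyp_fraction fraction of CYP activity retained, in (0, 1]
#' @return a new `model_definition`
#' @export
apply_cirrhosis <- function(model, scaling = scaling_map(), cyp_fraction = 0.11) {
  stopifnot(inherits(model, "model_definition"), inherits(scaling, "scaling_map"))
  if (!is.finite(cyp_fraction) || cyp_fraction <= 0 || cyp_fraction > 1)
    stop("cyp_fraction must be in (0, 1]", call. = FALSE)
  mult <- scaling$multipliers
  genes_in_model <- unique(stats::na.omit(vapply(model$processes, `[[`, "", "gene")))
  missing <- setdiff(names(mult), genes_in_model)
  if (length(missing))
    warning("scaling entries for genes absent from model '", model$name, "': ",
            paste(missing, collapse = ", "), call. = FALSE)
  model$processes <- lapply(model$processes, function(p) {
    if (p$kind == "enzymatic_first_order" && !is.na(p$gene) &&
        startsWith(p$gene, "Cyp")) {
      p$params$cl <- p$params$cl * cyp_fraction
    } else if (p$kind == "total_hepatic_clearance") {
      p$params$cl <- p$params$cl * cyp_fraction
    }
    if (!is.na(p$gene) && p$gene %in% names(mult) &&
        p$kind %in% c("mm_transport", "biliary_clearance")) {
      f <- mult[[p$gene]]
      if (!is.null(p$params$vmax)) p$params$vmax <- p$params$vmax * f
      if (!is.null(p$params$cl)) p$params$cl <- p$params$cl * f
    }
    p
  })
  validate_model(model)
  model
}

hypothesis_matches <- function(model, id) {
  is_gluc <- vapply(model$species, `[[`, TRUE, "is_glucuronide")
  vapply(model$processes, function(p) {
    switch(id,
      H1 = p$kind == "enzymatic_first_order" && identical(p$gene, "Ugt"),
      H2 = (p$kind == "biliary_clearance" ||
              (p$kind == "mm_transport" && identical(p$membrane, "canalicular"))) &&
           isTRUE(is_gluc[[p$substrate]]),
      H3 = p$kind == "mm_transport" && identical(p$membrane, "sinusoidal_out") &&
           isTRUE(is_gluc[[p$substrate]])
    )
  }, TRUE)
}

#' Apply a structural hypothesis to a model
#'
#' Multiplies the rate constants of the processes matched by the hypothesis
#' selector by `spec$theta`: H1 the UGT conjugation clearances, H2 the
#' canalicular/biliary export of glucuronides, H3 their sinusoidal export.
#' Composable with [apply_cirrhosis()] (the two transforms act on disjoint
#' targets and commute). The input model is not mutated.
#'
#' @param model a [model_definition()]
#' @param spec a [hypothesis_spec()]
#' @return a new `model_definition`
#' @export
apply_hypothesis <- function(model, spec) {
  stopifnot(inherits(model, "model_definition"), inherits(spec, "hypothesis_spec"))
  hit <- hypothesis_matches(model, spec$id)
  if (!any(hit))
    stop("hypothesis ", spec$id, " matches no process in model '",
         model$name %||% "<unnamed>", "'", call. = FALSE)
  model$processes[hit] <- lapply(model$processes[hit], function(p) {
    if (!is.null(p$params$vmax)) p$params$vmax <- p$params$vmax * spec$theta
    else p$params$cl <- p$params$cl * spec$theta
    p
  })
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a cirrhosis scenario (and optionally a hypothesis) to a model
#'
#' @param model healthy reference model
#' @param scenario a [cirrhosis_scenario()]
#' @param hypothesis optional [hypothesis_spec()] applied on top
#' @return transformed `model_definition`
#' @export
apply_scenario <- function(model, scenario, hypothesis = NULL) {
  stopifnot(inherits(scenario, "cirrhosis_scenario"))
  out <- apply_cirrhosis(model, scenario$scaling, scenario$cyp_fraction)
  if (!is.null(hypothesis)) out <- apply_hypothesis(out, hypothesis)
  out
}

#' Scale gross physiology for sensitivity sweeps
#'
#' Multiplies named physiology entries; intended for ruling out gross
#' hemodynamic explanations (hepatic blood flow, plasma volume) by
#' sensitivity simulation, not for disease modelling.
#'
#' @param model a [model_definition()]
#' @param knobs named list/vector with any of `liver_blood_flow_fraction`,
#'   `plasma_volume_fraction` (> 0)
#' @return a new `model_definition` with scaled physiology
#' @export
scale_physiology <- function(model, knobs) {
  known <- c("liver_blood_flow_fraction", "plasma_volume_fraction")
  bad <- setdiff(names(knobs), known)
  if (length(bad))
    stop("unknown physiology knob(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "), call. = FALSE)
  if (any(unlist(knobs) <= 0)) stop("knob fractions must be > 0", call. = FALSE)
  phys <- model$physiology
  if (!is.null(knobs$liver_blood_flow_fraction))
    phys$blood_flows[["liver"]] <- phys$blood_flows[["liver"]] *
      knobs$liver_blood_flow_fraction
  if (!is.null(knobs$plasma_volume_fraction))
    phys$compartment_volumes[["plasma"]] <- phys$compartment_volumes[["plasma"]] *
      knobs$plasma_volume_fraction
  model_definition(phys, model$species, model$processes, name = model$name)
}
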