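.MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a model definition to JSON
#'
#' The document carries a `schema_version` field; [read_model_json()]
#' refuses versions it does not know. Round-trips exactly through
#' [model_definition()] validation.
#'
#' @param model a [model_definition()]
#' @param path output file
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "model_definition"))
  doc <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    name = model$name,
    physiology = list(
      body_weight = model$physiology$body_weight,
      compartment_volumes = as.list(model$physiology$compartment_volumes),
      blood_flows = as.list(model$physiology$blood_flows),
      gfr = model$physiology$gfr,
      bile_flow = model$physiology$bile_flow
    ),
    species = lapply(model$species, function(s) list(
      name = s$name, molecular_weight = s$molecular_weight,
      fraction_unbound = s$fraction_unbound, partition = as.list(s$partition),
      passive_exchange_cl = s$passive_exchange_cl,
      is_glucuronide = s$is_glucuronide
    )),
    processes = lapply(model$processes, function(p) {
      out <- list(kind = p$kind, gene = p$gene, substrate = p$substrate,
                  product = p$product, source = p$source, target = p$target,
                  params = p$params)
      if (!is.null(p$membrane)) out$membrane <- p$membrane
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @param path JSON file written by [write_model_json()]
#' @return a validated `model_definition`
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, .MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version: ", doc$schema_version, call. = FALSE)
  phys <- physiology(
    body_weight = doc$physiology$body_weight,
    compartment_volumes = unlist(doc$physiology$compartment_volumes),
    blood_flows = unlist(doc$physiology$blood_flows),
    gfr = doc$physiology$gfr,
    bile_flow = doc$physiology$bile_flow
  )
  species <- lapply(doc$species, function(s)
    chem_species(s$name, s$molecular_weight, s$fraction_unbound,
                 unlist(s$partition), s$passive_exchange_cl,
                 isTRUE(s$is_glucuronide)))
  processes <- lapply(doc$processes, function(p) {
    gene <- if (is.null(p$gene)) NA_character_ else p$gene
    switch(p$kind,
      enzymatic_first_order = p_enzymatic(gene, p$substrate, p$product, p$params$cl),
      total_hepatic_clearance = p_total_clearance(p$substrate, p$params$cl),
      mm_transport = p_mm_transport(gene, p$substrate, p$membrane,
                                    p$params$vmax, p$params$km),
      glomerular_filtration = p_glomerular_filtration(p$substrate, p$params$cl),
      biliary_clearance = p_biliary_clearance(p$substrate, p$params$cl, gene),
      passive_exchange = p_passive_exchange(p$substrate, p$params$cl,
                                            p$source, p$target),
      stop("unknown process kind in document: ", p$kind, call. = FALSE)
    )
  })
  model_definition(phys, species, processes,
                   name = if (is.null(doc$name)) NULL else doc$name)
}
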