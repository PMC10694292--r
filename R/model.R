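.COMPARTMENTS <- c("plasma", "liver_blood", "hepatocyte", "kidney", "rest_of_body",
                   "urine", "bile", "unknown_sink")
.VOLUMETRIC <- c("plasma", "liver_blood", "hepatocyte", "kidney", "rest_of_body")
.SINKS <- c("urine", "bile", "unknown_sink")

#' Compartmental model definition for one drug family
#'
#' Bundles a [physiology()], the chemical species of one drug family
#' (parent first) and the ADME processes connecting them. Three cumulative
#' sinks (urine, bile, unknown_sink) are implicit in every model. Each
#' species is carried in all compartments; metabolites are counted
#' mole-per-mole as parent equivalents, so total moles across compartments
#' and sinks are conserved.
#'
#' @param physiology a [physiology()] object
#' @param species list of [chem_species()] (parent drug first)
#' @param processes list of processes (see [process])
#' @param name optional model label
#' @return an object of class `model_definition`
#' @export
model_definition <- function(physiology, species, processes, name = NULL) {
  stopifnot(inherits(physiology, "physiology"))
  if (!length(species) || !all(vapply(species, inherits, TRUE, "chem_species")))
    stop("species must be a non-empty list of chem_species", call. = FALSE)
  if (!all(vapply(processes, inherits, TRUE, "process")))
    stop("processes must be a list of process objects", call. = FALSE)
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species names: ", paste(sp_names[duplicated(sp_names)], collapse = ", "),
         call. = FALSE)
  names(species) <- sp_names
  m <- structure(
    list(physiology = physiology, species = species, processes = processes,
         name = name),
    class = "model_definition"
  )
  validate_model(m)
  m
}

#' Validate a model definition
#'
#' Checks referential integrity (every process references declared species
#' and compartments), uniqueness of process ids, acyclicity of the
#' substrate-to-product metabolite graph, and the carrier-only membrane rule
#' for glucuronides. Called by [model_definition()]; exported for use after
#' manual edits.
#'
#' @param m a `model_definition`
#' @return `m`, invisibly; otherwise a definition error naming the offender
#' @export
validate_model <- function(m) {
  sp_names <- names(m$species)
  ids <- vapply(m$processes, process_id, "")
  if (anyDuplicated(ids))
    stop("duplicate process ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  edges <- list()
  for (p in m$processes) {
    if (!p$substrate %in% sp_names)
      stop("process ", process_id(p), " references undeclared species '", p$substrate, "'",
           call. = FALSE)
    if (!p$product %in% c(sp_names, "unknown_sink"))
      stop("process ", process_id(p), " references undeclared species '", p$product, "'",
           call. = FALSE)
    if (!p$source %in% .COMPARTMENTS || !p$target %in% .COMPARTMENTS)
      stop("process ", process_id(p), " references an unknown compartment", call. = FALSE)
    if (p$kind %in% c("enzymatic_first_order", "total_hepatic_clearance") &&
        p$source != "hepatocyte")
      stop("process ", process_id(p), " must be located in hepatocyte", call. = FALSE)
    if (p$kind == "glomerular_filtration" &&
        (p$source != "plasma" || p$target != "urine"))
      stop("glomerular_filtration must draw from plasma into urine", call. = FALSE)
    if (p$kind == "enzymatic_first_order")
      edges[[length(edges) + 1L]] <- c(p$substrate, p$product)
  }
  # metabolite graph must be acyclic (depth-limited walk over the edge list)
  if (length(edges)) {
    from <- vapply(edges, `[`, "", 1L)
    to <- vapply(edges, `[`, "", 2L)
    reach <- function(start) {
      seen <- character()
      frontier <- start
      while (length(frontier)) {
        nxt <- to[from %in% frontier]
        nxt <- setdiff(nxt, seen)
        if (start %in% nxt)
          stop("cyclic metabolite graph involving species '", start, "'", call. = FALSE)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
    }
    for (s in unique(from)) reach(s)
  }
  for (sp in m$species)
    if (sp$is_glucuronide && sp$passive_exchange_cl != 0)
      stop("glucuronide species '", sp$name, "' must have passive_exchange_cl = 0",
           call. = FALSE)
  invisible(m)
}

#' Get or set a process rate constant by process id
#'
#' @param m a `model_definition`
#' @param id a [process_id()] string
#' @param field `"cl"` or `"vmax"`
#' @param value new value (> 0 for rate constants under estimation)
#' @return `get_model_param` returns the numeric value; `set_model_param`
#'   returns a modified copy of the model (the input is never mutated)
#' @export
get_model_param <- function(m, id, field = c("cl", "vmax")) {
  field <- match.arg(field)
  i <- match_process(m, id)
  v <- m$processes[[i]]$params[[field]]
  if (is.null(v)) stop("process ", id, " has no parameter '", field, "'", call. = FALSE)
  v
}

#' @rdname get_model_param
#' @export
set_model_param <- function(m, id, field = c("cl", "vmax"), value) {
  field <- match.arg(field)
  if (!is.finite(value) || value < 0) stop("parameter value must be >= 0", call. = FALSE)
  i <- match_process(m, id)
  if (is.null(m$processes[[i]]$params[[field]]))
    stop("process ", id, " has no parameter '", field, "'", call. = FALSE)
  m$processes[[i]]$params[[field]] <- value
  m
}

match_process <- function(m, id) {
  ids <- vapply(m$processes, process_id, "")
  i <- match(id, ids)
  if (is.na(i))
    stop("no process with id '", id, "'; available: ", paste(ids, collapse = "; "),
         call. = FALSE)
  i
}

#' @export
print.model_definition <- function(x, ...) {
  cat("<model_definition>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  species:", paste(names(x$species), collapse = ", "), "\n")
  cat("  processes:\n")
  for (p in x$processes) cat("   -", process_id(p), "\n")
  invisible(x)
}
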