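.PROCESS_KINDS <- c("enzymatic_first_order", "total_hepatic_clearance", "mm_transport",
                    "glomerular_filtration", "biliary_clearance", "passive_exchange")
.MEMBRANES <- c(sinusoidal_in = "liver_blood>hepatocyte",
                sinusoidal_out = "hepatocyte>liver_blood",
                canalicular = "hepatocyte>bile")

#' ADME process definitions
#'
#' A `process` couples a chemical species to a kinetic law. Supported kinds:
#' \describe{
#'   \item{enzymatic_first_order}{hepatocellular metabolism, rate = cl * Cu
#'     (Cu = unbound hepatocyte concentration), substrate -> product}
#'   \item{total_hepatic_clearance}{lumped hepatocellular elimination to
#'     unquantified metabolites, rate = cl * Cu, substrate -> unknown_sink}
#'   \item{mm_transport}{carrier-mediated membrane transport, rate =
#'     vmax * Cu / (km + Cu) with Cu at the source compartment; Km defaults
#'     to 1000 nmol/L (1 umol/L) and is conventionally not fitted}
#'   \item{glomerular_filtration}{renal filtration, plasma -> urine,
#'     rate = cl * fu * C_plasma (cl is the filtration rate, L/min)}
#'   \item{biliary_clearance}{hepatocyte -> bile, rate = cl * Cu}
#'   \item{passive_exchange}{bidirectional diffusion on the unbound gradient
#'     between two compartments, rate = cl * (Cu_source - Cu_target)}
#' }
#'
#' @param gene optional gene label attributing the process (e.g. "Cyp3a11",
#'   "Ugt", "Abcc3", "Slco1b2"); used by the disease-scaling selectors
#' @param substrate,product species names; `product` defaults to the
#'   substrate itself for pure transfer processes
#' @param cl clearance (L/min), >= 0
#' @param vmax maximal transport rate (nmol/min), >= 0
#' @param km Michaelis constant (nmol/L), > 0
#' @param membrane for `mm_transport`: one of "sinusoidal_in",
#'   "sinusoidal_out", "canalicular"
#' @param source,target compartment names for `passive_exchange`
#' @return an object of class `process`
#' @name process
NULL

new_process <- function(kind, substrate, product, source, target, gene = NA_character_,
                        params = list()) {
  kind <- match.arg(kind, .PROCESS_KINDS)
  if (!is.null(params$cl) && (!is.finite(params$cl) || params$cl < 0))
    stop("cl must be >= 0", call. = FALSE)
  if (!is.null(params$vmax) && (!is.finite(params$vmax) || params$vmax < 0))
    stop("vmax must be >= 0", call. = FALSE)
  if (!is.null(params$km) && (!is.finite(params$km) || params$km <= 0))
    stop("km must be > 0", call. = FALSE)
  if (kind == "mm_transport" && identical(source, target))
    stop("mm_transport must have source != target", call. = FALSE)
  structure(
    list(kind = kind, gene = gene, substrate = substrate, product = product,
         source = source, target = target, params = params),
    class = "process"
  )
}

#' @rdname process
#' @export
p_enzymatic <- function(gene, substrate, product, cl) {
  new_process("enzymatic_first_order", substrate, product,
              source = "hepatocyte", target = "hepatocyte",
              gene = gene, params = list(cl = cl))
}

#' @rdname process
#' @export
p_total_clearance <- function(substrate, cl) {
  new_process("total_hepatic_clearance", substrate, "unknown_sink",
              source = "hepatocyte", target = "unknown_sink",
              params = list(cl = cl))
}

#' @rdname process
#' @export
p_mm_transport <- function(gene, substrate, membrane, vmax, km = 1000) {
  membrane <- match.arg(membrane, names(.MEMBRANES))
  ends <- strsplit(.MEMBRANES[[membrane]], ">", fixed = TRUE)[[1L]]
  p <- new_process("mm_transport", substrate, substrate,
                   source = ends[1L], target = ends[2L],
                   gene = gene, params = list(vmax = vmax, km = km))
  p$membrane <- membrane
  p
}

#' @rdname process
#' @export
p_glomerular_filtration <- function(substrate, cl) {
  new_process("glomerular_filtration", substrate, substrate,
              source = "plasma", target = "urine", params = list(cl = cl))
}

#' @rdname process
#' @export
p_biliary_clearance <- function(substrate, cl, gene = NA_character_) {
  new_process("biliary_clearance", substrate, substrate,
              source = "hepatocyte", target = "bile",
              gene = gene, params = list(cl = cl))
}

#' @rdname process
#' @export
p_passive_exchange <- function(substrate, cl, source = "liver_blood", target = "hepatocyte") {
  new_process("passive_exchange", substrate, substrate,
              source = source, target = target, params = list(cl = cl))
}

#' Identifier of a process within a model
#'
#' Deterministic id built from kind, gene, substrate and target compartment;
#' used as the `name` path of [parameter_spec()] and by the scenario
#' selectors. Ids are validated to be unique within a [model_definition()].
#'
#' @param p a `process`
#' @return a string id
#' @export
process_id <- function(p) {
  g <- if (is.na(p$gene)) "" else paste0(p$gene, ".")
  paste0(p$kind, ":", g, p$substrate, ">", p$target)
}

#' @export
print.process <- function(x, ...) {
  pr <- paste(names(x$params), signif(unlist(x$params), 4), sep = "=", collapse = ", ")
  cat(sprintf("<process> %s  [%s]\n", process_id(x), pr))
  invisible(x)
}
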