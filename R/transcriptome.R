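#' Differential-expression table
#'
#' A data frame with columns `gene_symbol`, `log2fc`, `fdr` plus a species
#' tag ("mouse" or "human") carried as an attribute. DE computation itself
#' (read counts to logFC/FDR) is upstream of this package; the module
#' consumes result tables.
#'
#' @param df data frame with gene_symbol, log2fc, fdr
#' @param species "mouse" or "human"
#' @return the validated data frame with attribute `species`
#' @export
de_table <- function(df, species = c("mouse", "human")) {
  species <- match.arg(species)
  req <- c("gene_symbol", "log2fc", "fdr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("DE table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!nzchar(df$gene_symbol))) stop("empty gene symbol", call. = FALSE)
  if (anyDuplicated(df$gene_symbol))
    stop("gene symbols must be unique per table", call. = FALSE)
  if (any(df$fdr < 0 | df$fdr > 1)) stop("fdr must lie in [0, 1]", call. = FALSE)
  attr(df, "species") <- species
  df
}

de_species <- function(table) {
  sp <- attr(table, "species")
  if (is.null(sp)) stop("DE table lacks a species tag; use de_table()", call. = FALSE)
  sp
}

#' Flag differentially expressed genes
#'
#' Species-specific inclusive thresholds: a mouse gene is differentially
#' expressed if |log2FC| >= 1 and FDR <= 0.05; a human gene under the more
#' relaxed |log2FC| >= log2(1.5) and FDR <= 0.2.
#'
#' @param table a [de_table()]
#' @return the table with a logical `de` column (idempotent)
#' @export
flag_de <- function(table) {
  sp <- de_species(table)
  th <- switch(sp,
    mouse = c(lfc = 1, fdr = 0.05),
    human = c(lfc = log2(1.5), fdr = 0.2)
  )
  table$de <- abs(table$log2fc) >= th[["lfc"]] & table$fdr <= th[["fdr"]]
  table
}

#' Ortholog mapping table
#'
#' @param df data frame with columns `human_symbol`, `mouse_symbol`;
#'   many human genes may map to one mouse gene, but no human gene may map
#'   to two mouse genes
#' @return the validated data frame of class kept as plain data.frame
#' @export
ortholog_map <- function(df) {
  req <- c("human_symbol", "mouse_symbol")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("ortholog map lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- unique(df[, req])
  if (anyDuplicated(dup$human_symbol))
    stop("a human symbol maps to two mouse symbols", call. = FALSE)
  dup
}

#' Collapse a human DE table onto mouse symbols
#'
#' Human rows are re-keyed to their ortholog mouse symbols. When several
#' human genes map to one mouse gene, the collapsed log2FC is the
#' arithmetic mean of the human log2FCs; the FDR is combined as the
#' minimum (a package convention: the collapsed gene is at least as
#' significant as its best-supported member). Unmapped rows are dropped and
#' counted.
#'
#' @param human a human [de_table()]
#' @param map an [ortholog_map()]
#' @return a mouse-symbol [de_table()] (species "human": the values are
#'   still human measurements) with attribute `n_dropped`
#' @export
collapse_orthologs <- function(human, map) {
  if (de_species(human) != "human")
    stop("collapse_orthologs expects a human DE table", call. = FALSE)
  map <- ortholog_map(map)
  if (!nrow(map)) stop("empty ortholog map", call. = FALSE)
  idx <- match(human$gene_symbol, map$human_symbol)
  dropped <- sum(is.na(idx))
  kept <- human[!is.na(idx), , drop = FALSE]
  kept$mouse_symbol <- map$mouse_symbol[idx[!is.na(idx)]]
  lfc <- tapply(kept$log2fc, kept$mouse_symbol, mean)
  fdr <- tapply(kept$fdr, kept$mouse_symbol, min)
  out <- data.frame(gene_symbol = names(lfc), log2fc = as.numeric(lfc),
                    fdr = as.numeric(fdr), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- de_table(out, "human")
  attr(out, "n_dropped") <- dropped
  out
}

#' Cross-species log-fold-change correlation
#'
#' Pearson correlation of mouse and (ortholog-collapsed) human log2FC over
#' the genes shared by both tables, optionally restricted to a gene family.
#' The two-sided p-value comes from the t transform of r.
#'
#' @param mouse a mouse [de_table()]
#' @param human_collapsed a mouse-symbol-keyed human table
#'   (see [collapse_orthologs()])
#' @param gene_set optional character vector restricting the pairs
#' @return list with elements `r`, `n`, `p`
#' @export
correlate_logfc <- function(mouse, human_collapsed, gene_set = NULL) {
  shared <- intersect(mouse$gene_symbol, human_collapsed$gene_symbol)
  if (!is.null(gene_set)) shared <- intersect(shared, gene_set)
  if (length(shared) < 3L)
    stop("need at least 3 shared genes; got ", length(shared), call. = FALSE)
  x <- mouse$log2fc[match(shared, mouse$gene_symbol)]
  y <- human_collapsed$log2fc[match(shared, human_collapsed$gene_symbol)]
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(shared), p = ct$p.value)
}

#' Derive a transporter scaling map from mouse DE results
#'
#' For each requested gene the multiplier is 2^log2FC if the gene passes
#' the mouse DE thresholds, else 1.0 (the significance gate is a package
#' convention for robustness; provenance records which rule produced each
#' multiplier). Genes absent from the table get multiplier 1.0 with a
#' warning.
#'
#' @param mouse a mouse [de_table()]
#' @param genes non-empty character vector of transporter genes
#' @return a [scaling_map()]
#' @export
derive_scaling_map <- function(mouse, genes) {
  if (!length(genes)) stop("genes must be non-empty", call. = FALSE)
  flagged <- flag_de(mouse)
  mult <- stats::setNames(rep(1, length(genes)), genes)
  prov <- stats::setNames(rep("fixed", length(genes)), genes)
  absent <- setdiff(genes, flagged$gene_symbol)
  if (length(absent))
    warning("genes absent from DE table get multiplier 1: ",
            paste(absent, collapse = ", "), call. = FALSE)
  for (g in intersect(genes, flagged$gene_symbol)) {
    row <- flagged[flagged$gene_symbol == g, ]
    if (isTRUE(row$de)) {
      mult[[g]] <- 2^row$log2fc
      prov[[g]] <- sprintf("from_log2fc(%g)", row$log2fc)
    } else {
      prov[[g]] <- "not_de"
    }
  }
  scaling_map(mult, prov)
}

#' Read a DE table or ortholog map from delimited text
#'
#' Expected headers: `gene_symbol`, `log2fc`, `fdr` for DE tables;
#' `human_symbol`, `mouse_symbol` for ortholog maps. Tab- or
#' comma-delimited (autodetected by extension: .csv uses comma).
#'
#' @param path file path
#' @param species species tag for the DE table
#' @return validated table
#' @export
read_de_table <- function(path, species = c("mouse", "human")) {
  reader <- if (grepl("\\.csv$", path)) utils::read.csv else utils::read.delim
  de_table(reader(path, stringsAsFactors = FALSE), match.arg(species))
}

#' @rdname read_de_table
#' @export
read_ortholog_map <- function(path) {
  reader <- if (grepl("\\.csv$", path)) utils::read.csv else utils::read.delim
  ortholog_map(reader(path, stringsAsFactors = FALSE))
}
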