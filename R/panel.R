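#' Define a sequencing panel
#'
#' A panel is the set of genes whose coding exons are captured, together
#' with the total coding territory in megabases used to normalize mutation
#' counts. Regions, when supplied, are 1-based inclusive intervals.
#'
#' @param name panel name.
#' @param genes character vector of gene symbols targeted by the panel.
#' @param coding_mb total coding territory in megabases (> 0).
#' @param regions optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return an object of class `panel_definition`.
#' @export
panel_definition <- function(name, genes, coding_mb, regions = NULL) {
  if (!is.numeric(coding_mb) || length(coding_mb) != 1L || coding_mb <= 0)
    stop("coding_mb must be a single positive number", call. = FALSE)
  genes <- unique(as.character(genes))
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
    if (any(regions$end < regions$start))
      stop("regions must have end >= start (1-based inclusive)", call. = FALSE)
  }
  structure(list(name = name, genes = genes, coding_mb = coding_mb,
                 regions = regions),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("panel '%s': %d genes, %.3g Mb coding territory\n",
              x$name, length(x$genes), x$coding_mb))
  invisible(x)
}

# Mismatch repair and polymerase genes plus common cancer genes; the rest
# of the 315-gene panel is filled with synthetic symbols.
.core_genes <- c(
  "MLH1", "MSH2", "MSH6", "PMS2", "POLE", "POLD1", "TP53", "BRAF", "KRAS",
  "NRAS", "EGFR", "PIK3CA", "PTEN", "APC", "RB1", "CDKN2A", "ATM", "BRCA1",
  "BRCA2", "ARID1A", "KMT2D", "NF1", "SMAD4", "STK11", "VHL", "IDH1",
  "CTNNB1", "FBXW7", "NOTCH1", "ERBB2"
)

# Genes treated as tumor suppressors for the truncation filter.
.ts_genes <- c("MLH1", "MSH2", "MSH6", "PMS2", "TP53", "PTEN", "APC", "RB1",
               "CDKN2A", "ATM", "BRCA1", "BRCA2", "ARID1A", "NF1", "SMAD4",
               "STK11", "VHL", "FBXW7")

#' Default 315-gene, 1.1 Mb comprehensive profiling panel
#'
#' Emulates a hybrid-capture comprehensive genomic profiling assay
#' targeting 315 cancer genes with 1.1 Mb of coding territory inside a
#' 38 Mb exome. Gene territories (used by the synthetic generator to
#' place mutations) are deterministic and sum to `coding_mb`.
#'
#' @param n_genes number of genes (default 315).
#' @param coding_mb coding territory in Mb (default 1.1).
#' @return a `panel_definition` with a `gene_mb` attribute (named numeric
#'   vector of per-gene coding megabases) and a `ts_genes` attribute.
#' @export
default_panel <- function(n_genes = 315L, coding_mb = 1.1) {
  extra <- n_genes - length(.core_genes)
  genes <- c(.core_genes,
             if (extra > 0) sprintf("PANG%03d", seq_len(extra)))
  genes <- genes[seq_len(n_genes)]
  # deterministic uneven territories: long tail of gene sizes
  w <- 0.5 + (seq_len(n_genes) %% 7) + ((seq_len(n_genes) * 13) %% 11) / 4
  gene_mb <- coding_mb * w / sum(w)
  names(gene_mb) <- genes
  p <- panel_definition("cgp315", genes, coding_mb)
  attr(p, "gene_mb") <- gene_mb
  attr(p, "ts_genes") <- intersect(.ts_genes, genes)
  p
}

#' Whole-exome "panel" (38 Mb)
#'
#' @param coding_mb exome coding size estimate in Mb (default 38).
#' @return a `panel_definition` with `genes = NULL` meaning "all genes".
#' @export
exome_panel <- function(coding_mb = 38) {
  p <- panel_definition("exome", character(0), coding_mb)
  p$genes <- NULL   # NULL genes = no gene restriction
  p
}
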