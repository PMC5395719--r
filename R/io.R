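#' @name cli_io
#' @title File formats
#' @description
#' Tab-separated tables (UTF-8, `#` comments, header row required) for
#' variants (MAF-like), specimens, MSI profiles and results; BED (0-based
#' half-open, converted to 1-based inclusive on read) plus a gene list for
#' panels; JSON for ground truth and run manifests; VCF v4.2 export/import
#' of variant calls (one file per specimen, annotation flags in INFO).
#' Numeric fields are serialized at full precision so write-then-read
#' round-trips exactly.
NULL

.fwrite_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.fread_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       na.strings = "NA"))
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss))
      stop(path, " missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  x
}

#' Read variant calls from MAF-like TSV or VCF
#'
#' @param path input file.
#' @param format `"maf_tsv"` (tab-separated with header) or `"vcf"`
#'   (v4.2; annotation flags read from INFO keys written by
#'   [write_variants_vcf()]; unknown flags default to FALSE).
#' @param specimen_id specimen id for VCF input (default: file name
#'   without extension).
#' @return a validated variant-call table.
#' @export
read_variants <- function(path, format = c("maf_tsv", "vcf"),
                          specimen_id = NULL) {
  format <- match.arg(format)
  if (format == "maf_tsv") {
    v <- .fread_tsv(path, required = c("specimen_id", "chrom", "pos",
                                       "ref", "alt", "gene", "effect",
                                       "coding"))
    bad <- which(v$pos < 1)
    if (length(bad))
      stop(path, ": pos < 1 at data row(s) ",
           paste(head(bad, 5), collapse = ", "),
           " (coordinates are 1-based)", call. = FALSE)
    return(validate_variants(v))
  }
  .read_vcf_variants(path, specimen_id)
}

.vcf_info_keys <- data.frame(
  key = c("GENE", "EFFECT", "CODING", "KSH", "TST", "DBSNP", "POPC",
          "RECG", "ZYG", "VAF", "HPLEN"),
  col = c("gene", "effect", "coding", "known_somatic_hotspot",
          "ts_truncation", "dbsnp", "population_count",
          "recurrent_germline", "zygosity_call", "allele_fraction",
          "homopolymer_len"),
  type = c("s", "s", "f", "f", "f", "f", "i", "f", "s", "n", "i"),
  stringsAsFactors = FALSE)

#' Write variant calls as VCF v4.2 (one file per specimen)
#'
#' Annotation flags are stored as INFO keys (GENE, EFFECT, CODING, KSH,
#' TST, DBSNP, POPC, RECG, ZYG, VAF, HPLEN). Returns the written paths.
#'
#' @param variants variant-call table.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, one per specimen.
#' @export
write_variants_vcf <- function(variants, dir) {
  variants <- validate_variants(variants)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- .vcf_info_keys
  paths <- vapply(split(variants, variants$specimen_id), function(v) {
    sid <- v$specimen_id[1]
    path <- file.path(dir, paste0(sid, ".vcf"))
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##tmbscape_specimen=%s", sid),
             sprintf(paste0("##INFO=<ID=%s,Number=%s,Type=%s,",
                            "Description=\"%s\">"),
                     ks$key, ifelse(ks$type == "f", "0", "1"),
                     c(s = "String", f = "Flag", i = "Integer",
                       n = "Float")[ks$type], ks$col),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- vapply(seq_len(nrow(v)), function(i) {
      parts <- character(0)
      for (j in seq_len(nrow(ks))) {
        val <- v[[ks$col[j]]][i]
        parts <- c(parts, switch(ks$type[j],
          f = if (isTRUE(val)) ks$key[j] else NULL,
          s = sprintf("%s=%s", ks$key[j], val),
          i = sprintf("%s=%d", ks$key[j], as.integer(val)),
          n = if (is.na(val)) NULL
              else sprintf("%s=%s", ks$key[j], format(val, digits = 17))))
      }
      paste(parts, collapse = ";")
    }, "")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                    v$chrom, v$pos, v$ref, v$alt, info)
    writeLines(c(hdr, body), path)
    path
  }, "")
  unname(paths)
}

.read_vcf_variants <- function(path, specimen_id = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##fileformat=VCF", lines[1]))
    stop(path, ": not a VCF file", call. = FALSE)
  spec_line <- grep("^##tmbscape_specimen=", lines, value = TRUE)
  if (is.null(specimen_id))
    specimen_id <- if (length(spec_line))
      sub("^##tmbscape_specimen=", "", spec_line[1])
    else sub("\\.vcf$", "", basename(path))
  body <- lines[!startsWith(lines, "#")]
  empty <- validate_variants(data.frame(
    specimen_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), gene = character(0),
    effect = character(0), coding = logical(0), stringsAsFactors = FALSE))
  if (!length(body)) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(f, length, 0L)
  if (any(nf < 8))
    stop(path, ": malformed VCF record at line ",
         which(!startsWith(lines, "#"))[which(nf < 8)[1]], call. = FALSE)
  ks <- .vcf_info_keys
  info <- lapply(f, function(x) strsplit(x[8], ";", fixed = TRUE)[[1]])
  get_kv <- function(items, key) {
    hit <- grep(paste0("^", key, "="), items, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA
  }
  v <- data.frame(
    specimen_id = specimen_id,
    chrom = vapply(f, `[`, "", 1L),
    pos = as.integer(vapply(f, `[`, "", 2L)),
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L),
    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(ks))) {
    key <- ks$key[j]; col <- ks$col[j]
    v[[col]] <- switch(ks$type[j],
      f = vapply(info, function(it) key %in% it, TRUE),
      s = vapply(info, get_kv, "", key),
      i = as.integer(vapply(info, get_kv, "", key)),
      n = as.numeric(vapply(info, get_kv, "", key)))
  }
  v$coding <- vapply(info, function(it) "CODING" %in% it, TRUE)
  v$gene[is.na(v$gene)] <- "."
  v$effect[is.na(v$effect)] <- "noncoding"
  v$zygosity_call[is.na(v$zygosity_call)] <- "uncalled"
  v$population_count[is.na(v$population_count)] <- 0L
  v$homopolymer_len[is.na(v$homopolymer_len)] <- 0L
  validate_variants(v)
}

#' Read a panel from BED plus a gene-territory list
#'
#' @param bed_path BED file (0-based half-open; converted to 1-based
#'   inclusive).
#' @param genes_path TSV with columns `gene`, `coding_mb` (per-gene coding
#'   megabases).
#' @param name panel name.
#' @return a [panel_definition()]; total `coding_mb` is the sum of the
#'   per-gene territories, kept in the `gene_mb` attribute.
#' @export
read_panel <- function(bed_path, genes_path, name = "panel") {
  genes <- .fread_tsv(genes_path, required = c("gene", "coding_mb"))
  regions <- NULL
  if (!is.null(bed_path)) {
    bed <- as.data.frame(data.table::fread(bed_path, header = FALSE,
                                           sep = "\t"))
    regions <- data.frame(chrom = bed[[1]], start = bed[[2]] + 1L,
                          end = bed[[3]], stringsAsFactors = FALSE)
  }
  p <- panel_definition(name, genes$gene, sum(genes$coding_mb), regions)
  attr(p, "gene_mb") <- setNames(genes$coding_mb, genes$gene)
  p
}

#' @rdname cli_io
#' @param specimens,variants,profiles tables to write.
#' @param path file path.
#' @export
write_specimens <- function(specimens, path) .fwrite_tsv(specimens, path)

#' @rdname cli_io
#' @export
read_specimens <- function(path)
  .fread_tsv(path, required = c("specimen_id"))

#' @rdname cli_io
#' @export
write_variants <- function(variants, path)
  .fwrite_tsv(validate_variants(variants), path)

#' @rdname cli_io
#' @export
write_msi_profiles <- function(profiles, path) .fwrite_tsv(profiles, path)

#' @rdname cli_io
#' @export
read_msi_profiles <- function(path)
  .fread_tsv(path, required = c("specimen_id", "locus_id",
                                "repeat_length"))

#' @rdname cli_io
#' @param ground_truth ground-truth list from [generate_cohort()].
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname cli_io
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$specimens <- as.data.frame(gt$specimens, stringsAsFactors = FALSE)
  if (!is.null(gt$variant_origin))
    gt$variant_origin <- as.data.frame(gt$variant_origin,
                                       stringsAsFactors = FALSE)
  gt
}
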