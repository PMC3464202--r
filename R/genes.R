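#' Read gene models from BED or GFF3
#'
#' BED input is taken as BED4 (name column = gene id); GFF3 input is
#' filtered to `gene` features and the id taken from the `Name`, `ID` or
#' `gene_id` attribute, in that order. Coordinates are normalised to the
#' internal 0-based half-open convention and records sorted by
#' (chrom, start). Strand is recorded but plays no part in interval
#' overlap.
#'
#' @param path BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  d <- as.data.frame(gr)
  if (format == "gff3") {
    d <- d[d$type == "gene", , drop = FALSE]
    id <- d$Name
    if (is.null(id)) id <- rep(NA_character_, nrow(d))
    if ("ID" %in% names(d)) id <- ifelse(is.na(id), d$ID, id)
    if ("gene_id" %in% names(d)) id <- ifelse(is.na(id), d$gene_id, id)
    d$name <- id
  }
  if (!nrow(d)) stop("no gene records in ", path)
  out <- data.frame(gene_id = as.character(d$name),
                    chrom = as.character(d$seqnames),
                    start = d$start - 1,   # GRanges is 1-based inclusive
                    end = as.numeric(d$end),
                    strand = as.character(d$strand),
                    stringsAsFactors = FALSE)
  bad <- out$end <= out$start
  if (any(bad)) stop("end <= start for gene record ",
                     paste(out$gene_id[bad], collapse = ", "))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write gene models as BED4
#'
#' @param genes Data frame as returned by [read_gene_models()].
#' @param path Output file.
#' @export
write_gene_models <- function(genes, path) {
  writeLines(paste(genes$chrom,
                   format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene_id, sep = "\t"), path)
  invisible(path)
}

## Gene ids overlapping (>= 1 bp of gene body) any of a set of 0-based
## half-open intervals on one chromosome.
genes_in_intervals <- function(genes, chrom, starts, ends) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g) || !length(starts)) return(character(0))
  hit <- logical(nrow(g))
  for (i in seq_along(starts)) {
    hit <- hit | (g$start < ends[i] & starts[i] < g$end)
  }
  unique(g$gene_id[hit])
}
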