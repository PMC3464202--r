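#' QTL table
#'
#' QTLs are kept as a data frame with columns `qtl_id`, `phenotype`,
#' `chrom`, `ci_start`, `ci_end` (the 95% confidence interval, stored
#' 0-based half-open) and `peak_logP`. On disk the TSV dialect
#' (`# `-prefixed header) carries 1-based inclusive coordinates, the
#' usual convention for published QTL tables.
#'
#' @param qtl_id,phenotype,chrom Character vectors.
#' @param ci_start,ci_end Numeric, 0-based half-open CI bounds in bp.
#' @param peak_logP Numeric peak association score (-log10 p).
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   to check that CIs lie within chromosome bounds.
#' @return A `data.frame` of class `qtl_table`.
#' @export
qtl_table <- function(qtl_id, phenotype, chrom, ci_start, ci_end,
                      peak_logP = NA_real_, chrom_lengths = NULL) {
  q <- data.frame(qtl_id = as.character(qtl_id),
                  phenotype = as.character(phenotype),
                  chrom = as.character(chrom),
                  ci_start = as.numeric(ci_start),
                  ci_end = as.numeric(ci_end),
                  peak_logP = as.numeric(peak_logP),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(q$qtl_id)) stop("duplicated qtl_id")
  bad <- q$ci_start >= q$ci_end
  if (any(bad)) stop("ci_start >= ci_end for QTL ",
                     paste(q$qtl_id[bad], collapse = ", "))
  if (any(q$ci_start < 0)) stop("negative ci_start")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[q$chrom]
    if (anyNA(len)) stop("QTL on unknown chromosome: ",
                         paste(unique(q$chrom[is.na(len)]), collapse = ", "))
    out <- q$ci_end > len
    if (any(out)) stop("CI beyond chromosome end for QTL ",
                       paste(q$qtl_id[out], collapse = ", "))
  }
  class(q) <- c("qtl_table", "data.frame")
  q
}

#' Read / write QTL tables
#'
#' @param path TSV file; columns `qtl_id phenotype chrom ci_start ci_end
#'   peak_logP`, coordinates 1-based inclusive.
#' @param chrom_lengths Passed to [qtl_table()].
#' @return `read_qtl_table`: a `qtl_table`.
#' @export
read_qtl_table <- function(path, chrom_lengths = NULL) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("qtl_id", "phenotype", "chrom",
                                       "ci_start", "ci_end", "peak_logP"))
  qtl_table(d$qtl_id, d$phenotype, d$chrom,
            d$ci_start - 1, d$ci_end, d$peak_logP, chrom_lengths)
}

#' @param qtls A `qtl_table`.
#' @rdname read_qtl_table
#' @export
write_qtl_table <- function(qtls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#qtl_id\tphenotype\tchrom\tci_start\tci_end\tpeak_logP", con)
  writeLines(paste(qtls$qtl_id, qtls$phenotype, qtls$chrom,
                   format(qtls$ci_start + 1, scientific = FALSE, trim = TRUE),
                   format(qtls$ci_end, scientific = FALSE, trim = TRUE),
                   qtls$peak_logP, sep = "\t"), con)
  invisible(path)
}

#' De-duplicate overlapping QTLs across traits
#'
#' QTLs mapped for different measures of the same construct often
#' coincide; for downstream enrichment each genomic locus should be
#' counted once. Within each connected component of the interval-overlap
#' graph (per chromosome) only the QTL with the smallest 95% confidence
#' interval is retained. `method = "greedy"` instead accepts QTLs in
#' order of increasing CI width, skipping any that overlap an already
#' accepted QTL (so non-adjacent members of a chain can both survive).
#' Ties are broken by smaller `ci_start`, then lexically by `qtl_id`.
#'
#' @param qtls A `qtl_table`.
#' @param method `"component"` (default) or `"greedy"`.
#' @return A `qtl_table` whose intervals are pairwise non-overlapping
#'   per chromosome.
#' @export
dedupe_qtls <- function(qtls, method = c("component", "greedy")) {
  method <- match.arg(method)
  keep <- logical(nrow(qtls))
  for (cc in unique(qtls$chrom)) {
    idx <- which(qtls$chrom == cc)
    q <- qtls[idx, ]
    if (method == "component") {
      o <- order(q$ci_start, q$ci_end)
      comp <- integer(length(o))
      cur <- 0L
      run_end <- -Inf
      for (j in seq_along(o)) {
        i <- o[j]
        if (q$ci_start[i] >= run_end) cur <- cur + 1L
        comp[i] <- cur
        run_end <- max(run_end, q$ci_end[i])
      }
      for (g in unique(comp)) {
        m <- which(comp == g)
        w <- q$ci_end[m] - q$ci_start[m]
        best <- m[order(w, q$ci_start[m], q$qtl_id[m])][1]
        keep[idx[best]] <- TRUE
      }
    } else {
      w <- q$ci_end - q$ci_start
      o <- order(w, q$ci_start, q$qtl_id)
      acc <- integer(0)
      for (i in o) {
        ov <- any(q$ci_start[acc] < q$ci_end[i] &
                    q$ci_start[i] < q$ci_end[acc])
        if (!ov) {
          acc <- c(acc, i)
          keep[idx[i]] <- TRUE
        }
      }
    }
  }
  out <- qtls[keep, , drop = FALSE]
  out[order(out$chrom, out$ci_start), , drop = FALSE]
}
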