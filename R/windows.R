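#' Tile chromosomes into G+C windows and bin them into GC deciles
#'
#' Chromosomes are divided into fixed-size windows (default 1 Mb; the
#' last window of a chromosome may be truncated) and each window is
#' assigned to one of `n_bins` equally populated genome-wide %G+C bins.
#' Bins are formed from the ranks of the window GC fractions, so with
#' distinct GC values every bin holds `n/n_bins` windows (within one)
#' and bin membership is a monotone function of GC. Degenerate GC
#' distributions (heavy ties) leave bins empty and trigger a warning.
#'
#' @param sequence_source Either a FASTA path (GC computed from
#'   sequence), a TSV path with columns `chrom start end gc`
#'   (0-based half-open, `#` headers allowed), or a data frame of the
#'   same shape.
#' @param window_size Window size in bp (default 1e6).
#' @param n_bins Number of GC bins (default 10).
#' @return A `data.frame` of class `window_table`: `chrom`, `start`,
#'   `end` (0-based half-open), `gc_fraction`, `gc_bin` (0-based).
#' @export
compute_gc_windows <- function(sequence_source, window_size = 1e6,
                               n_bins = 10) {
  from_fasta <- is.character(sequence_source) &&
    length(sequence_source) == 1L &&
    grepl("\\.(fa|fasta|fna)(\\.gz)?$", sequence_source,
          ignore.case = TRUE)
  if (from_fasta) {
    w <- gc_windows_from_fasta(sequence_source, window_size)
  } else if (is.data.frame(sequence_source)) {
    w <- sequence_source
  } else {
    w <- utils::read.table(sequence_source, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gc"))
  }
  w <- data.frame(chrom = as.character(w$chrom), start = as.numeric(w$start),
                  end = as.numeric(w$end), gc_fraction = as.numeric(w$gc),
                  stringsAsFactors = FALSE)
  if (any(w$gc_fraction < 0 | w$gc_fraction > 1)) {
    stop("gc fractions must lie in [0, 1]")
  }
  ## precomputed tables carry their own window size
  if (!from_fasta) window_size <- min(window_size, max(w$end - w$start))
  short <- tapply(w$end - w$start, w$chrom, max) < window_size
  if (any(short)) {
    warning("chromosome(s) shorter than one window: ",
            paste(names(short)[short], collapse = ", "))
  }
  n <- nrow(w)
  r <- rank(w$gc_fraction, ties.method = "min")
  w$gc_bin <- as.integer(pmin(floor((r - 1) * n_bins / n), n_bins - 1L))
  if (length(unique(w$gc_bin)) < n_bins && n >= n_bins) {
    warning("degenerate GC distribution: ",
            n_bins - length(unique(w$gc_bin)), " empty GC bin(s)")
  }
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  rownames(w) <- NULL
  class(w) <- c("window_table", "data.frame")
  w
}

gc_windows_from_fasta <- function(path, window_size) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    len <- Biostrings::width(seqs)[i]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    v <- Biostrings::Views(seqs[[i]], start = starts + 1, end = ends)
    gc_n <- Biostrings::letterFrequency(v, letters = "GC")
    acgt_n <- Biostrings::letterFrequency(v, letters = "ACGT")
    data.frame(chrom = names(seqs)[i], start = starts, end = ends,
               gc = as.numeric(gc_n) / pmax(as.numeric(acgt_n), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname compute_gc_windows
#' @param windows A `window_table`.
#' @param path Output TSV.
#' @export
write_gc_windows <- function(windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tgc", con)
  writeLines(paste(windows$chrom,
                   format(windows$start, scientific = FALSE, trim = TRUE),
                   format(windows$end, scientific = FALSE, trim = TRUE),
                   sprintf("%.17g", windows$gc_fraction), sep = "\t"), con)
  invisible(path)
}

## chromosome lengths implied by a window tiling
window_chrom_lengths <- function(windows) {
  tapply(windows$end, windows$chrom, max)
}
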