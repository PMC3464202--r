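#' Strain distribution pattern (SDP) matrix
#'
#' An `sdp_matrix` holds the biallelic variants of one chromosome as an
#' M x K binary matrix over the K founder strains of a multi-parent
#' population: entry 0 is the reference-like allele, 1 the alternate.
#' Each row is a variant's strain distribution pattern (SDP).
#'
#' @param chrom Chromosome identifier (length-1 character).
#' @param positions Integer vector of 1-based bp positions, strictly
#'   increasing.
#' @param alleles M x K matrix of 0/1 alleles, rows aligned with
#'   `positions`.
#' @param strain_names Character vector of K founder strain names, in the
#'   fixed founder order used throughout an analysis.
#' @return An object of class `sdp_matrix`.
#' @export
sdp_matrix <- function(chrom, positions, alleles, strain_names = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(strain_names)) {
    strain_names <- paste0("founder", seq_len(ncol(alleles)))
  }
  if (length(chrom) != 1L) stop("'chrom' must be a single chromosome id")
  if (ncol(alleles) < 2L) stop("an SDP matrix needs K >= 2 founder strains")
  if (length(strain_names) != ncol(alleles)) {
    stop("length(strain_names) must equal ncol(alleles)")
  }
  if (length(positions) != nrow(alleles)) {
    stop("length(positions) must equal nrow(alleles)")
  }
  if (nrow(alleles) > 0L) {
    if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
    o <- order(positions)
    positions <- as.numeric(positions[o])
    alleles <- alleles[o, , drop = FALSE]
    if (anyDuplicated(positions)) {
      stop("duplicated variant position: ",
           positions[anyDuplicated(positions)])
    }
    seg <- rowSums(alleles) %% ncol(alleles) != 0L
    if (!all(seg)) stop("non-segregating SDP row(s): ",
                        paste(which(!seg), collapse = ", "))
  } else {
    positions <- numeric(0)
  }
  structure(
    list(chrom = chrom, positions = positions, alleles = alleles,
         strain_names = strain_names),
    class = "sdp_matrix"
  )
}

#' @exportS3Method base::print
print.sdp_matrix <- function(x, ...) {
  cat(sprintf("sdp_matrix: %d variants x %d strains on %s\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom))
  if (length(x$positions)) {
    cat(sprintf("  positions %s..%s\n",
                format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ",")))
  }
  cat("  strains:", paste(x$strain_names, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::dim
dim.sdp_matrix <- function(x) dim(x$alleles)

sdp_strings <- function(sdp) {
  apply(sdp$alleles, 1L, paste, collapse = "")
}

## Restrict an sdp_matrix to a 0-based half-open bp window.
sdp_window <- function(sdp, start, end) {
  keep <- sdp$positions > start & sdp$positions <= end  # 1-based points
  sdp_matrix(sdp$chrom, sdp$positions[keep],
             sdp$alleles[keep, , drop = FALSE], sdp$strain_names)
}

#' Read founder SDPs from a TSV or VCF file
#'
#' The TSV dialect has comment/header lines starting with `#` and three
#' columns `chrom pos allele_string`, where `pos` is 1-based and
#' `allele_string` is K characters of `0`/`1` (one per founder strain, in
#' fixed order). A `#strains: a,b,c` header line names the strains.
#' For VCF input the K founder sample columns must carry homozygous
#' genotypes: heterozygous or missing calls are treated as missing and
#' the variant is dropped (with a message reporting the count), as are
#' multi-allelic and non-segregating records.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param strain_names Optional founder names overriding any in the file.
#' @return A single `sdp_matrix` if the file holds one chromosome,
#'   otherwise a named list of `sdp_matrix`, one per chromosome.
#' @export
read_sdp_table <- function(path, format = c("auto", "tsv", "vcf"),
                           strain_names = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    return(read_sdp_vcf(path, strain_names))
  }
  lines <- readLines(path)
  strains <- strain_names
  hdr <- grep("^#strains:", lines, value = TRUE)
  if (is.null(strains) && length(hdr)) {
    strains <- strsplit(sub("^#strains:\\s*", "", hdr[1]), ",")[[1]]
    strains <- trimws(strains)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop("no SDP records in ", path)
  parts <- strsplit(body, "\t")
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed SDP line ", which(nf != 3L)[1], ": expected 3 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos)) stop("malformed position on line ", which(is.na(pos))[1])
  sdps <- vapply(parts, `[[`, "", 3L)
  K <- nchar(sdps[1])
  if (any(nchar(sdps) != K)) {
    stop("malformed allele string on line ", which(nchar(sdps) != K)[1],
         ": all SDP strings must have equal length")
  }
  bad <- grepl("[^01]", sdps)
  if (any(bad)) {
    stop("malformed allele code on line ", which(bad)[1],
         ": allele strings must be 0/1")
  }
  alle <- matrix(as.integer(unlist(strsplit(sdps, ""))),
                 ncol = K, byrow = TRUE)
  nonseg <- rowSums(alle) %% K == 0L
  if (any(nonseg)) {
    message(sum(nonseg), " non-segregating variant(s) dropped")
  }
  keep <- !nonseg
  build_sdp_set(chrom[keep], pos[keep], alle[keep, , drop = FALSE], strains)
}

read_sdp_vcf <- function(path, strain_names = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(gt)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) message(sum(multi), " multi-allelic record(s) dropped")
  code <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(g %in% c("0/0", "0"), 0L, ifelse(g %in% c("1/1", "1"), 1L, NA))
  }
  alle <- apply(gt, 2L, code)
  if (is.null(dim(alle))) alle <- matrix(alle, nrow = nrow(gt))
  dimnames(alle) <- NULL
  miss <- apply(alle, 1L, anyNA)
  if (any(miss & !multi)) {
    message(sum(miss & !multi),
            " variant(s) with heterozygous/missing founder call(s) dropped")
  }
  keep <- !multi & !miss
  alle <- alle[keep, , drop = FALSE]
  nonseg <- rowSums(alle) %% ncol(alle) == 0L
  if (any(nonseg)) message(sum(nonseg),
                           " non-segregating variant(s) dropped")
  keep2 <- !nonseg
  if (is.null(strain_names)) strain_names <- colnames(gt)
  build_sdp_set(fix[keep, "CHROM"][keep2],
                as.numeric(fix[keep, "POS"])[keep2],
                alle[keep2, , drop = FALSE], strain_names)
}

build_sdp_set <- function(chrom, pos, alle, strains) {
  chroms <- unique(chrom)
  out <- lapply(chroms, function(cc) {
    i <- chrom == cc
    sdp_matrix(cc, pos[i], alle[i, , drop = FALSE], strains)
  })
  names(out) <- chroms
  if (length(out) == 1L) out[[1]] else out
}

#' Write an SDP matrix (or list of them) in the TSV dialect
#'
#' @param sdp An `sdp_matrix` or list of them.
#' @param path Output file.
#' @export
write_sdp_table <- function(sdp, path) {
  if (inherits(sdp, "sdp_matrix")) sdp <- list(sdp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#strains: ",
                    paste(sdp[[1]]$strain_names, collapse = ",")), con)
  writeLines("#chrom\tpos\tsdp", con)
  for (s in sdp) {
    if (!nrow(s$alleles)) next
    writeLines(paste(s$chrom, format(s$positions, scientific = FALSE,
                                     trim = TRUE),
                     sdp_strings(s), sep = "\t"), con)
  }
  invisible(path)
}
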