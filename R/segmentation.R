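#' Four-gamete compatibility of two SDPs
#'
#' Two biallelic variants are consistent with a single phylogenetic tree
#' (under the infinite-sites assumption) if and only if at most three of
#' the four possible allele pairs (0,0), (0,1), (1,0), (1,1) occur
#' across the founder strains.
#'
#' @param sdp_a,sdp_b Equal-length binary vectors (one allele per
#'   strain).
#' @return `TRUE` if the pair passes the four-gamete test.
#' @export
four_gamete_compatible <- function(sdp_a, sdp_b) {
  if (length(sdp_a) != length(sdp_b)) {
    stop("SDP length mismatch: ", length(sdp_a), " vs ", length(sdp_b))
  }
  g <- unique(sdp_a * 2L + sdp_b)
  length(g) <= 3L
}

#' Partition a region into tree-consistent intervals
#'
#' Scans the variants of a region left to right, growing each interval
#' until the next variant fails the four-gamete test against any
#' variant already in the interval, then starting a new interval. With
#' complete binary data, pairwise compatibility of all members implies
#' a single perfect phylogeny for the interval (splits compatibility),
#' and the greedy left-anchored scan yields the minimal contiguous
#' partition. Interval boundaries are placed at the midpoint between
#' the flanking variants of adjacent intervals; the first and last
#' intervals extend to the region bounds. A variant-free region yields
#' one interval with a single leaf.
#'
#' @param sdps An [sdp_matrix()].
#' @param region Numeric length-2, 0-based half-open `[start, end)`
#'   bounds of the region (e.g. a QTL confidence interval).
#' @return A `data.frame` of class `phylo_intervals` with columns
#'   `chrom`, `start`, `end`, `interval_id`, `n_leaves`, `leaf_string`
#'   (leaf label of each strain, in strain order), plus a
#'   `member_variants` list-column of row indices into `sdps`.
#' @export
segment_by_compatibility <- function(sdps, region) {
  stopifnot(inherits(sdps, "sdp_matrix"))
  start <- region[1]; end <- region[2]
  if (!(start < end)) stop("empty region [", start, ", ", end, ")")
  inside <- which(sdps$positions > start & sdps$positions <= end)
  K <- ncol(sdps$alleles)
  if (!length(inside)) {
    return(new_phylo_intervals(sdps, start, end,
                               members = list(integer(0))))
  }
  pos <- sdps$positions[inside]
  A <- sdps$alleles[inside, , drop = FALSE]
  m <- length(inside)
  cuts <- integer(0)              # index i: boundary between i and i+1
  first <- 1L
  if (m > 1L) {
    for (j in 2L:m) {
      ok <- TRUE
      for (i in first:(j - 1L)) {
        if (!four_gamete_compatible(A[i, ], A[j, ])) { ok <- FALSE; break }
      }
      if (!ok) {
        cuts <- c(cuts, j - 1L)
        first <- j
      }
    }
  }
  groups <- split(seq_len(m), cumsum(seq_len(m) %in% (cuts + 1L)))
  members <- unname(lapply(groups, function(g) inside[g]))
  ## boundaries at inter-variant midpoints
  bnd <- vapply(cuts, function(i) (pos[i] + pos[i + 1L]) / 2, 0)
  new_phylo_intervals(sdps, start, end, members, bnd)
}

new_phylo_intervals <- function(sdps, start, end, members,
                                boundaries = numeric(0)) {
  starts <- c(start, boundaries)
  ends <- c(boundaries, end)
  lf <- lapply(members, function(idx) leaf_partition(sdps, idx))
  out <- data.frame(
    chrom = sdps$chrom,
    start = starts,
    end = ends,
    interval_id = paste0(sdps$chrom, ":", seq_along(members)),
    n_leaves = vapply(lf, function(z) max(z) + 1L, 0L),
    leaf_string = vapply(lf, paste, "", collapse = ""),
    stringsAsFactors = FALSE
  )
  out$member_variants <- members
  out$leaf_of_strain <- lf
  class(out) <- c("phylo_intervals", "data.frame")
  out
}

#' Leaf partition of the founder strains over an interval's variants
#'
#' Strains with identical allele vectors across the member variants are
#' indistinguishable on the interval's tree and share a leaf; leaf
#' labels (0-based) are assigned in order of first strain occurrence.
#' With no member variants all strains share one leaf.
#'
#' @param sdps An [sdp_matrix()].
#' @param member_idx Row indices of the interval's variants.
#' @return Integer vector of leaf labels, one per strain, named by
#'   strain.
#' @export
leaf_partition <- function(sdps, member_idx) {
  K <- ncol(sdps$alleles)
  if (!length(member_idx)) {
    return(stats::setNames(rep(0L, K), sdps$strain_names))
  }
  A <- sdps$alleles[member_idx, , drop = FALSE]
  key <- apply(A, 2L, paste, collapse = "")
  stats::setNames(match(key, unique(key)) - 1L, sdps$strain_names)
}

#' @exportS3Method base::print
print.phylo_intervals <- function(x, ...) {
  cat(sprintf("phylo_intervals: %d tree-consistent interval(s) on %s [%s, %s)\n",
              nrow(x), x$chrom[1],
              format(min(x$start), big.mark = ","),
              format(max(x$end), big.mark = ",")))
  print.data.frame(x[, c("interval_id", "start", "end", "n_leaves",
                         "leaf_string")], row.names = FALSE)
  invisible(x)
}

#' Read tree-consistent intervals from BED4+
#'
#' Inverse of [write_phylo_intervals()] for downstream stages: the
#' member-variant indices are not stored on disk, but the leaf
#' partition (all the merge test needs) is recovered from
#' `leaf_string`.
#'
#' @param path BED4+ file written by [write_phylo_intervals()].
#' @return A `phylo_intervals` data frame (without `member_variants`).
#' @export
read_phylo_intervals <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "interval_id", "n_leaves",
                                       "leaf_string"),
                         colClasses = c(leaf_string = "character"))
  d$leaf_of_strain <- lapply(strsplit(d$leaf_string, ""), as.integer)
  class(d) <- c("phylo_intervals", "data.frame")
  d
}

#' Write tree-consistent intervals as BED4+
#'
#' Columns: `chrom start end interval_id n_leaves leaf_string`.
#'
#' @param intervals A `phylo_intervals` object.
#' @param path Output file.
#' @param header Optional extra `#` header lines.
#' @export
write_phylo_intervals <- function(intervals, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  writeLines("#chrom\tstart\tend\tinterval_id\tn_leaves\tleaf_string", con)
  writeLines(paste(intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   intervals$interval_id, intervals$n_leaves,
                   intervals$leaf_string, sep = "\t"), con)
  invisible(path)
}
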