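#' Founder-descent probability tensor
#'
#' Per-individual, per-locus probabilities of descent from each of the
#' K founders on one chromosome (as produced externally by an ancestral
#' haplotype-reconstruction HMM, or by the synthetic generator). Stored
#' either densely (`N x T x K` array) or compactly as a founder-state
#' matrix (one-hot, optionally blurred towards uniform by `epsilon`).
#' Every (individual, locus) probability row sums to 1 (checked to
#' 1e-6).
#'
#' @param probs `N x T x K` array, or `NULL` when `states` is given.
#' @param positions 1-based bp positions of the T loci, ascending.
#' @param chrom Chromosome id.
#' @param individuals Individual ids (default `ind1..indN`).
#' @param strain_names Founder names.
#' @param states Integer `N x T` matrix of founder indices (1..K) for
#'   the compact one-hot representation.
#' @param K Number of founders (required with `states`).
#' @param epsilon Blur: each row becomes `(1-epsilon)` on the true
#'   founder plus `epsilon/K` everywhere.
#' @return Object of class `descent_probs`.
#' @export
descent_probs <- function(probs = NULL, positions, chrom,
                          individuals = NULL, strain_names = NULL,
                          states = NULL, K = NULL, epsilon = 0) {
  if (is.null(probs) == is.null(states)) {
    stop("give exactly one of 'probs' or 'states'")
  }
  if (!is.null(probs)) {
    dm <- dim(probs)
    if (length(dm) != 3L) stop("'probs' must be an N x T x K array")
    if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
    rs <- apply(probs, c(1, 2), sum)
    if (any(abs(rs - 1) > 1e-6)) {
      stop("descent probability rows must sum to 1 (tolerance 1e-6)")
    }
    K <- dm[3]; N <- dm[1]; T_ <- dm[2]
  } else {
    if (is.null(K)) stop("'K' required with 'states'")
    storage.mode(states) <- "integer"
    if (any(states < 1L | states > K)) stop("founder state outside 1..K")
    N <- nrow(states); T_ <- ncol(states)
  }
  if (length(positions) != T_) stop("length(positions) must equal T")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("locus positions must be strictly increasing")
  }
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(N))
  if (is.null(strain_names)) strain_names <- paste0("founder", seq_len(K))
  structure(
    list(probs = probs, states = states, epsilon = epsilon,
         positions = as.numeric(positions), chrom = chrom,
         individuals = individuals, strain_names = strain_names,
         K = as.integer(K)),
    class = "descent_probs"
  )
}

#' @exportS3Method base::print
print.descent_probs <- function(x, ...) {
  cat(sprintf("descent_probs: %d individuals x %d loci x %d founders on %s (%s)\n",
              n_individuals(x), n_loci(x), x$K, x$chrom,
              if (is.null(x$probs)) sprintf("one-hot, epsilon = %g", x$epsilon)
              else "dense"))
  invisible(x)
}

n_individuals <- function(dp) {
  if (!is.null(dp$probs)) dim(dp$probs)[1] else nrow(dp$states)
}
n_loci <- function(dp) {
  if (!is.null(dp$probs)) dim(dp$probs)[2] else ncol(dp$states)
}
n_founders <- function(dp) dp$K

#' Descent probabilities at one locus
#'
#' @param dp A [descent_probs()] object.
#' @param t Locus index.
#' @return N x K matrix of probabilities.
#' @export
descent_locus <- function(dp, t) {
  if (!is.null(dp$probs)) return(dp$probs[, t, ])
  K <- dp$K
  P <- matrix(dp$epsilon / K, n_individuals(dp), K)
  P[cbind(seq_len(nrow(P)), dp$states[, t])] <-
    1 - dp$epsilon + dp$epsilon / K
  P
}

#' Read / write descent probabilities as wide TSV
#'
#' Dialect: `#`-prefixed header, then columns
#' `individual chrom pos p1..pK` (one row per individual x locus,
#' positions 1-based).
#'
#' @param path TSV file.
#' @param strain_names Optional founder names.
#' @return A `descent_probs`, or a named list of them (one per
#'   chromosome).
#' @export
read_descent_tsv <- function(path, strain_names = NULL) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, skip = "individual")
  pcols <- grep("^p[0-9]+$", names(d), value = TRUE)
  K <- length(pcols)
  if (K < 2L) stop("descent TSV needs at least 2 founder columns")
  chroms <- unique(d$chrom)
  out <- lapply(chroms, function(cc) {
    dc <- d[d$chrom == cc, ]
    inds <- unique(dc$individual)
    pos <- sort(unique(dc$pos))
    A <- array(NA_real_, c(length(inds), length(pos), K))
    ii <- match(dc$individual, inds)
    tt <- match(dc$pos, pos)
    for (k in seq_len(K)) {
      A[cbind(ii, tt, k)] <- dc[[pcols[k]]]
    }
    if (anyNA(A)) stop("incomplete descent tensor for chromosome ", cc)
    descent_probs(A, pos, cc, individuals = inds,
                  strain_names = strain_names)
  })
  names(out) <- chroms
  if (length(out) == 1L) out[[1]] else out
}

#' @param dp A `descent_probs` or list of them.
#' @rdname read_descent_tsv
#' @export
write_descent_tsv <- function(dp, path) {
  if (inherits(dp, "descent_probs")) dp <- list(dp)
  tabs <- lapply(dp, function(x) {
    N <- n_individuals(x); T_ <- n_loci(x)
    P <- matrix(0, N * T_, x$K)
    for (t in seq_len(T_)) {
      P[(t - 1L) * N + seq_len(N), ] <- descent_locus(x, t)
    }
    dt <- data.table::data.table(
      individual = rep(x$individuals, times = T_),
      chrom = x$chrom,
      pos = rep(x$positions, each = N))
    for (k in seq_len(x$K)) dt[[paste0("p", k)]] <- P[, k]
    dt
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t")
  invisible(path)
}

#' Read / write phenotype tables
#'
#' TSV with header `individual` plus one column per trait (named `y`
#' for a single-trait table, or by phenotype id) and any covariate
#' columns; missing trait values are rejected.
#'
#' @param path TSV file.
#' @return A `data.frame` with `individual` and the trait/covariate
#'   columns.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (!"individual" %in% names(d) || ncol(d) < 2L) {
    stop("phenotype table needs an 'individual' column and >= 1 trait")
  }
  traits <- setdiff(names(d), "individual")
  if (anyNA(d[traits])) stop("missing trait values in ", path)
  d
}

#' @param phen Phenotype data frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
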