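#' Kinship from founder-descent probabilities
#'
#' Expected founder-haplotype sharing between individuals:
#' `K[i,j] = mean over loci of sum_f p[i,f] * p[j,f]`, i.e. the
#' probability, averaged along the genome, that two individuals carry
#' descent from the same founder. Used as the covariance structure of
#' the polygenic random effect.
#'
#' @param probs A [descent_probs()] object.
#' @param loci Optional subset of locus indices (e.g. a thinned grid)
#'   to average over.
#' @return N x N symmetric PSD matrix with entries in `[0, 1]`.
#' @export
kinship_from_descent <- function(probs, loci = NULL) {
  stopifnot(inherits(probs, "descent_probs"))
  T_ <- n_loci(probs)
  if (T_ == 0L) stop("empty descent tensor")
  if (is.null(loci)) loci <- seq_len(T_)
  N <- n_individuals(probs)
  K <- matrix(0, N, N)
  for (t in loci) {
    P <- descent_locus(probs, t)
    K <- K + P %*% t(P)
  }
  K <- K / length(loci)
  (K + t(K)) / 2
}

#' Variance components of the polygenic mixed model by spectral REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g2 * K)` and
#' `e ~ N(0, sigma_e2 * I)` by restricted maximum likelihood, profiling
#' everything except the variance ratio `delta = sigma_e2 / sigma_g2`.
#' After eigendecomposition of the projected kinship `S K S`
#' (`S = I - X (X'X)^-1 X'`), the REML log-likelihood is a cheap 1-D
#' function of `delta`, maximised on a log10 grid over `[-10, 10]` and
#' refined with bounded scalar optimisation. Deterministic for fixed
#' inputs.
#'
#' @param y Numeric response (no missing values).
#' @param X Fixed-effect design matrix; `NULL` means intercept only.
#' @param kinship N x N PSD kinship matrix.
#' @param prep Optional precomputed [reml_prep()] (reuse across
#'   phenotypes sharing `X` and `kinship`).
#' @return Object of class `variance_components`: `sigma_g2`,
#'   `sigma_e2`, `delta`, `h2`, `logREML`, and the kinship
#'   eigendecomposition used for whitening in the association tests.
#' @export
reml_variance_components <- function(y, X = NULL, kinship = NULL,
                                     prep = NULL) {
  if (is.null(prep)) prep <- reml_prep(kinship, X, n = length(y))
  n <- prep$n; q <- prep$q
  if (length(y) != n) stop("length(y) does not match kinship")
  if (stats::var(y) == 0) stop("constant phenotype: variance components undefined")
  eta <- drop(crossprod(prep$U_R, y))
  lam <- prep$lambda_R
  nq <- n - q
  negll <- function(log10d) {
    d <- 10^log10d
    ss <- sum(eta^2 / (lam + d))
    -0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(ss) -
              sum(log(lam + d)))
  }
  grid <- seq(-10, 10, by = 0.5)
  vals <- vapply(grid, negll, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(negll, c(lo, hi))
  ## compare refined optimum against the grid edge winners
  log10d <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
  delta <- 10^log10d
  sigma_g2 <- sum(eta^2 / (lam + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
         h2 = 1 / (1 + delta), logREML = -negll(log10d),
         eigen_K = prep$eigen_K, n = n),
    class = "variance_components"
  )
}

#' @exportS3Method base::print
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (REML): sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  delta = %.4g, h2 = %.3f\n", x$delta, x$h2))
  invisible(x)
}

#' Precompute decompositions for repeated REML fits
#'
#' @param kinship N x N PSD kinship matrix; a ridge of at most 1e-8 is
#'   added if slightly indefinite, larger negativity is an error.
#' @param X Fixed-effect design (`NULL` = intercept).
#' @param n Number of individuals (needed if `X` is `NULL`).
#' @return A list reusable as the `prep` argument of
#'   [reml_variance_components()].
#' @export
reml_prep <- function(kinship, X = NULL, n = nrow(kinship)) {
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design")
  q <- ncol(X)
  if (n < q + 2) stop("need at least rank(X) + 2 observations")
  eK <- eigen(kinship, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(abs(eK$values))) {
    kinship <- kinship + diag(1e-8, n)
    eK <- eigen(kinship, symmetric = TRUE)
    if (min(eK$values) < -1e-8 * max(abs(eK$values))) {
      stop("kinship matrix is not positive semidefinite")
    }
  }
  eK$values <- pmax(eK$values, 0)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  ## decompose S (K + I) S rather than S K S: K + I is full rank, so
  ## the n - q positive eigenvalues and their eigenvectors are uniquely
  ## confined to the complement of the fixed-effect column space even
  ## when the kinship itself is singular
  eS <- eigen(S %*% (kinship + diag(n)) %*% S, symmetric = TRUE)
  idx <- seq_len(n - q)
  list(n = n, q = q, U_R = eS$vectors[, idx, drop = FALSE],
       lambda_R = pmax(eS$values[idx] - 1, 0), eigen_K = eK)
}

## Whitening transform rows: with Sigma propto U (Lambda + delta I) U',
## premultiplying by diag(1/sqrt(lambda + delta)) U' makes errors iid.
## sigma_g2 = 0 (delta infinite) degenerates to the identity transform.
whiten_transform <- function(vc) {
  if (vc$sigma_g2 <= 0 || !is.finite(vc$delta) || vc$delta > 1e8) {
    return(NULL)  # ordinary least squares
  }
  e <- vc$eigen_K
  diag(1 / sqrt(e$values + vc$delta)) %*% t(e$vectors)
}

## F-test of [X, D] against [X] on whitened data; returns logP (-log10 p)
whitened_ftest <- function(y, X, D, vc) {
  W <- whiten_transform(vc)
  if (!is.null(W)) {
    y <- drop(W %*% y); X <- W %*% X
    if (!is.null(D)) D <- W %*% D
  }
  q0 <- qr(X)
  r0 <- q0$rank
  rss0 <- sum(qr.resid(q0, y)^2)
  q1 <- qr(cbind(X, D))
  r1 <- q1$rank
  if (r1 <= r0) return(0)  # no genetic contrast beyond covariates
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- r1 - r0
  df2 <- length(y) - r1
  if (df2 <= 0) stop("no residual degrees of freedom for the F-test")
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(Fstat) || Fstat <= 0) return(0)
  -stats::pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Unconstrained founder-haplotype association test
#'
#' Mixed-model F-test of the K founder-descent dosage columns at one
#' locus against the covariate-only null, after whitening data and
#' design by the eigenstructure of the fitted covariance
#' `sigma_g2 K + sigma_e2 I`. One dosage column is dropped (the
#' dosages sum to one, so the K-th is collinear with the intercept);
#' which column is dropped does not change the F-test. Returns
#' `logP = -log10` of the F p-value, 0 when the locus adds no column
#' space beyond the covariates.
#'
#' @param y Phenotype vector.
#' @param X Covariate design (`NULL` = intercept only).
#' @param locus_probs N x K matrix of founder-descent probabilities at
#'   the test locus.
#' @param vc [reml_variance_components()] fit of the covariate-only
#'   model for this phenotype.
#' @param drop_col Dosage column dropped for identifiability
#'   (default K).
#' @return logP (non-negative scalar).
#' @export
haplotype_logp <- function(y, X = NULL, locus_probs, vc, drop_col = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  locus_probs <- as.matrix(locus_probs)
  if (is.null(drop_col)) drop_col <- ncol(locus_probs)
  D <- locus_probs[, -drop_col, drop = FALSE]
  whitened_ftest(y, as.matrix(X), D, vc)
}

#' Tree-constrained (merged) association test
#'
#' The merge analysis constrains founders sharing a tree leaf to a
#' common effect: founder dosage columns are summed within the leaves
#' of the interval's phylogenetic tree, giving a pseudo multi-allelic
#' marker with L alleles, and the L-column model is F-tested against
#' the covariate-only null exactly as in [haplotype_logp()]. A
#' single-leaf tree has no genetic contrast and scores `logP = 0`.
#'
#' @inheritParams haplotype_logp
#' @param leaf_of_strain Integer leaf label per strain (0-based), as
#'   from [leaf_partition()].
#' @return logP (non-negative scalar).
#' @export
merge_logp <- function(y, X = NULL, locus_probs, leaf_of_strain, vc) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  locus_probs <- as.matrix(locus_probs)
  if (length(leaf_of_strain) != ncol(locus_probs)) {
    stop("leaf_of_strain must have one label per founder column")
  }
  L <- max(leaf_of_strain) + 1L
  if (L == 1L) return(0)
  M <- matrix(0, ncol(locus_probs), L)
  M[cbind(seq_along(leaf_of_strain), leaf_of_strain + 1L)] <- 1
  D <- (locus_probs %*% M)[, -L, drop = FALSE]
  whitened_ftest(y, as.matrix(X), D, vc)
}

#' Merge analysis of one QTL: call tree-consistent intervals
#'
#' For each tree-consistent interval of a QTL confidence interval, the
#' merged (leaf-constrained) model and the unconstrained K-founder
#' haplotype model are tested at the descent-probability locus nearest
#' the interval midpoint. An interval is called consistent when its
#' merged logP equals or exceeds the haplotype logP — the tree then
#' explains the allelic effects at least as well with fewer degrees of
#' freedom. A 0-0 tie carries no evidence and is not called.
#'
#' @param qtl One row of a [qtl_table()].
#' @param intervals `phylo_intervals` tiling the QTL CI.
#' @param probs [descent_probs()] for the QTL's chromosome.
#' @param y,X Phenotype and covariates (see [haplotype_logp()]).
#' @param vc Covariate-only [reml_variance_components()] fit.
#' @return A `data.frame` of class `merge_result`: `qtl_id`,
#'   `interval_id`, `start`, `end`, `n_leaves`, `df_merge`, `df_hap`,
#'   `logP_merge`, `logP_hap`, `consistent`, sorted by start.
#' @export
call_consistent_intervals <- function(qtl, intervals, probs, y, X = NULL,
                                      vc) {
  pos <- probs$positions
  in_ci <- pos > qtl$ci_start & pos <= qtl$ci_end
  if (!any(in_ci)) {
    stop("no descent-probability locus inside the CI of ", qtl$qtl_id)
  }
  K <- n_founders(probs)
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    mid <- (intervals$start[i] + intervals$end[i]) / 2
    t_idx <- which(in_ci)[which.min(abs(pos[in_ci] - mid))]
    P <- descent_locus(probs, t_idx)
    lh <- haplotype_logp(y, X, P, vc)
    leaf <- intervals$leaf_of_strain[[i]]
    lm_ <- merge_logp(y, X, P, leaf, vc)
    data.frame(qtl_id = qtl$qtl_id, interval_id = intervals$interval_id[i],
               start = intervals$start[i], end = intervals$end[i],
               n_leaves = intervals$n_leaves[i],
               df_merge = intervals$n_leaves[i] - 1L, df_hap = K - 1L,
               test_locus = pos[t_idx],
               logP_merge = lm_, logP_hap = lh,
               consistent = lm_ > 0 && lm_ >= lh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("merge_result", "data.frame")
  out
}

#' @exportS3Method base::print
print.merge_result <- function(x, ...) {
  cat(sprintf("merge_result: %s — %d interval(s), %d consistent\n",
              x$qtl_id[1], nrow(x), sum(x$consistent)))
  print.data.frame(x[, c("interval_id", "start", "end", "n_leaves",
                         "logP_merge", "logP_hap", "consistent")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @exportS3Method base::summary
summary.merge_result <- function(object, ...) {
  data.frame(qtl_id = object$qtl_id[1], n_intervals = nrow(object),
             n_consistent = sum(object$consistent),
             max_logP_hap = max(object$logP_hap),
             max_logP_merge = max(object$logP_merge))
}

#' Read merge results back from TSV
#'
#' Inverse of [write_merge_results()] (enough of it for the enrichment
#' stage: interval coordinates and the consistency flag).
#'
#' @param path TSV written by [write_merge_results()].
#' @return A `merge_result` data frame.
#' @export
read_merge_results <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("qtl_id", "interval_id", "start",
                                       "end", "n_leaves", "logP_merge",
                                       "logP_hap", "consistent"))
  d$consistent <- as.logical(d$consistent)
  class(d) <- c("merge_result", "data.frame")
  d
}

#' Write merge results as TSV
#'
#' @param results A `merge_result` (or rbind of several).
#' @param path Output file.
#' @param header Optional `#` header lines.
#' @export
write_merge_results <- function(results, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  writeLines("#qtl_id\tinterval_id\tstart\tend\tL\tlogP_merge\tlogP_hap\tconsistent", con)
  writeLines(paste(results$qtl_id, results$interval_id,
                   format(results$start, scientific = FALSE, trim = TRUE),
                   format(results$end, scientific = FALSE, trim = TRUE),
                   results$n_leaves,
                   sprintf("%.17g", results$logP_merge),
                   sprintf("%.17g", results$logP_hap),
                   as.integer(results$consistent), sep = "\t"), con)
  invisible(path)
}
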