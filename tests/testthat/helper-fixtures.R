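## Shared fixtures and independent oracles for the test suite.

## random segregating SDP matrix (M variants x K strains)
random_sdp_matrix <- function(M, K = 8, chrom = "chrT",
                              span = c(0, 1e6)) {
  rows <- matrix(0L, M, K)
  for (i in seq_len(M)) {
    repeat {
      v <- stats::rbinom(K, 1, 0.5)
      if (any(v == 1) && any(v == 0)) break
    }
    rows[i, ] <- v
  }
  pos <- sort(sample(seq.int(span[1] + 1, span[2]), M))
  sdp_matrix(chrom, pos, rows)
}

## Independent segmentation oracle: precompute the full pairwise
## compatibility matrix (counting distinct gamete pairs via table()),
## then scan it. Returns the cut positions (inter-variant midpoints).
brute_force_cuts <- function(sdp, region) {
  keep <- sdp$positions > region[1] & sdp$positions <= region[2]
  A <- sdp$alleles[keep, , drop = FALSE]
  pos <- sdp$positions[keep]
  m <- nrow(A)
  if (m < 2) return(numeric(0))
  compat <- matrix(TRUE, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    n_gametes <- nrow(unique(cbind(A[i, ], A[j, ])))
    compat[i, j] <- compat[j, i] <- n_gametes <= 3
  }
  cuts <- numeric(0)
  first <- 1
  for (j in 2:m) {
    if (!all(compat[first:(j - 1), j])) {
      cuts <- c(cuts, (pos[j - 1] + pos[j]) / 2)
      first <- j
    }
  }
  cuts
}

## Direct generalized-least-squares F-test oracle: invert the full
## covariance sigma_g2 * K + sigma_e2 * I, no spectral shortcut.
gls_logp <- function(y, X, D, vc, kinship) {
  n <- length(y)
  Sigma <- vc$sigma_g2 * kinship + vc$sigma_e2 * diag(n)
  W <- chol(solve(Sigma))
  yt <- drop(W %*% y)
  X0 <- W %*% X
  X1 <- W %*% cbind(X, D)
  q0 <- qr(X0); q1 <- qr(X1)
  rss0 <- sum(qr.resid(q0, yt)^2)
  rss1 <- sum(qr.resid(q1, yt)^2)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  Fs <- ((rss0 - rss1) / df1) / (rss1 / df2)
  -stats::pf(Fs, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
}

## random dense PSD kinship with unit mean diagonal
random_kinship <- function(n) {
  K <- crossprod(matrix(stats::rnorm(n * n), n)) / n
  K / mean(diag(K))
}

## family-block kinship: nf families of fs members, within-family rho
block_kinship <- function(nf, fs, rho = 0.5) {
  K <- kronecker(diag(nf), matrix(rho, fs, fs))
  diag(K) <- 1
  K
}

## tiny 3-term chain ontology (root <- mid <- leaf) + 2 genes
tiny_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid process",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf process",
    "namespace: biological_process", "is_a: GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000004", "name: side process",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000009", "name: gone process",
    "namespace: biological_process", "is_obsolete: true", "",
    "[Term]", "id: GO:0000008", "name: other namespace",
    "namespace: molecular_function"), path)
  path
}

tiny_gaf <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(gene = c("geneA", "geneB"),
                       term = c("GO:0000003", "GO:0000002"),
                       qual = "", ev = c("IDA", "IEA"))
  }
  writeLines(c("!gaf-version: 2.1",
               paste("DB", rows$gene, rows$gene, rows$qual, rows$term,
                     "REF", rows$ev, "", "P", "", "", "gene",
                     "taxon:0", "20120101", "DB", sep = "\t")), path)
  path
}

## gene models on one or two chromosomes at fixed coordinates
toy_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100e3, 500e3, 900e3, 200e3, 700e3),
    end = c(120e3, 520e3, 920e3, 220e3, 720e3),
    strand = "+", stringsAsFactors = FALSE)
}

## uniform window table over given chromosome lengths (one GC bin per
## decile of distinct synthetic GC values)
toy_windows <- function(chrom_lengths, window_size = 1e5) {
  set.seed(424242)
  w <- do.call(rbind, lapply(names(chrom_lengths), function(cc) {
    starts <- seq(0, chrom_lengths[[cc]] - 1, by = window_size)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + window_size, chrom_lengths[[cc]]),
               gc = runif(length(starts), 0.35, 0.55))
  }))
  compute_gc_windows(w)
}
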