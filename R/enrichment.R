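#' Consistent-interval sets for enrichment
#'
#' The enrichment test consumes, per QTL, the tree-consistent
#' sub-intervals expressed as offsets relative to the CI start, so the
#' same pattern can be overlaid on randomly placed null intervals.
#'
#' @param qtls A [qtl_table()].
#' @param merge_results `merge_result` rows (rbind over QTLs), or
#'   `NULL` with `whole_ci = TRUE`.
#' @param whole_ci If `TRUE` each QTL's single "consistent" interval is
#'   its whole CI (the unfiltered comparison).
#' @return A named list (by `qtl_id`) of lists with `chrom`,
#'   `ci_start`, `ci_end` and an `offsets` matrix (columns start, end;
#'   0-based, relative to `ci_start`), class `consistent_sets`.
#' @export
consistent_sets <- function(qtls, merge_results = NULL, whole_ci = FALSE) {
  out <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    if (whole_ci) {
      off <- cbind(start = 0, end = q$ci_end - q$ci_start)
    } else {
      m <- merge_results[merge_results$qtl_id == q$qtl_id &
                           merge_results$consistent, , drop = FALSE]
      off <- cbind(start = m$start - q$ci_start, end = m$end - q$ci_start)
    }
    if (nrow(off)) {
      o <- order(off[, 1])
      off <- off[o, , drop = FALSE]
      w <- q$ci_end - q$ci_start
      if (any(off[, 1] < 0 | off[, 2] > w | off[, 1] >= off[, 2])) {
        stop("consistent offsets outside [0, ci_width) for ", q$qtl_id)
      }
    }
    list(qtl_id = q$qtl_id, chrom = q$chrom, ci_start = q$ci_start,
         ci_end = q$ci_end, offsets = off)
  })
  names(out) <- qtls$qtl_id
  class(out) <- "consistent_sets"
  out
}

## gene -> propagated term list, inverted once from a go_index
gene_term_map <- function(go_index) {
  tg <- go_index$term_genes
  g <- unlist(tg, use.names = FALSE)
  t <- rep(names(tg), lengths(tg))
  split(t, g)
}

## Precomputed counting engine: per-chromosome gene coordinates and
## per-gene integer term indices, so replicate counting is cheap.
enrich_prep <- function(genes, go_index) {
  term_ids <- names(go_index$term_genes)
  g2t <- gene_term_map(go_index)
  by_chrom <- lapply(split(genes, genes$chrom), function(g) {
    list(start = g$start, end = g$end,
         terms = lapply(g2t[g$gene_id], function(tt) {
           if (is.null(tt)) integer(0) else match(tt, term_ids)
         }))
  })
  list(term_ids = term_ids, by_chrom = by_chrom)
}

## integer term indices hit by one placed interval set
terms_hit_idx <- function(prep, chrom, starts, ends) {
  g <- prep$by_chrom[[chrom]]
  if (is.null(g) || !length(starts)) return(integer(0))
  hit <- logical(length(g$start))
  for (i in seq_along(starts)) {
    hit <- hit | (g$start < ends[i] & starts[i] < g$end)
  }
  if (!any(hit)) return(integer(0))
  unique(unlist(g$terms[hit], use.names = FALSE))
}

#' Observed per-term QTL counts
#'
#' For each GO term j, the number of QTLs (`n_Qj`) whose consistent
#' sub-intervals overlap at least one gene annotated (after true-path
#' propagation) with j. A QTL contributes at most 1 to a term however
#' many of its genes carry it; genes inside the CI but outside the
#' consistent sub-intervals are ignored, mirroring the null sets.
#'
#' @param csets A [consistent_sets()] object.
#' @param genes Gene models ([read_gene_models()]).
#' @param go_index A [build_go_index()] object.
#' @param prep Precomputed counting engine (internal reuse).
#' @return Named integer vector over all indexed annotated terms.
#' @export
observed_term_counts <- function(csets, genes, go_index, prep = NULL) {
  if (is.null(prep)) prep <- enrich_prep(genes, go_index)
  counts <- stats::setNames(integer(length(prep$term_ids)),
                            prep$term_ids)
  for (cs in csets) {
    if (!nrow(cs$offsets)) next
    ts <- terms_hit_idx(prep, cs$chrom,
                        cs$ci_start + cs$offsets[, 1],
                        cs$ci_start + cs$offsets[, 2])
    counts[ts] <- counts[ts] + 1L
  }
  counts
}

#' Sample G+C- and chromosome-matched null interval sets
#'
#' One null replicate places, for every QTL, an interval of the QTL's
#' CI length at a random location on the same chromosome: the window
#' containing the QTL's CI midpoint gives the source %G+C bin, a
#' same-chromosome window of that bin is drawn uniformly, a start drawn
#' uniformly inside it, and the interval clipped to fit the chromosome.
#' The QTL's consistent-interval offsets are overlaid on each placement.
#' If the bin has no same-chromosome window, the nearest non-empty bin
#' is used (with a warning). Optional gene-number matching redraws a
#' placement (up to `max_tries`) until the gene count inside the
#' overlaid consistent sub-intervals is within 20% of the source
#' QTL's, removing between-replicate gene-count variance.
#'
#' @param csets A [consistent_sets()] object.
#' @param windows A [compute_gc_windows()] table.
#' @param n_reps Number of replicates.
#' @param seed RNG seed (reproducible sets).
#' @param gene_match Enable gene-number matching (default off).
#' @param genes Gene models, required when `gene_match = TRUE`.
#' @param max_tries Rejection-sampling cap for gene matching.
#' @return List of `n_reps` replicates; each a data frame
#'   `qtl_id chrom start length` (placed interval; overlay offsets come
#'   from `csets`). Class `null_interval_sets`.
#' @export
sample_null_sets <- function(csets, windows, n_reps, seed = 1,
                             gene_match = FALSE, genes = NULL,
                             max_tries = 100) {
  if (gene_match && is.null(genes)) stop("gene_match needs gene models")
  chrom_len <- window_chrom_lengths(windows)
  ## per-QTL candidate windows (same chromosome, source GC bin)
  cand <- lapply(csets, function(cs) {
    mid <- (cs$ci_start + cs$ci_end) / 2
    src <- which(windows$chrom == cs$chrom & windows$start <= mid &
                   mid < windows$end)
    if (!length(src)) stop("no GC window containing the midpoint of ",
                           cs$qtl_id)
    bin <- windows$gc_bin[src[1]]
    same <- windows$chrom == cs$chrom
    hit <- which(same & windows$gc_bin == bin)
    if (!length(hit)) {
      bins <- sort(unique(windows$gc_bin[same]))
      bin2 <- bins[which.min(abs(bins - bin))]
      warning("no window of GC bin ", bin, " on ", cs$chrom,
              "; falling back to bin ", bin2, " for ", cs$qtl_id)
      hit <- which(same & windows$gc_bin == bin2)
    }
    n_src <- if (gene_match) {
      length(genes_in_intervals(genes, cs$chrom,
                                cs$ci_start + cs$offsets[, 1],
                                cs$ci_start + cs$offsets[, 2]))
    } else NA_integer_
    list(len = cs$ci_end - cs$ci_start, chrom = cs$chrom,
         win = hit, n_src = n_src, offsets = cs$offsets)
  })
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    starts <- vapply(cand, function(cd) {
      draw <- function() {
        w <- cd$win[sample.int(length(cd$win), 1L)]
        s <- windows$start[w] +
          floor(stats::runif(1) * (windows$end[w] - windows$start[w]))
        max(0, min(s, chrom_len[[cd$chrom]] - cd$len))
      }
      s <- draw()
      if (gene_match) {
        for (k in seq_len(max_tries)) {
          ng <- length(genes_in_intervals(genes, cd$chrom,
                                          s + cd$offsets[, 1],
                                          s + cd$offsets[, 2]))
          if (abs(ng - cd$n_src) <= 0.2 * cd$n_src) break
          s <- draw()
        }
      }
      s
    }, 0)
    reps[[r]] <- data.frame(qtl_id = names(cand),
                            chrom = vapply(cand, `[[`, "", "chrom"),
                            start = starts,
                            length = vapply(cand, `[[`, 0, "len"),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  class(reps) <- "null_interval_sets"
  reps
}

## per-term QTL counts for one null replicate (overlaying csets offsets)
null_term_counts <- function(rep_df, csets, prep) {
  counts <- integer(length(prep$term_ids))
  for (i in seq_len(nrow(rep_df))) {
    cs <- csets[[rep_df$qtl_id[i]]]
    if (!nrow(cs$offsets)) next
    ts <- terms_hit_idx(prep, rep_df$chrom[i],
                        rep_df$start[i] + cs$offsets[, 1],
                        rep_df$start[i] + cs$offsets[, 2])
    counts[ts] <- counts[ts] + 1L
  }
  counts
}

## counts matrix: replicates x terms
null_count_matrix <- function(null_sets, csets, genes, go_index,
                              prep = NULL) {
  if (is.null(prep)) prep <- enrich_prep(genes, go_index)
  C <- matrix(0L, length(null_sets), length(prep$term_ids),
              dimnames = list(NULL, prep$term_ids))
  for (r in seq_along(null_sets)) {
    C[r, ] <- null_term_counts(null_sets[[r]], csets, prep)
  }
  C
}

#' Empirical per-term enrichment p-values
#'
#' For each term j, `p_j` is the fraction of null replicates whose
#' count `n_rj` equals or exceeds the observed `n_Qj` (so `n_Qj = 0`
#' gives `p_j = 1`). With `pseudocount = TRUE` the estimator is
#' `(1 + c) / (1 + N)`, never exactly zero. Fold enrichment is
#' `n_Qj / mean(n_rj)` (`Inf` when the null mean is 0 and `n_Qj > 0`).
#'
#' @param observed_counts From [observed_term_counts()].
#' @param null_sets From [sample_null_sets()] (at least 100
#'   replicates).
#' @param genes,go_index As in [observed_term_counts()].
#' @param csets The [consistent_sets()] whose offsets the null sets
#'   overlay.
#' @param pseudocount Use the `(1+c)/(1+N)` estimator.
#' @param prep Precomputed counting engine (internal reuse).
#' @return A `data.frame` of class `enrichment_table` (`term_id`,
#'   `name`, `n_Q`, `null_mean`, `p`, `fold`, `significant`), with the
#'   replicate-by-term null count matrix in
#'   `attr(, "null_counts")`.
#' @export
empirical_pvalues <- function(observed_counts, null_sets, csets, genes,
                              go_index, pseudocount = FALSE,
                              prep = NULL) {
  if (length(null_sets) < 100) {
    warning("fewer than 100 null replicates: p-value resolution is poor")
  }
  C <- null_count_matrix(null_sets, csets, genes, go_index, prep = prep)
  N <- nrow(C)
  term_ids <- colnames(C)
  obs <- observed_counts[term_ids]
  ge <- colSums(C >= matrix(obs, N, length(obs), byrow = TRUE))
  p <- if (pseudocount) (1 + ge) / (1 + N) else ge / N
  nm <- colMeans(C)
  fold <- ifelse(obs == 0, NA_real_,
                 ifelse(nm == 0, Inf, obs / nm))
  out <- data.frame(
    term_id = term_ids,
    name = go_index$terms$name[match(term_ids, go_index$terms$id)],
    n_Q = as.integer(obs), null_mean = nm, p = as.numeric(p),
    fold = fold, significant = NA, stringsAsFactors = FALSE,
    row.names = NULL)
  attr(out, "null_counts") <- C
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @exportS3Method base::print
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d terms, %d with n_Q > 0 (%d null replicates)\n",
              nrow(x), sum(x$n_Q > 0), nrow(attr(x, "null_counts"))))
  top <- x[order(x$p, -x$n_Q), ][seq_len(min(10L, nrow(x))), ]
  print.data.frame(top[, c("term_id", "n_Q", "null_mean", "p", "fold",
                           "significant")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Empirical-FDR p-value threshold
#'
#' For candidate thresholds t (the sorted observed p-values), the
#' experimental FDR is the mean number of terms an independent bank of
#' null interval sets discovers at t, divided by the observed discovery
#' count at t. The threshold returned is the largest t with
#' `FDR(t) <= q` (0, i.e. no discoveries, if none qualifies).
#'
#' @param observed_p Observed per-term p-values.
#' @param null_p Matrix (null sets x terms) of p-values obtained by
#'   treating each extra null set as observed (see
#'   [null_pvalue_matrix()]).
#' @param q Target FDR in (0, 1].
#' @return List with `t_star`, `n_significant`, and the per-candidate
#'   `table` (`t`, `n_obs`, `mean_null`, `fdr`).
#' @export
fdr_threshold <- function(observed_p, null_p, q = 0.10) {
  if (!(q > 0 && q <= 1)) stop("q must lie in (0, 1]")
  cand <- sort(unique(observed_p))
  n_obs <- vapply(cand, function(t) sum(observed_p <= t), 0)
  mean_null <- vapply(cand, function(t) mean(rowSums(null_p <= t)), 0)
  fdr <- mean_null / pmax(1, n_obs)
  ok <- fdr <= q
  t_star <- if (any(ok)) max(cand[ok]) else 0
  list(t_star = t_star,
       n_significant = if (any(ok)) n_obs[which(cand == t_star)] else 0L,
       table = data.frame(t = cand, n_obs = n_obs, mean_null = mean_null,
                          fdr = fdr))
}

#' Per-term p-values of extra null sets against the primary bank
#'
#' Each extra (FDR-bank) null set is scored exactly like the observed
#' data: its per-term counts are compared with the primary bank's count
#' distribution.
#'
#' @param extra_counts Matrix (extra sets x terms) of null counts.
#' @param bank_counts Matrix (primary replicates x terms).
#' @return Matrix (extra sets x terms) of empirical p-values.
#' @export
null_pvalue_matrix <- function(extra_counts, bank_counts) {
  stopifnot(identical(colnames(extra_counts), colnames(bank_counts)))
  N <- nrow(bank_counts)
  out <- matrix(NA_real_, nrow(extra_counts), ncol(extra_counts),
                dimnames = dimnames(extra_counts))
  for (j in seq_len(ncol(extra_counts))) {
    cb <- bank_counts[, j]
    mx <- max(cb, extra_counts[, j])
    cnt <- tabulate(cb + 1L, nbins = mx + 1L)
    lt <- c(0, cumsum(cnt))          # lt[v+1] = #{bank < v}
    out[, j] <- (N - lt[extra_counts[, j] + 1L]) / N
  }
  out
}

#' Information score: functional coherence of a gene set
#'
#' The sum of the negative base-10 logarithms of the per-term empirical
#' p-values over all GO terms associated with at least one gene in the
#' consistent intervals. Zero p-values are rejected (use the
#' pseudocount estimator, which cannot produce them).
#'
#' @param pvalues Per-term p-values (already restricted to terms with
#'   an annotated gene in the intervals, i.e. `n_Q >= 1`).
#' @return Non-negative scalar; 0 with a warning for an empty term set.
#' @export
information_score <- function(pvalues) {
  if (!length(pvalues)) {
    warning("empty term set: information score 0")
    return(0)
  }
  if (any(pvalues <= 0)) {
    stop("zero p-value(s): recompute with pseudocount = TRUE ",
         "before scoring")
  }
  if (any(pvalues > 1)) stop("p-values must lie in (0, 1]")
  sum(-log10(pvalues))
}

#' Monte Carlo test of the observed information score
#'
#' Every primary-bank null replicate is scored by the same pipeline as
#' the observation, leave-one-out: its per-term p-values are taken
#' against the remaining replicates (with the pseudocount estimator, so
#' scores are finite), and its score sums `-log10 p` over the terms it
#' hits. The empirical P is the fraction of null scores at or above the
#' observed score.
#'
#' @param enrich An [empirical_pvalues()] table (carries the null count
#'   bank).
#' @return Object of class `info_score_test`: `observed`, `null_scores`,
#'   `p` (plain) and `p_pseudo`.
#' @export
information_score_test <- function(enrich) {
  C <- attr(enrich, "null_counts")
  N <- nrow(C)
  if (N < 100) warning("fewer than 100 replicates: empirical P has ",
                       "resolution 1/", N)
  obs_n <- enrich$n_Q
  ## observed score: pseudocount p over terms with n_Q >= 1
  ge_obs <- colSums(C >= matrix(obs_n, N, length(obs_n), byrow = TRUE))
  p_obs <- (1 + ge_obs) / (1 + N)
  sel <- obs_n >= 1L
  observed <- if (any(sel)) information_score(p_obs[sel]) else {
    warning("no term hits any consistent interval"); 0
  }
  ## leave-one-out null scores: p = (#{others >= self} + 1) / N
  null_scores <- numeric(N)
  for (j in seq_len(ncol(C))) {
    cb <- C[, j]
    mx <- max(cb)
    if (mx == 0L) next
    cnt <- tabulate(cb + 1L, nbins = mx + 1L)
    lt <- c(0, cumsum(cnt))
    ge_self <- N - lt[cb + 1L]       # includes self, so >= 1
    contrib <- -log10(ge_self / N)
    contrib[cb == 0L] <- 0           # term not hit by that replicate
    null_scores <- null_scores + contrib
  }
  structure(
    list(observed = observed, null_scores = null_scores,
         p = sum(null_scores >= observed) / N,
         p_pseudo = (1 + sum(null_scores >= observed)) / (1 + N)),
    class = "info_score_test")
}

#' @exportS3Method base::print
print.info_score_test <- function(x, ...) {
  cat(sprintf("information score %.2f vs %d null sets: empirical P = %.4g\n",
              x$observed, length(x$null_scores), x$p))
  cat(sprintf("  (pseudocount P = %.4g; null mean %.2f, max %.2f)\n",
              x$p_pseudo, mean(x$null_scores), max(x$null_scores)))
  invisible(x)
}

#' Full Monte Carlo GO enrichment analysis of consistent intervals
#'
#' Chains [observed_term_counts()], two independent banks of
#' [sample_null_sets()] (p-value bank and FDR bank, separate seed
#' streams), [empirical_pvalues()], [fdr_threshold()] and
#' [information_score_test()].
#'
#' @param csets [consistent_sets()].
#' @param genes,go_index,windows Inputs as above.
#' @param n_reps_p,n_reps_fdr Replicates for the p-value and FDR banks.
#' @param q Target FDR.
#' @param seed Base seed; the two banks use `seed` and `seed + 1`.
#' @param pseudocount,gene_match Passed through.
#' @return Object of class `go_enrichment`: `table`
#'   (`enrichment_table` with `significant` filled), `t_star`, `fdr`,
#'   `info` (`info_score_test`), and the call parameters.
#' @export
go_enrichment <- function(csets, genes, go_index, windows,
                          n_reps_p = 5000, n_reps_fdr = 5000, q = 0.10,
                          seed = 1, pseudocount = FALSE,
                          gene_match = FALSE) {
  prep <- enrich_prep(genes, go_index)
  obs <- observed_term_counts(csets, genes, go_index, prep = prep)
  bank_p <- sample_null_sets(csets, windows, n_reps_p, seed = seed,
                             gene_match = gene_match, genes = genes)
  tab <- empirical_pvalues(obs, bank_p, csets, genes, go_index,
                           pseudocount = pseudocount, prep = prep)
  bank_f <- sample_null_sets(csets, windows, n_reps_fdr, seed = seed + 1,
                             gene_match = gene_match, genes = genes)
  Cf <- null_count_matrix(bank_f, csets, genes, go_index, prep = prep)
  np <- null_pvalue_matrix(Cf, attr(tab, "null_counts"))
  fdr <- fdr_threshold(tab$p, np, q = q)
  tab$significant <- tab$p <= fdr$t_star & tab$n_Q > 0
  info <- information_score_test(tab)
  structure(
    list(table = tab, t_star = fdr$t_star, fdr = fdr, info = info,
         n_reps_p = n_reps_p, n_reps_fdr = n_reps_fdr, q = q,
         seed = seed),
    class = "go_enrichment")
}

#' @exportS3Method base::print
print.go_enrichment <- function(x, ...) {
  cat(sprintf("go_enrichment: %d significant term(s) at FDR %.0f%% (t* = %g)\n",
              sum(x$table$significant, na.rm = TRUE), 100 * x$q, x$t_star))
  print(x$info)
  sig <- x$table[which(x$table$significant), ]
  if (nrow(sig)) {
    print.data.frame(sig[order(sig$p), c("term_id", "name", "n_Q", "p",
                                         "fold")],
                     row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param enrich An `enrichment_table` or `go_enrichment`.
#' @param path Output file.
#' @param header Optional `#` header lines.
#' @export
write_enrichment_table <- function(enrich, path, header = character(0)) {
  tab <- if (inherits(enrich, "go_enrichment")) enrich$table else enrich
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("#", h), con)
  writeLines("#term_id\tname\tn_Q\tnull_mean\tp\tfold\tsignificant", con)
  writeLines(paste(tab$term_id, tab$name, tab$n_Q,
                   sprintf("%.17g", tab$null_mean),
                   sprintf("%.17g", tab$p), tab$fold,
                   as.integer(tab$significant), sep = "\t"), con)
  invisible(path)
}
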