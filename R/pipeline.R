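#' Read a run configuration
#'
#' YAML with per-module sections. Top-level keys: `seed`, `outdir`,
#' `simulate` (logical `enabled` plus [sim_config()] overrides),
#' `inputs` (paths: `sdp`, `qtls`, `descent`, `phenotypes`, `genes`,
#' `obo`, `gaf`, `gc_windows`), `merge` (`covariates`), `enrich`
#' (`n_reps_p`, `n_reps_fdr`, `q`, `pseudocount`, `gene_match`,
#' `namespace`, `whole_ci_comparison`). Missing keys take defaults;
#' referenced input paths must exist.
#'
#' @param path YAML file, or a list already in config shape.
#' @param require_inputs Check the `inputs` paths (skipped when the
#'   simulate stage or an in-memory corpus supplies the data).
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path, require_inputs = TRUE) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- list(seed = 1, outdir = "phyloqtl_run",
              simulate = list(enabled = FALSE),
              inputs = list(),
              merge = list(covariates = character(0)),
              enrich = list(n_reps_p = 5000, n_reps_fdr = 5000, q = 0.10,
                            pseudocount = FALSE, gene_match = FALSE,
                            namespace = "biological_process",
                            whole_ci_comparison = FALSE))
  cfg <- utils::modifyList(def, cfg)
  if (require_inputs && !isTRUE(cfg$simulate$enabled)) {
    need <- c("sdp", "qtls", "descent", "phenotypes", "genes", "obo",
              "gaf", "gc_windows")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "))
    gone <- !vapply(cfg$inputs[need], file.exists, NA)
    if (any(gone)) stop("input file(s) not found: ",
                        paste(unlist(cfg$inputs[need][gone]),
                              collapse = ", "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

## FNV-1a over the serialised config: a short stable fingerprint for
## output headers
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL   # the fingerprint covers the analysis, not paths
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

run_header <- function(cfg) {
  c(paste0("phyloqtl ",
           as.character(utils::packageVersion("phyloqtl"))),
    paste0("seed ", cfg$seed),
    paste0("config ", config_hash(cfg)))
}

#' Pipeline stages
#'
#' The `run` pipeline is the composition of three stages, each usable
#' on its own: segmentation of every QTL CI into tree-consistent
#' intervals, mixed-model merge analysis of those intervals, and the
#' Monte Carlo GO enrichment of the surviving (consistent) intervals.
#'
#' @param sdps Named list of [sdp_matrix()] per chromosome (or a single
#'   one).
#' @param qtls A deduplicated [qtl_table()].
#' @return `stage_segment`: named list (by `qtl_id`) of
#'   `phylo_intervals`.
#' @export
stage_segment <- function(sdps, qtls) {
  if (inherits(sdps, "sdp_matrix")) {
    sdps <- stats::setNames(list(sdps), sdps$chrom)
  }
  out <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    if (is.null(sdps[[q$chrom]])) {
      stop("no SDPs for chromosome ", q$chrom, " (QTL ", q$qtl_id, ")")
    }
    segment_by_compatibility(sdps[[q$chrom]], c(q$ci_start, q$ci_end))
  })
  names(out) <- qtls$qtl_id
  out
}

#' @param segs From [stage_segment()].
#' @param descent Named list of [descent_probs()] per chromosome.
#' @param phen Phenotype data frame (`individual` + one column per
#'   phenotype named in `qtls$phenotype`).
#' @param covariates Covariate column names in `phen`.
#' @param kinship Optional kinship matrix; computed from `descent`
#'   (loci thinned 10-fold) when missing.
#' @rdname stage_segment
#' @return `stage_merge`: list with `results` (rbound `merge_result`),
#'   `vc` (per-phenotype variance components), `kinship`.
#' @export
stage_merge <- function(qtls, segs, descent, phen,
                        covariates = character(0), kinship = NULL) {
  if (inherits(descent, "descent_probs")) {
    descent <- stats::setNames(list(descent), descent$chrom)
  }
  if (is.null(kinship)) {
    acc <- 0; nl <- 0
    for (dp in descent) {
      loci <- seq(1L, n_loci(dp), by = 10L)
      acc <- acc + kinship_from_descent(dp, loci) * length(loci)
      nl <- nl + length(loci)
    }
    kinship <- acc / nl
  }
  X <- if (length(covariates)) {
    cbind(1, as.matrix(phen[, covariates, drop = FALSE]))
  } else NULL
  prep <- reml_prep(kinship, X, n = nrow(phen))
  vcs <- list()
  res <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    ph <- q$phenotype
    if (is.null(phen[[ph]])) stop("phenotype column '", ph, "' missing")
    if (is.null(vcs[[ph]])) {
      vcs[[ph]] <<- reml_variance_components(phen[[ph]], X, kinship,
                                             prep = prep)
    }
    call_consistent_intervals(q, segs[[q$qtl_id]], descent[[q$chrom]],
                              phen[[ph]], X, vcs[[ph]])
  })
  results <- do.call(rbind, res)
  class(results) <- c("merge_result", "data.frame")
  list(results = results, vc = vcs, kinship = kinship)
}

#' @param merge_results `merge_result` rows from [stage_merge()].
#' @param genes,go_index,windows Enrichment inputs.
#' @param enrich_opts List of [go_enrichment()] options (`n_reps_p`,
#'   `n_reps_fdr`, `q`, `pseudocount`, `gene_match`,
#'   `whole_ci_comparison`).
#' @param seed Seed for the null interval banks.
#' @rdname stage_segment
#' @return `stage_enrich`: list with `filtered` (consistent-interval
#'   [go_enrichment()]), and `unfiltered` (whole-CI run) when
#'   requested.
#' @export
stage_enrich <- function(qtls, merge_results, genes, go_index, windows,
                         enrich_opts = list(), seed = 1) {
  eo <- utils::modifyList(
    list(n_reps_p = 5000, n_reps_fdr = 5000, q = 0.10,
         pseudocount = FALSE, gene_match = FALSE,
         whole_ci_comparison = FALSE), enrich_opts)
  cs <- consistent_sets(qtls, merge_results)
  filt <- go_enrichment(cs, genes, go_index, windows,
                        n_reps_p = eo$n_reps_p,
                        n_reps_fdr = eo$n_reps_fdr, q = eo$q,
                        seed = seed, pseudocount = eo$pseudocount,
                        gene_match = eo$gene_match)
  out <- list(filtered = filt, csets = cs)
  if (isTRUE(eo$whole_ci_comparison)) {
    cs_all <- consistent_sets(qtls, whole_ci = TRUE)
    out$unfiltered <- go_enrichment(cs_all, genes, go_index, windows,
                                    n_reps_p = eo$n_reps_p,
                                    n_reps_fdr = eo$n_reps_fdr,
                                    q = eo$q, seed = seed,
                                    pseudocount = eo$pseudocount,
                                    gene_match = eo$gene_match)
  }
  out
}

#' Run the full phylogenetic-filtering pipeline
#'
#' Segmentation, merge analysis and enrichment chained end to end,
#' with all outputs written into a run directory: the tree-consistent
#' intervals (`intervals.bed`), the per-interval merge results
#' (`merge.tsv`), the enrichment table (`enrichment.tsv`), the
#' information-score null histogram (`info_score.tsv`) and a
#' machine-readable `summary.json` (QTL, gene and significant-term
#' counts, information scores and their empirical P). Identical seeds
#' and inputs give byte-identical run directories.
#'
#' @param config A [read_run_config()] config (list or YAML path).
#' @param corpus Optional in-memory [simulate_corpus()] (used instead
#'   of files; implies the simulate stage).
#' @return Invisibly, a list with the stage outputs and the summary.
#' @export
run_full_pipeline <- function(config, corpus = NULL) {
  cfg <- read_run_config(config, require_inputs = is.null(corpus))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- run_header(cfg)
  log <- function(...) message("[phyloqtl] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(corpus) && isTRUE(cfg$simulate$enabled)) {
    log("simulating corpus")
    sc <- cfg$simulate
    sc$enabled <- NULL
    if (is.null(sc$seed)) sc$seed <- cfg$seed
    corpus <- stage("simulate", simulate_corpus(do.call(sim_config, sc)))
  }
  if (!is.null(corpus)) {
    sdps <- corpus$sdps; qtls <- corpus$qtls; descent <- corpus$descent
    phen <- corpus$phenotypes; genes <- corpus$genes
    windows <- corpus$windows; kinship <- corpus$kinship
    od <- file.path(cfg$outdir, "go")
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_obo(corpus$go$terms, file.path(od, "go.obo"))
    write_gaf(corpus$go$annot, file.path(od, "go.gaf"))
    go_index <- build_go_index(file.path(od, "go.obo"),
                               file.path(od, "go.gaf"),
                               namespace = cfg$enrich$namespace)
  } else {
    log("loading inputs")
    inp <- cfg$inputs
    sdps <- stage("load", read_sdp_table(inp$sdp))
    windows <- stage("load", compute_gc_windows(inp$gc_windows))
    qtls <- stage("load", read_qtl_table(inp$qtls,
                                         window_chrom_lengths(windows)))
    descent <- stage("load", read_descent_tsv(inp$descent))
    phen <- stage("load", read_phenotypes(inp$phenotypes))
    genes <- stage("load", read_gene_models(inp$genes))
    go_index <- stage("load", build_go_index(inp$obo, inp$gaf,
                                             namespace = cfg$enrich$namespace,
                                             gene_universe = genes$gene_id))
    kinship <- NULL
  }
  if (inherits(sdps, "sdp_matrix")) {
    sdps <- stats::setNames(list(sdps), sdps$chrom)
  }
  if (inherits(descent, "descent_probs")) {
    descent <- stats::setNames(list(descent), descent$chrom)
  }

  n_qtls_in <- nrow(qtls)
  qtls <- stage("dedupe", dedupe_qtls(qtls))
  log(sprintf("%d QTL(s) after de-duplication (of %d)", nrow(qtls),
              n_qtls_in))

  segs <- stage("segment", stage_segment(sdps, qtls))
  all_int <- do.call(rbind, lapply(names(segs), function(id) {
    s <- segs[[id]]
    s$interval_id <- paste0(id, ":", seq_len(nrow(s)))
    s
  }))
  write_phylo_intervals(all_int, file.path(cfg$outdir, "intervals.bed"),
                        header = hdr)

  log("merge analysis")
  mg <- stage("merge", stage_merge(qtls, segs, descent, phen,
                                   cfg$merge$covariates, kinship))
  write_merge_results(mg$results, file.path(cfg$outdir, "merge.tsv"),
                      header = hdr)

  log("enrichment")
  en <- stage("enrich", stage_enrich(qtls, mg$results, genes, go_index,
                                     windows, cfg$enrich,
                                     seed = cfg$seed + 100))
  write_enrichment_table(en$filtered,
                         file.path(cfg$outdir, "enrichment.tsv"),
                         header = hdr)
  info <- en$filtered$info
  info_tab <- data.frame(score = info$null_scores)
  con <- file(file.path(cfg$outdir, "info_score.tsv"), "w")
  for (h in hdr) writeLines(paste0("#", h), con)
  writeLines(sprintf("#observed_score\t%.17g", info$observed), con)
  writeLines(sprintf("#empirical_P\t%.17g", info$p), con)
  writeLines("#null_score", con)
  writeLines(sprintf("%.17g", info_tab$score), con)
  close(con)

  csets <- en$csets
  genes_ci <- unique(unlist(lapply(seq_len(nrow(qtls)), function(i) {
    genes_in_intervals(genes, qtls$chrom[i], qtls$ci_start[i],
                       qtls$ci_end[i])
  })))
  genes_cons <- unique(unlist(lapply(csets, function(cs) {
    if (!nrow(cs$offsets)) return(character(0))
    genes_in_intervals(genes, cs$chrom, cs$ci_start + cs$offsets[, 1],
                       cs$ci_start + cs$offsets[, 2])
  })))
  sig <- en$filtered$table[which(en$filtered$table$significant), ]
  summary <- list(
    seed = cfg$seed, config = config_hash(cfg),
    n_qtls_input = n_qtls_in, n_qtls = nrow(qtls),
    n_consistent_intervals = sum(mg$results$consistent),
    n_genes_under_ci = length(genes_ci),
    n_genes_under_consistent = length(genes_cons),
    n_significant_terms = nrow(sig),
    significant_terms = sig$term_id,
    information_score = info$observed,
    information_score_P = info$p)
  if (!is.null(en$unfiltered)) {
    summary$information_score_unfiltered <- en$unfiltered$info$observed
    summary$information_score_P_unfiltered <- en$unfiltered$info$p
  }
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done: ", cfg$outdir)
  invisible(list(config = cfg, qtls = qtls, segments = segs, merge = mg,
                 enrichment = en, summary = summary))
}
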