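#' Configuration for the synthetic heterogeneous-stock corpus
#'
#' Defaults emulate a desk-scale heterogeneous stock (HS) study: 8
#' founder strains, two 35 Mb chromosomes, 20 QTLs with 3 Mb 95%
#' confidence intervals (the mapping resolution typical of an HS), 500
#' individuals whose genomes are founder mosaics with ~3 Mb segments,
#' 1,000 genes and 500 background GO terms, one term planted across the
#' causal intervals of 8 carrier QTLs.
#'
#' @param seed RNG seed for the whole corpus.
#' @param K Number of founder strains.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param block_len Range (min, max) of tree-block lengths (bp);
#'   lengths are drawn uniformly.
#' @param variants_per_block Variants emitted per block.
#' @param N Individuals.
#' @param switch_rate Founder-switch rate per bp of the descent mosaic.
#' @param epsilon Blur of the one-hot descent probabilities.
#' @param n_qtls,ci_width QTL count and CI width (bp).
#' @param n_genes,gene_len Gene count and fixed gene length (bp).
#' @param n_terms Background GO terms.
#' @param genes_per_term Mean genes per background term.
#' @param tandem_cluster Assign background terms to runs of adjacent
#'   genes (functionally clustered neighbours) instead of independent
#'   draws.
#' @param planted_term Plant an enriched term (`FALSE` for a fully null
#'   corpus).
#' @param planted_qtls Number of carrier QTLs for the planted term.
#' @param effect_size Planted founder-group effect, in phenotype SD
#'   units.
#' @param h2_background Polygenic background heritability.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, K = 8,
                       chrom_lengths = c(chr1 = 35e6, chr2 = 35e6),
                       block_len = c(1e5, 3e5), variants_per_block = 6,
                       N = 500, switch_rate = 3e-7, epsilon = 0,
                       n_qtls = 20, ci_width = 3e6,
                       n_genes = 1000, gene_len = 2e4, n_terms = 500,
                       genes_per_term = 10, tandem_cluster = FALSE,
                       planted_term = TRUE, planted_qtls = 8,
                       effect_size = 1, h2_background = 0.3) {
  cfg <- list(seed = seed, K = K, chrom_lengths = chrom_lengths,
              block_len = block_len,
              variants_per_block = variants_per_block, N = N,
              switch_rate = switch_rate, epsilon = epsilon,
              n_qtls = n_qtls, ci_width = ci_width, n_genes = n_genes,
              gene_len = gene_len, n_terms = n_terms,
              genes_per_term = genes_per_term,
              tandem_cluster = tandem_cluster,
              planted_term = planted_term, planted_qtls = planted_qtls,
              effect_size = effect_size, h2_background = h2_background)
  stopifnot(K >= 2, N > 0, n_qtls > 0, n_genes > 0, n_terms > 0,
            effect_size >= 0, h2_background >= 0, h2_background < 1,
            variants_per_block > 0)
  class(cfg) <- "sim_config"
  cfg
}

## random laminar family of strain bipartitions (splits of a random
## nested hierarchy); every pair of splits is four-gamete compatible
random_splits <- function(members, K) {
  if (length(members) < 2L) return(list())
  repeat {
    side <- stats::runif(length(members)) < 0.5
    if (any(side) && !all(side)) break
  }
  v <- integer(K)
  v[members[side]] <- 1L
  c(list(v), random_splits(members[side], K),
    random_splits(members[!side], K))
}

#' Generate founder SDPs with planted tree blocks
#'
#' Each chromosome is tiled with blocks of random length; within a
#' block, variants are drawn only from the compatible splits of one
#' random nested strain hierarchy, so all pairs pass the four-gamete
#' test. The first variant of each block is forced to be incompatible
#' with at least one variant of the previous block, so the planted
#' block boundaries are exactly the conflicts a segmentation scan must
#' recover.
#'
#' Uses the current RNG stream (seed it, or call via
#' [simulate_corpus()]).
#'
#' @param config A [sim_config()].
#' @return List with `sdps` (named list of [sdp_matrix()] per
#'   chromosome) and `blocks` (per chromosome: data frame of block
#'   `start`/`end` plus the emitted variant count).
#' @export
gen_founder_sdps <- function(config) {
  K <- config$K
  strains <- paste0("founder", seq_len(K))
  sdps <- list(); blocks <- list()
  for (cc in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[cc]]
    bl <- numeric(0); at <- 0
    while (at < len) {
      w <- stats::runif(1, config$block_len[1], config$block_len[2])
      bl <- c(bl, min(w, len - at)); at <- at + w
    }
    bstart <- cumsum(c(0, bl[-length(bl)])); bend <- cumsum(bl)
    m <- config$variants_per_block
    pos <- NULL; alle <- NULL; prev <- NULL
    for (b in seq_along(bl)) {
      if (bend[b] - bstart[b] < m + 1) {
        stop("block too short for ", m, " variants on ", cc)
      }
      ## a split is "deep" when both sides have >= 2 strains; only deep
      ## splits can cross (fail the 4-gamete test against) another
      ## split, so every block must carry one for adjacent blocks to be
      ## distinguishable
      found <- FALSE
      for (try in 1:500) {
        spl <- random_splits(seq_len(K), K)
        deep <- which(vapply(spl, function(v) {
          min(sum(v), K - sum(v)) >= 2L
        }, NA))
        if (!length(deep)) next
        pick <- sample.int(length(spl), m, replace = TRUE)
        if (!any(pick %in% deep)) {
          pick[sample.int(m, 1L)] <- deep[sample.int(length(deep), 1L)]
        }
        if (!is.null(prev)) {
          conf <- which(vapply(seq_along(spl), function(j) {
            any(vapply(seq_len(nrow(prev)), function(i) {
              !four_gamete_compatible(prev[i, ], spl[[j]])
            }, NA))
          }, NA))
          if (!length(conf)) next
          pick[1L] <- conf[sample.int(length(conf), 1L)]
        }
        A <- do.call(rbind, spl[pick])
        found <- TRUE
        break
      }
      if (!found) stop("could not force a block conflict on ", cc)
      p <- sort(sample(seq.int(floor(bstart[b]) + 1L, floor(bend[b])), m))
      pos <- c(pos, p); alle <- rbind(alle, A); prev <- A
    }
    sdps[[cc]] <- sdp_matrix(cc, pos, alle, strains)
    blocks[[cc]] <- data.frame(start = bstart, end = bend,
                               n_variants = m)
  }
  list(sdps = sdps, blocks = blocks)
}

#' Generate a mosaic HS population with descent probabilities
#'
#' Each individual's chromosome is a Markov mosaic over the K founders:
#' a uniform founder at the left end, switch events at rate
#' `switch_rate` per bp, each switching to a uniformly chosen
#' *different* founder. Descent probabilities at the variant loci are
#' the one-hot truth, optionally blurred by `epsilon` towards uniform.
#'
#' @param config A [sim_config()].
#' @param sdps Named list of [sdp_matrix()] (loci = variant positions).
#' @return List with `descent` (named list of [descent_probs()] per
#'   chromosome) and `n_switches` (per individual, summed over
#'   chromosomes).
#' @export
gen_hs_population <- function(config, sdps) {
  K <- config$K; N <- config$N
  descent <- list()
  nsw <- integer(N)
  for (cc in names(sdps)) {
    len <- config$chrom_lengths[[cc]]
    pos <- sdps[[cc]]$positions
    S <- matrix(0L, N, length(pos))
    for (i in seq_len(N)) {
      k <- stats::rpois(1, config$switch_rate * len)
      nsw[i] <- nsw[i] + k
      bp <- sort(stats::runif(k, 0, len))
      f <- integer(k + 1L)
      f[1] <- sample.int(K, 1L)
      if (k > 0) for (j in seq_len(k)) {
        f[j + 1L] <- sample(setdiff(seq_len(K), f[j]), 1L)
      }
      S[i, ] <- f[findInterval(pos, bp) + 1L]
    }
    descent[[cc]] <- descent_probs(states = S, positions = pos,
                                   chrom = cc, K = K,
                                   epsilon = config$epsilon,
                                   strain_names = sdps[[cc]]$strain_names)
  }
  list(descent = descent, n_switches = nsw)
}

#' Generate phenotypes with a tree-consistent planted QTL effect
#'
#' `y = effect(leaf of the founder carried at the causal locus) +
#' polygenic background (variance `h2_background`, covariance the true
#' kinship) + iid noise (variance `1 - h2_background`)`, so the
#' background SD is 1 and `effect_size` is in SD units. The effect is
#' carried by one leaf of the causal interval's tree (the smallest
#' leaf, the sharpest founder contrast), so founders sharing a leaf
#' receive identical effects and the merged model is true.
#'
#' @param config A [sim_config()].
#' @param population From [gen_hs_population()].
#' @param causal List: `chrom`, `locus` (locus index), `leaf_of_strain`
#'   (0-based labels). `NULL` plants no effect (pure background).
#' @param kinship_chol Cholesky factor (upper) of the true kinship
#'   (+ jitter); computed if missing.
#' @param effect_size Overrides `config$effect_size`.
#' @return List `y` (length N), `effects` (per-strain fixed effect),
#'   `effect_leaf`.
#' @export
gen_phenotypes <- function(config, population, causal = NULL,
                           kinship_chol = NULL,
                           effect_size = config$effect_size) {
  N <- config$N
  h2 <- config$h2_background
  if (is.null(kinship_chol) && h2 > 0) {
    Kin <- kinship_from_descent(population$descent[[1]])
    kinship_chol <- chol(Kin + diag(1e-6, N))
  }
  g <- if (h2 > 0) {
    sqrt(h2) * drop(crossprod(kinship_chol, stats::rnorm(N)))
  } else numeric(N)
  e <- stats::rnorm(N, 0, sqrt(1 - h2))
  eff <- numeric(N); leaf_eff <- NULL; strain_eff <- NULL
  if (!is.null(causal)) {
    leaf <- causal$leaf_of_strain
    L <- max(leaf) + 1L
    if (L < 2L) stop("causal interval has a single leaf: no contrast")
    sizes <- tabulate(leaf + 1L, nbins = L)
    target <- which.min(sizes) - 1L
    strain_eff <- ifelse(leaf == target, effect_size, 0)
    st <- population$descent[[causal$chrom]]$states[, causal$locus]
    eff <- strain_eff[st]
    leaf_eff <- target
  }
  list(y = eff + g + e, effects = strain_eff, effect_leaf = leaf_eff)
}

#' Generate gene models and GO annotation with planted enrichment
#'
#' Genes of fixed length are placed on a non-overlapping slot grid,
#' uniformly at random. Background terms are assigned to random genes
#' (independently, or in `tandem_cluster` mode to runs of adjacent
#' genes, emulating functionally related tandem duplicates). When
#' `csets` is given and `config$planted_term` is `TRUE`, one extra term
#' is annotated to exactly one gene inside the consistent intervals of
#' each carrier QTL (a gene is relocated into the interval when none
#' overlaps it), so the planted term's observed count equals the
#' carrier count by construction.
#'
#' @param config A [sim_config()].
#' @param csets A [consistent_sets()] restricted to the carrier QTLs
#'   (or `NULL` for a fully null annotation).
#' @return List: `genes` (gene-model data frame), `terms` (OBO-ready
#'   table), `annot` (GAF-ready gene/term pairs), `planted`
#'   (term id, carrier QTLs, planted genes; `NULL` when nothing is
#'   planted).
#' @export
gen_gene_annotation <- function(config, csets = NULL) {
  gl <- config$gene_len
  slot_tab <- do.call(rbind, lapply(names(config$chrom_lengths),
    function(cc) {
      ns <- floor(config$chrom_lengths[[cc]] / gl)
      data.frame(chrom = cc, slot = seq_len(ns) - 1L,
                 stringsAsFactors = FALSE)
    }))
  if (config$n_genes > nrow(slot_tab)) {
    stop("more genes than non-overlapping slots at gene_len = ", gl)
  }
  take <- sort(sample.int(nrow(slot_tab), config$n_genes))
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    chrom = slot_tab$chrom[take],
    start = slot_tab$slot[take] * gl,
    end = slot_tab$slot[take] * gl + gl,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  term_ids <- sprintf("GO:%07d", seq_len(config$n_terms))
  annot <- vector("list", config$n_terms)
  for (j in seq_len(config$n_terms)) {
    s <- 1L + stats::rpois(1, config$genes_per_term - 1)
    gs <- if (config$tandem_cluster) {
      picked <- integer(0)
      while (length(picked) < s) {
        g0 <- sample.int(config$n_genes, 1L)
        run <- 1L + stats::rgeom(1L, 1 / 3)
        picked <- unique(c(picked, seq.int(g0, min(g0 + run - 1L,
                                                   config$n_genes))))
      }
      picked[seq_len(s)]
    } else {
      sample.int(config$n_genes, min(s, config$n_genes))
    }
    annot[[j]] <- data.frame(gene = genes$gene_id[gs], term = term_ids[j],
                             stringsAsFactors = FALSE)
  }
  planted <- NULL
  if (!is.null(csets) && isTRUE(config$planted_term)) {
    pt <- sprintf("GO:%07d", config$n_terms + 1L)
    pg <- character(0)
    for (cs in csets) {
      abs_s <- cs$ci_start + cs$offsets[, 1]
      abs_e <- cs$ci_start + cs$offsets[, 2]
      hit <- genes_in_intervals(genes, cs$chrom, abs_s, abs_e)
      if (!length(hit)) {
        ## relocate a spare gene into the widest consistent interval
        wi <- which.max(abs_e - abs_s)
        lo <- ceiling(abs_s[wi] / gl); hi <- floor(abs_e[wi] / gl) - 1L
        if (hi < lo) stop("consistent interval of ", cs$qtl_id,
                          " too narrow to host a gene")
        occ <- genes$start[genes$chrom == cs$chrom] / gl
        free <- setdiff(seq.int(lo, hi), occ)
        if (!length(free)) stop("no free gene slot in ", cs$qtl_id)
        mv <- max(which(!genes$gene_id %in% pg))
        genes$chrom[mv] <- cs$chrom
        genes$start[mv] <- free[1] * gl
        genes$end[mv] <- free[1] * gl + gl
        hit <- genes$gene_id[mv]
      }
      pg <- c(pg, hit[1])
    }
    annot <- c(annot, list(data.frame(gene = pg, term = pt,
                                      stringsAsFactors = FALSE)))
    planted <- list(term = pt, carriers = names(csets), genes = pg)
    term_ids <- c(term_ids, pt)
  }
  terms <- data.frame(id = c("GO:0000000", term_ids),
                      name = c("biological_process",
                               paste0("synthetic process ",
                                      seq_along(term_ids))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  terms$parents <- c(list(character(0)),
                     rep(list("GO:0000000"), length(term_ids)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, terms = terms,
       annot = do.call(rbind, annot), planted = planted)
}

#' Draw synthetic G+C windows
#'
#' Default mode draws per-window GC fractions (clipped normal around
#' 0.42, the mammalian genome-wide mean) rather than computing them
#' from sequence.
#'
#' @param config A [sim_config()].
#' @param window_size Window size in bp.
#' @return A [compute_gc_windows()] table.
#' @export
gen_gc_windows <- function(config, window_size = 1e6) {
  w <- do.call(rbind, lapply(names(config$chrom_lengths), function(cc) {
    len <- config$chrom_lengths[[cc]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + window_size, len),
               gc = pmin(pmax(stats::rnorm(length(starts), 0.42, 0.025),
                              0.30), 0.60),
               stringsAsFactors = FALSE)
  }))
  compute_gc_windows(w)
}

#' Simulate a complete HS corpus with ground truth
#'
#' Chains the generators into a self-consistent corpus: founder SDPs
#' with planted tree blocks, QTL confidence intervals, a mosaic
#' population with descent probabilities and true kinship, one
#' phenotype per QTL (each QTL is a mapped locus and gets a planted
#' leaf effect at the tree interval nearest its CI midpoint), GC
#' windows, and gene/GO annotation with the planted term annotated to
#' one gene in each carrier QTL's causal interval.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_corpus` with elements `sdps`, `qtls`,
#'   `descent`, `kinship`, `phenotypes`, `windows`, `genes`,
#'   `go` (`terms` + `annot`), and `ground_truth`.
#' @export
simulate_corpus <- function(config = sim_config()) {
  set.seed(config$seed)
  fs <- gen_founder_sdps(config)
  pop <- gen_hs_population(config, fs$sdps)

  ## QTLs: evenly spread, disjoint, allocated per chromosome
  chroms <- names(config$chrom_lengths)
  per <- table(rep(chroms, length.out = config$n_qtls))
  qrows <- do.call(rbind, lapply(chroms, function(cc) {
    k <- per[[cc]]
    len <- config$chrom_lengths[[cc]]
    gap <- (len - k * config$ci_width) / (k + 1)
    if (gap < 0) stop("chromosome ", cc, " too short for ", k, " QTLs")
    s <- gap + (seq_len(k) - 1) * (config$ci_width + gap)
    data.frame(chrom = cc, ci_start = floor(s),
               ci_end = floor(s) + config$ci_width,
               stringsAsFactors = FALSE)
  }))
  qtls <- qtl_table(sprintf("qtl%02d", seq_len(nrow(qrows))),
                    sprintf("trait%02d", seq_len(nrow(qrows))),
                    qrows$chrom, qrows$ci_start, qrows$ci_end,
                    peak_logP = NA_real_,
                    chrom_lengths = config$chrom_lengths)

  ## causal interval per QTL: the tree interval at the CI midpoint
  causal <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    seg <- segment_by_compatibility(fs$sdps[[q$chrom]],
                                    c(q$ci_start, q$ci_end))
    mid <- (q$ci_start + q$ci_end) / 2
    j <- which(seg$start <= mid & mid < seg$end)[1]
    if (seg$n_leaves[j] < 2L) j <- which(seg$n_leaves >= 2L)[1]
    memb <- seg$member_variants[[j]]
    pos <- fs$sdps[[q$chrom]]$positions[memb]
    locus <- memb[which.min(abs(pos - (seg$start[j] + seg$end[j]) / 2))]
    list(qtl_id = q$qtl_id, chrom = q$chrom, interval_start = seg$start[j],
         interval_end = seg$end[j], locus = locus,
         leaf_of_strain = seg$leaf_of_strain[[j]])
  })
  names(causal) <- qtls$qtl_id

  carriers <- qtls$qtl_id[seq_len(min(config$planted_qtls,
                                      nrow(qtls)))]
  ## kinship from a thinned locus grid (every 10th variant), then exact
  ## chol for the polygenic background
  kin <- Reduce(`+`, lapply(pop$descent, function(dp) {
    loci <- seq(1L, n_loci(dp), by = 10L)
    kinship_from_descent(dp, loci) * length(loci)
  }))
  nl <- sum(vapply(pop$descent, function(dp)
    length(seq(1L, n_loci(dp), by = 10L)), 0))
  kin <- kin / nl
  kch <- chol(kin + diag(1e-6, config$N))

  ## every QTL is a mapped locus: each gets a leaf-constant effect at
  ## its causal interval (its own phenotype); the planted GO term is
  ## carried only by the carrier subset
  phen <- data.frame(individual = pop$descent[[1]]$individuals,
                     stringsAsFactors = FALSE)
  strain_effects <- list()
  for (i in seq_len(nrow(qtls))) {
    id <- qtls$qtl_id[i]
    ph <- gen_phenotypes(config, pop,
                         causal = if (config$effect_size > 0)
                           causal[[id]],
                         kinship_chol = kch)
    phen[[qtls$phenotype[i]]] <- ph$y
    strain_effects[[id]] <- ph$effects
  }

  windows <- gen_gc_windows(config)
  plant_sets <- consistent_sets(
    qtls[qtls$qtl_id %in% carriers, , drop = FALSE],
    merge_results = data.frame(
      qtl_id = carriers,
      start = vapply(causal[carriers], `[[`, 0, "interval_start"),
      end = vapply(causal[carriers], `[[`, 0, "interval_end"),
      consistent = TRUE, stringsAsFactors = FALSE))
  ann <- gen_gene_annotation(config,
                             csets = if (config$planted_term) plant_sets)

  gt <- list(
    blocks = fs$blocks,
    causal = lapply(causal, function(cz) cz[c("qtl_id", "chrom",
                                              "interval_start",
                                              "interval_end", "locus")]),
    carriers = carriers,
    strain_effects = strain_effects,
    enrichment = ann$planted)
  structure(
    list(config = config, sdps = fs$sdps, qtls = qtls,
         descent = pop$descent, kinship = kin, phenotypes = phen,
         windows = windows, genes = ann$genes,
         go = list(terms = ann$terms, annot = ann$annot),
         ground_truth = gt),
    class = "sim_corpus")
}

#' @exportS3Method base::print
print.sim_corpus <- function(x, ...) {
  cat(sprintf("sim_corpus: %d founders, %d chromosomes, %d variants, %d individuals\n",
              x$config$K, length(x$sdps),
              sum(vapply(x$sdps, function(s) nrow(s$alleles), 0)),
              x$config$N))
  cat(sprintf("  %d QTLs (%d carriers), %d genes, %d GO terms%s\n",
              nrow(x$qtls), length(x$ground_truth$carriers),
              nrow(x$genes), nrow(x$go$terms) - 1L,
              if (!is.null(x$ground_truth$enrichment))
                paste0(", planted term ", x$ground_truth$enrichment$term)
              else ""))
  invisible(x)
}

#' Write a simulated corpus in the package's file dialects
#'
#' Emits `sdp.tsv`, `qtls.tsv`, `descent.tsv`, `phenotypes.tsv`,
#' `genes.bed`, `go.obo`, `go.gaf`, `gc_windows.tsv` and
#' `ground_truth.json` into a directory; every file parses back
#' through the package readers.
#'
#' @param corpus A [simulate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sdp_table(corpus$sdps, file.path(dir, "sdp.tsv"))
  write_qtl_table(corpus$qtls, file.path(dir, "qtls.tsv"))
  write_descent_tsv(corpus$descent, file.path(dir, "descent.tsv"))
  write_phenotypes(corpus$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_gene_models(corpus$genes, file.path(dir, "genes.bed"))
  write_obo(corpus$go$terms, file.path(dir, "go.obo"))
  write_gaf(corpus$go$annot, file.path(dir, "go.gaf"))
  write_gc_windows(corpus$windows, file.path(dir, "gc_windows.tsv"))
  jsonlite::write_json(corpus$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Synthetic per-QTL consistent-interval offsets
#'
#' For enrichment-only studies: gives every QTL a fixed number of
#' equal-width sub-intervals at random offsets inside its CI (sorted,
#' non-overlapping), standing in for merge-analysis output.
#'
#' @param qtls A [qtl_table()].
#' @param n_sub Sub-intervals per QTL.
#' @param frac Width of each sub-interval as a fraction of the CI.
#' @return A [consistent_sets()] object.
#' @export
gen_consistent_offsets <- function(qtls, n_sub = 3, frac = 0.05) {
  cs <- consistent_sets(qtls, whole_ci = TRUE)
  for (i in seq_along(cs)) {
    w <- cs[[i]]$ci_end - cs[[i]]$ci_start
    sw <- floor(frac * w)
    ## place n_sub starts in the gaps of a uniform partition
    slots <- floor(stats::runif(n_sub) * (w / n_sub - sw)) +
      (seq_len(n_sub) - 1) * floor(w / n_sub)
    cs[[i]]$offsets <- cbind(start = slots, end = slots + sw)
  }
  cs
}
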