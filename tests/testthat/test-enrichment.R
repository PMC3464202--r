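## A hand-built geometry used across the counting tests: chr1 of 2 Mb;
## leaf term GO:0000003 on genes gA (100-120 kb) and gB (500-520 kb);
## side-branch term GO:0000004 on gC (1.5-1.52 Mb).
enrich_fixture <- function() {
  obo <- tiny_obo(tempfile(fileext = ".obo"))
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", c("gA", "gB", "gC"), c("gA", "gB", "gC"), "",
                     c("GO:0000003", "GO:0000003", "GO:0000004"),
                     "REF", "IDA", "", "P", "", "", "gene", "taxon:0",
                     "20120101", "DB", sep = "\t")), gaf)
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(100e3, 500e3, 1500e3),
                      end = c(120e3, 520e3, 1520e3), strand = "+",
                      stringsAsFactors = FALSE)
  list(goi = build_go_index(obo, gaf), genes = genes)
}

test_that("empirical p is the fraction of null counts at or above n_Q", {
  fx <- enrich_fixture()
  qtls <- qtl_table(c("q1", "q2"), c("t", "t"), "chr1",
                    c(80e3, 480e3), c(180e3, 580e3))
  csets <- consistent_sets(qtls, whole_ci = TRUE)
  obs <- observed_term_counts(csets, fx$genes, fx$goi)
  expect_equal(unname(obs[["GO:0000003"]]), 2L)   # both QTLs hit
  expect_equal(unname(obs[["GO:0000004"]]), 0L)   # gC untouched
  ## hand-placed null replicates give GO:0000003 counts 0, 1, 1, 2
  place <- function(s1, s2) data.frame(
    qtl_id = c("q1", "q2"), chrom = "chr1", start = c(s1, s2),
    length = 100e3, stringsAsFactors = FALSE)
  nulls <- list(place(900e3, 1000e3), place(90e3, 1000e3),
                place(900e3, 490e3), place(90e3, 490e3))
  tab <- suppressWarnings(
    empirical_pvalues(obs, nulls, csets, fx$genes, fx$goi))
  expect_equal(tab$p[tab$term_id == "GO:0000003"], 1 / 4)
  ## n_Q = 0 always gives p = 1 (every null count is >= 0)
  expect_equal(tab$p[tab$term_id == "GO:0000004"], 1)
  ## pseudocount variant never returns 0
  tabp <- suppressWarnings(
    empirical_pvalues(obs, nulls, csets, fx$genes, fx$goi,
                      pseudocount = TRUE))
  expect_equal(tabp$p[tabp$term_id == "GO:0000003"], (1 + 1) / (1 + 4))
  ## fold enrichment: n_Q over the null mean
  expect_equal(tab$fold[tab$term_id == "GO:0000003"], 2 / 1)
})

test_that("counting is restricted to the consistent sub-intervals", {
  fx <- enrich_fixture()
  ## three QTLs; gene gA in q1's consistent interval, gB inside q2's CI
  ## but OUTSIDE its consistent interval, gC in q3's consistent interval
  qtls <- qtl_table(c("q1", "q2", "q3"), "t", "chr1",
                    c(50e3, 450e3, 1450e3), c(250e3, 650e3, 1650e3))
  mr <- data.frame(qtl_id = c("q1", "q2", "q3"),
                   start = c(90e3, 550e3, 1490e3),
                   end = c(130e3, 600e3, 1530e3),
                   consistent = TRUE, stringsAsFactors = FALSE)
  csets <- consistent_sets(qtls, mr)
  ## term GO:0000003 is on gA and gB; the root term also carries gC
  ## through propagation of the side branch
  obs <- observed_term_counts(csets, fx$genes, fx$goi)
  expect_equal(unname(obs[["GO:0000003"]]), 1L)   # q2's gB ignored
  expect_equal(unname(obs[["GO:0000001"]]), 2L)   # q1 (gA) + q3 (gC)
  ## two genes of one term inside one QTL still count once
  genes2 <- rbind(fx$genes,
                  data.frame(gene_id = "gA2", chrom = "chr1",
                             start = 95e3, end = 98e3, strand = "+"))
  gaf2 <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", c("gA", "gA2"), c("gA", "gA2"), "",
                     "GO:0000003", "REF", "IDA", "", "P", "", "",
                     "gene", "taxon:0", "20120101", "DB", sep = "\t")),
             gaf2)
  goi2 <- build_go_index(tiny_obo(tempfile(fileext = ".obo")), gaf2)
  obs2 <- observed_term_counts(csets, genes2, goi2)
  expect_equal(unname(obs2[["GO:0000003"]]), 1L)
})

test_that("observed counts ignore QTL and gene ordering", {
  fx <- enrich_fixture()
  qtls <- qtl_table(c("q1", "q2", "q3"), "t", "chr1",
                    c(80e3, 480e3, 1480e3), c(180e3, 580e3, 1580e3))
  csets <- consistent_sets(qtls, whole_ci = TRUE)
  obs <- observed_term_counts(csets, fx$genes, fx$goi)
  obs_r <- observed_term_counts(rev(csets), fx$genes[3:1, ], fx$goi)
  expect_equal(obs[sort(names(obs))], obs_r[sort(names(obs_r))])
})

test_that("null sets preserve length, chromosome and GC bin", {
  wt <- toy_windows(c(chr1 = 5e6, chr2 = 5e6))
  qtls <- qtl_table(c("q1", "q2"), "t", c("chr1", "chr2"),
                    c(1e6, 2e6), c(1.4e6, 2.4e6))
  csets <- gen_consistent_offsets(qtls, n_sub = 2, frac = 0.1)
  reps <- sample_null_sets(csets, wt, 100, seed = 9)
  expect_length(reps, 100)
  src_bin <- vapply(csets, function(cs) {
    mid <- (cs$ci_start + cs$ci_end) / 2
    wt$gc_bin[wt$chrom == cs$chrom & wt$start <= mid & mid < wt$end]
  }, 0L)
  chrom_len <- c(chr1 = 5e6, chr2 = 5e6)
  ok_bin <- 0; tot <- 0
  for (r in reps) {
    expect_equal(r$length, unname(qtls$ci_end - qtls$ci_start))
    expect_equal(r$chrom, qtls$chrom)
    for (i in 1:2) {
      ## placements clipped to the chromosome end may leave the
      ## sampled window; every unclipped start stays in the source bin
      if (r$start[i] == chrom_len[[r$chrom[i]]] - r$length[i]) next
      w <- which(wt$chrom == r$chrom[i] & wt$start <= r$start[i] &
                   r$start[i] < wt$end)
      tot <- tot + 1
      ok_bin <- ok_bin + (wt$gc_bin[w] == src_bin[i])
    }
  }
  expect_gte(ok_bin / tot, 0.99)
  ## reproducibility: identical seed, identical draws
  reps2 <- sample_null_sets(csets, wt, 100, seed = 9)
  expect_identical(reps, reps2)
  expect_false(identical(reps,
                         sample_null_sets(csets, wt, 100, seed = 10)))
})

test_that("gene-number matching keeps null gene counts near the source", {
  set.seed(6)
  cfg <- sim_config(seed = 6, chrom_lengths = c(chr1 = 20e6), N = 10,
                    n_qtls = 4, ci_width = 2e6, n_genes = 400,
                    n_terms = 20, planted_term = FALSE)
  ann <- gen_gene_annotation(cfg)
  wt <- toy_windows(c(chr1 = 20e6), window_size = 1e6)
  qtls <- qtl_table(sprintf("q%d", 1:4), "t", "chr1",
                    c(1e6, 6e6, 11e6, 16e6), c(3e6, 8e6, 13e6, 18e6))
  csets <- gen_consistent_offsets(qtls, n_sub = 3, frac = 0.15)
  reps <- sample_null_sets(csets, wt, 40, seed = 2, gene_match = TRUE,
                           genes = ann$genes)
  src <- vapply(csets, function(cs) {
    length(genes_in_intervals(ann$genes, cs$chrom,
                              cs$ci_start + cs$offsets[, 1],
                              cs$ci_start + cs$offsets[, 2]))
  }, 0L)
  frac_ok <- mean(unlist(lapply(reps, function(r) {
    vapply(seq_len(nrow(r)), function(i) {
      cs <- csets[[r$qtl_id[i]]]
      ng <- length(genes_in_intervals(ann$genes, r$chrom[i],
                                      r$start[i] + cs$offsets[, 1],
                                      r$start[i] + cs$offsets[, 2]))
      abs(ng - src[[r$qtl_id[i]]]) <= 0.2 * src[[r$qtl_id[i]]]
    }, NA)
  })))
  expect_gte(frac_ok, 0.8)   # rejection sampling caps at max_tries
})

test_that("FDR threshold follows the null-discovery formula", {
  obs <- c(0.001, 0.002, 0.5)
  null_p <- rbind(c(0.001, 1, 1),
                  c(0.4, 0.45, 1),
                  c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  colnames(null_p) <- c("a", "b", "c")
  fd <- fdr_threshold(obs, null_p, q = 0.10)
  ## at t = 0.002: mean null discoveries 0.2 over 2 observed = 0.1
  expect_equal(fd$t_star, 0.002)
  expect_equal(fd$n_significant, 2)
  expect_equal(fd$table$fdr[fd$table$t == 0.002], 0.1)
  ## no threshold attains the target: zero discoveries
  fd0 <- fdr_threshold(c(0.5, 0.9), null_p[, 1:2], q = 0.05)
  expect_equal(fd0$t_star, 0)
  expect_equal(fd0$n_significant, 0)
  expect_error(fdr_threshold(obs, null_p, q = 0), "q must")
})

test_that("extra-set p-values are computed against the primary bank", {
  bank <- cbind(a = c(0L, 1L, 1L, 2L), b = c(0L, 0L, 0L, 3L))
  extra <- cbind(a = c(2L, 0L), b = c(1L, 4L))
  np <- null_pvalue_matrix(extra, bank)
  expect_equal(unname(np[1, "a"]), 1 / 4)   # one bank count >= 2
  expect_equal(unname(np[2, "a"]), 1)       # every count >= 0
  expect_equal(unname(np[1, "b"]), 1 / 4)
  expect_equal(unname(np[2, "b"]), 0)       # no bank count >= 4
})

test_that("information score sums -log10 p over the hit terms", {
  expect_equal(information_score(c(0.1, 0.01)), 3)
  expect_equal(information_score(c(1, 1, 1)), 0)
  expect_warning(s0 <- information_score(numeric(0)), "empty")
  expect_equal(s0, 0)
  expect_error(information_score(c(0.5, 0)), "pseudocount")
  expect_error(information_score(c(0.5, 1.2)), "lie in")
  ## strictly decreasing in any single p
  set.seed(2)
  p <- runif(10, 0.01, 0.9)
  s <- information_score(p)
  for (j in 1:10) {
    p2 <- p; p2[j] <- min(1, p2[j] + 0.05)
    expect_lt(information_score(p2), s)
  }
})

test_that("an extreme observed score gets rank-0 empirical P", {
  fx <- enrich_fixture()
  set.seed(44)
  ## five QTLs, each with a consistent interval containing a term gene
  genes <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                      start = (0:4) * 4e6 + 1e6,
                      end = (0:4) * 4e6 + 1.02e6, strand = "+",
                      stringsAsFactors = FALSE)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", genes$gene_id, genes$gene_id, "",
                     "GO:0000003", "REF", "IDA", "", "P", "", "",
                     "gene", "taxon:0", "20120101", "DB", sep = "\t")),
             gaf)
  goi <- build_go_index(tiny_obo(tempfile(fileext = ".obo")), gaf)
  qtls <- qtl_table(sprintf("q%d", 1:5), "t", "chr1",
                    (0:4) * 4e6 + 0.5e6, (0:4) * 4e6 + 2.5e6)
  mr <- data.frame(qtl_id = qtls$qtl_id,
                   start = (0:4) * 4e6 + 0.95e6,
                   end = (0:4) * 4e6 + 1.1e6, consistent = TRUE)
  csets <- consistent_sets(qtls, mr)
  wt <- toy_windows(c(chr1 = 20e6), window_size = 1e6)
  obs <- observed_term_counts(csets, genes, goi)
  bank <- sample_null_sets(csets, wt, 150, seed = 3)
  tab <- empirical_pvalues(obs, bank, csets, genes, goi)
  it <- information_score_test(tab)
  expect_equal(it$p, 0)
  expect_equal(it$p_pseudo, 1 / 151)
  expect_gt(it$observed, max(it$null_scores))
})

test_that("enrichment tables are byte-identical under a fixed seed", {
  set.seed(10)
  cfg <- sim_config(seed = 10, chrom_lengths = c(chr1 = 10e6), N = 10,
                    n_qtls = 3, ci_width = 2e6, n_genes = 200,
                    n_terms = 30, planted_term = FALSE)
  ann <- gen_gene_annotation(cfg)
  wt <- toy_windows(c(chr1 = 10e6), window_size = 1e6)
  qtls <- qtl_table(sprintf("q%d", 1:3), "t", "chr1",
                    c(1e6, 4e6, 7e6), c(3e6, 6e6, 9e6))
  set.seed(77); csets <- gen_consistent_offsets(qtls)
  dir <- withr::local_tempdir()
  write_obo(ann$terms, file.path(dir, "o.obo"))
  write_gaf(ann$annot, file.path(dir, "o.gaf"))
  goi <- build_go_index(file.path(dir, "o.obo"), file.path(dir, "o.gaf"))
  e1 <- go_enrichment(csets, ann$genes, goi, wt, n_reps_p = 120,
                      n_reps_fdr = 120, seed = 5)
  f1 <- file.path(dir, "e1.tsv"); f2 <- file.path(dir, "e2.tsv")
  write_enrichment_table(e1, f1)
  e2 <- go_enrichment(csets, ann$genes, goi, wt, n_reps_p = 120,
                      n_reps_fdr = 120, seed = 5)
  write_enrichment_table(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(e1$info$p, e2$info$p)
})
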