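test_that("SDP TSV round-trips and filters non-segregating rows", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#strains: A/J,AKR/J,BALB/cJ,C3H/HeJ,C57BL/6J,CBA/J,DBA/2J,LP/J",
               "chr19\t5474844\t00100000",
               "chr19\t5474900\t00000000",   # non-segregating, dropped
               "chr19\t5480000\t00001111",
               "chr19\t5490000\t01100110"), tsv)
  expect_message(sdp <- read_sdp_table(tsv), "non-segregating")
  expect_s3_class(sdp, "sdp_matrix")
  expect_equal(dim(sdp), c(3L, 8L))
  expect_equal(sdp$strain_names[3], "BALB/cJ")
  ## the private-variant row: exactly one strain carries the alternate
  expect_equal(sum(sdp$alleles[1, ]), 1L)
  expect_equal(which(sdp$alleles[1, ] == 1L), 3L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_sdp_table(sdp, out)
  back <- read_sdp_table(out)
  expect_identical(back$alleles, sdp$alleles)
  expect_identical(back$positions, sdp$positions)
  expect_identical(back$strain_names, sdp$strain_names)
})

test_that("malformed SDP input is rejected with the offending line", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t0101", "chr1\t200\t01N1"), tsv)
  expect_error(read_sdp_table(tsv), "line 2")
  writeLines(c("chr1\t100\t0101", "chr1\t100\t0011"), tsv)
  expect_error(read_sdp_table(tsv), "duplicated")
  writeLines(c("chr1\t100\t0101", "chr1\t200\t011"), tsv)
  expect_error(read_sdp_table(tsv), "equal length")
})

test_that("VCF founder genotypes parse, het/multi-allelic dropped", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "f1", "f2", "f3", "f4", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t1/1",  # het
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2\t0/0", # multi
    "chr1\t400\t.\tT\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/0\t0/0"), vcf)
  msgs <- capture_messages(sdp <- read_sdp_table(vcf))
  expect_match(paste(msgs, collapse = " "), "multi-allelic")
  expect_match(paste(msgs, collapse = " "), "heterozygous")
  expect_equal(dim(sdp), c(2L, 4L))
  expect_equal(sdp$positions, c(100, 400))
  expect_equal(sdp$alleles[1, ], c(0L, 0L, 1L, 1L))
})

test_that("GO index propagates annotations up the DAG (true-path rule)", {
  obo <- tiny_obo(withr::local_tempfile(fileext = ".obo"))
  gaf <- tiny_gaf(withr::local_tempfile(fileext = ".gaf"))
  goi <- build_go_index(obo, gaf)
  ## geneA on leaf -> leaf, mid, root; geneB on mid -> mid, root
  expect_equal(goi$term_genes[["GO:0000003"]], "geneA")
  expect_equal(goi$term_genes[["GO:0000002"]], c("geneA", "geneB"))
  expect_equal(goi$term_genes[["GO:0000001"]], c("geneA", "geneB"))
  expect_equal(lengths(goi$term_genes[c("GO:0000003", "GO:0000002",
                                        "GO:0000001")]),
               c(`GO:0000003` = 1L, `GO:0000002` = 2L,
                 `GO:0000001` = 2L))
  ## obsolete and out-of-namespace terms are absent
  expect_false("GO:0000009" %in% goi$terms$id)
  expect_false("GO:0000008" %in% goi$terms$id)
})

test_that("GO index honours evidence and qualifier filters", {
  obo <- tiny_obo(withr::local_tempfile(fileext = ".obo"))
  gaf <- tiny_gaf(withr::local_tempfile(fileext = ".gaf"))
  goi <- build_go_index(obo, gaf, exclude_iea = TRUE)
  expect_false("geneB" %in% goi$genes)
  rows <- data.frame(gene = c("geneA", "geneC"),
                     term = c("GO:0000003", "GO:0000002"),
                     qual = c("", "NOT"), ev = "IDA")
  gaf2 <- tiny_gaf(withr::local_tempfile(fileext = ".gaf"), rows)
  goi2 <- build_go_index(obo, gaf2)
  expect_false("geneC" %in% goi2$genes)
  ## cyclic ontology is rejected
  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: a",
               "namespace: biological_process", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b",
               "namespace: biological_process", "is_a: GO:1"), cyc)
  expect_error(build_go_index(cyc, gaf), "cycle")
})

test_that("GC windows: decile bins are equally populated and monotone", {
  set.seed(1)
  gcs <- sample(seq(0.30, 0.60, length.out = 100))
  w <- data.frame(chrom = "chr1", start = (0:99) * 1e6,
                  end = (1:100) * 1e6, gc = gcs)
  wt <- compute_gc_windows(w)
  expect_equal(unname(table(wt$gc_bin)), rep(10L, 10),
               ignore_attr = TRUE)
  ## monotone in GC
  o <- order(wt$gc_fraction)
  expect_true(all(diff(wt$gc_bin[o]) >= 0))
})

test_that("GC windows: degenerate and short-chromosome cases warn", {
  w <- data.frame(chrom = "chr1", start = (0:49) * 1e6,
                  end = (1:50) * 1e6, gc = 0.5)
  expect_warning(wt <- compute_gc_windows(w), "degenerate")
  expect_equal(length(unique(wt$gc_bin)), 1L)
  ## sequence-derived GC: GGCCAATT repeats = 0.5, short chromosome
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrS", strrep("GGCCAATT", 1000)), fa)
  expect_warning(ws <- compute_gc_windows(fa), "shorter than one window")
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$gc_fraction, 0.5)
  expect_equal(ws$end, 8000)
})

test_that("GC window TSV round-trips exactly", {
  wt <- toy_windows(c(chr1 = 1e6, chr2 = 5e5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gc_windows(wt, f)
  back <- compute_gc_windows(f)
  expect_equal(back$gc_fraction, wt$gc_fraction)
  expect_equal(back$gc_bin, wt$gc_bin)
  expect_equal(back$start, wt$start)
})

test_that("QTL dedup keeps the smallest CI per overlap component", {
  q <- qtl_table(c("A", "B"), c("t1", "t2"), c("chr1", "chr1"),
                 c(0, 2e6), c(3e6, 4e6))          # widths 3 Mb, 2 Mb
  kept <- dedupe_qtls(q)
  expect_equal(kept$qtl_id, "B")
  ## disjoint QTLs all survive
  q2 <- qtl_table(c("A", "B"), c("t1", "t2"), c("chr1", "chr1"),
                  c(0, 5e6), c(3e6, 8e6))
  expect_equal(nrow(dedupe_qtls(q2)), 2L)
  ## chain A-B-C (A,C disjoint), widths 3 > 2 > 1: component rule
  ## keeps only C; greedy keeps C and A
  q3 <- qtl_table(c("A", "B", "C"), c("t", "t", "t"), rep("chr1", 3),
                  c(0, 2.5e6, 4.4e6), c(3e6, 4.5e6, 5.4e6))
  expect_equal(dedupe_qtls(q3)$qtl_id, "C")
  expect_setequal(dedupe_qtls(q3, method = "greedy")$qtl_id, c("A", "C"))
})

test_that("dedup output is an overlap antichain per chromosome", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 30
    s <- runif(n, 0, 50e6)
    q <- qtl_table(sprintf("q%02d", 1:n), "t",
                   sample(c("chr1", "chr2"), n, TRUE),
                   s, s + runif(n, 1e6, 5e6))
    for (m in c("component", "greedy")) {
      d <- dedupe_qtls(q, method = m)
      for (cc in unique(d$chrom)) {
        dc <- d[d$chrom == cc, ]
        if (nrow(dc) > 1) {
          o <- order(dc$ci_start)
          expect_true(all(dc$ci_start[o][-1] >=
                            dc$ci_end[o][-nrow(dc)]))
        }
      }
    }
  }
})

test_that("QTL tables round-trip through the 1-based TSV dialect", {
  q <- qtl_table(c("q1", "q2"), c("ofa", "epm"), c("chr1", "chr2"),
                 c(1e6, 2e6), c(4e6, 5e6), c(5.2, 7.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_table(q, f)
  back <- read_qtl_table(f)
  expect_equal(back$ci_start, q$ci_start)
  expect_equal(back$ci_end, q$ci_end)
  expect_equal(back$qtl_id, q$qtl_id)
  expect_error(qtl_table("x", "t", "chr1", 5e6, 4e6), "ci_start")
  expect_error(qtl_table("x", "t", "chr1", 1e6, 4e6,
                         chrom_lengths = c(chr1 = 3e6)), "beyond")
})

test_that("gene models read from BED and GFF3, sorted, validated", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr19\t5490000\t5494100\tActb",
               "chr19\t5480000\t5482000\tUpstream"), bed)
  g <- read_gene_models(bed)
  expect_equal(nrow(g), 2L)
  expect_equal(g$gene_id, c("Upstream", "Actb"))  # sorted by start
  expect_equal(g$start[2], 5490000)
  expect_equal(g$end[2], 5494100)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gene:x1;Name=GeneX",
               "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=tx1;Parent=gene:x1",
               "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tParent=tx1"), gff)
  gg <- read_gene_models(gff)
  expect_equal(nrow(gg), 1L)           # only the gene feature
  expect_equal(gg$gene_id, "GeneX")
  expect_equal(gg$start, 1000)         # 0-based internally
  expect_equal(gg$end, 2000)

  f <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(g, f)
  expect_equal(read_gene_models(f), g, ignore_attr = TRUE)
})
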