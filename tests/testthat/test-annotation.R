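make_gene <- function(symbol = "GENE1", chrom = "chr1", strand = "+",
                      tx_start = 10000L, tx_end = 12000L) {
  data.frame(symbol = symbol, transcript_id = paste0("NM_", symbol),
             chrom = chrom, strand = strand, tx_start = tx_start,
             tx_end = tx_end, stringsAsFactors = FALSE)
}

test_that("refGene dumps load with and without the bin column, and BED6 loads", {
  d <- withr::local_tempdir()
  row_nobin <- paste(c("NR_001", "chr1", "+", 10000, 12000, 10000, 12000, 1,
                       "10000,", "12000,", 0, "GENE1", "cmpl", "cmpl", "0,"),
                     collapse = "\t")
  p1 <- file.path(d, "nobin.txt"); writeLines(row_nobin, p1)
  g1 <- load_refgene(p1)
  expect_equal(g1$symbol, "GENE1")
  expect_equal(g1$tx_start, 10000L)
  expect_equal(g1$tx_end, 12000L)
  expect_equal(g1$strand, "+")

  p2 <- file.path(d, "bin.txt")
  writeLines(paste("585", row_nobin, sep = "\t"), p2)
  g2 <- load_refgene(p2)
  expect_equal(g2[, c("symbol", "chrom", "strand", "tx_start", "tx_end")],
               g1[, c("symbol", "chrom", "strand", "tx_start", "tx_end")])

  p3 <- file.path(d, "genes.bed")
  writeLines("chr1\t10000\t12000\tGENE1\t0\t-", p3)
  g3 <- load_refgene(p3)
  expect_equal(g3$strand, "-")
  expect_equal(g3$tx_start, 10000L)

  p4 <- file.path(d, "weird.txt")
  writeLines("a\tb\tc", p4)
  expect_error(load_refgene(p4), "3 columns")
})

test_that("fixture annotation loads with symbol multiplicity preserved", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 5, n_genes = 50)
  ann <- make_annotation(spec, d)
  g <- load_refgene(ann$refgene_path)
  expect_equal(nrow(g), 50)
  expect_equal(g$symbol, ann$genes$symbol)
  expect_equal(g$tx_start, ann$genes$tx_start)
  expect_equal(g$strand, ann$genes$strand)
})

test_that("promoter windows span -upstream to +1 around the TSS, strand-aware", {
  # plus strand: TSS base at tx_start
  p <- promoter_interval(make_gene(strand = "+", tx_start = 10000L), 500L)
  expect_equal(c(p$start, p$end), c(9500L, 10001L))
  expect_equal(p$end - p$start, 501L)
  # minus strand: TSS base at tx_end - 1
  m <- promoter_interval(make_gene(strand = "-", tx_end = 20000L), 500L)
  expect_equal(c(m$start, m$end), c(19999L, 20500L))
  expect_equal(m$end - m$start, 501L)
  # clipped at chromosome start
  cl <- promoter_interval(make_gene(strand = "+", tx_start = 100L), 500L)
  expect_equal(c(cl$start, cl$end), c(0L, 101L))
  # upstream extent is configurable
  w <- promoter_interval(make_gene(strand = "+", tx_start = 10000L), 1000L)
  expect_equal(w$end - w$start, 1001L)
  expect_error(promoter_interval(make_gene(), -1), ">= 0")
})

test_that("promoter windows contain the TSS and mirror under reflection", {
  set.seed(404)
  for (i in 1:200) {
    strand <- sample(c("+", "-"), 1)
    s <- sample.int(1000000L, 1) + 1000L
    g <- make_gene(strand = strand, tx_start = s, tx_end = s + 2000L)
    p <- promoter_interval(g, 500L)
    tss <- if (strand == "+") g$tx_start else g$tx_end - 1L
    expect_equal(p$end - p$start, 501L)
    expect_true(p$start <= tss && tss < p$end)
    # reflect the gene about point P and flip strand: the promoter reflects
    P <- 2000000L
    gr <- make_gene(strand = if (strand == "+") "-" else "+",
                    tx_start = 2L * P - g$tx_end, tx_end = 2L * P - g$tx_start)
    pr <- promoter_interval(gr, 500L)
    expect_equal(pr$start, 2L * P - p$end)
    expect_equal(pr$end, 2L * P - p$start)
  }
})

test_that("gene body is the transcription unit", {
  b <- gene_body_interval(make_gene(tx_start = 10000L, tx_end = 12000L))
  expect_equal(c(b$start, b$end), c(10000L, 12000L))
  d <- withr::local_tempdir()
  p <- file.path(d, "zero.bed")
  writeLines("chr1\t500\t500\tG\t0\t+", p)
  expect_error(load_refgene(p), "length")
})

test_that("feature resolution is case-insensitive, unions isoforms, dedupes", {
  genes <- rbind(make_gene("GENE1", tx_start = 10000L, tx_end = 12000L),
                 make_gene("GENE1", tx_start = 10000L, tx_end = 15000L),
                 make_gene("GENE1", tx_start = 10000L, tx_end = 18000L),
                 make_gene("GENE2", strand = "-", tx_start = 30000L,
                           tx_end = 34000L))
  # 3 isoforms share a TSS: promoter mode gives one deduplicated interval
  rp <- resolve_features("gene1", genes, "promoter")
  expect_equal(rp$features$feature, "gene1_P")   # named after the query as typed
  expect_equal(nrow(rp$features), 1)
  expect_equal(c(rp$features$start, rp$features$end), c(9500L, 10001L))
  # "all" mode equals the brute-force union of promoter and body intervals
  ra <- resolve_features("GENE1", genes, "all")
  brute <- unique(rbind(
    do.call(rbind, lapply(1:3, function(i) promoter_interval(genes[i, ]))),
    do.call(rbind, lapply(1:3, function(i) gene_body_interval(genes[i, ])))))
  got <- ra$features[, c("chrom", "start", "end")]
  expect_equal(got[order(got$start, got$end), ],
               brute[order(brute$start, brute$end), ],
               ignore_attr = TRUE)
  # unmatched names are returned with a warning, not an error
  expect_warning(rb <- resolve_features(c("GENE2", "NOTAGENE"), genes, "all"),
                 "NOTAGENE")
  expect_equal(rb$unmatched, "NOTAGENE")
  expect_equal(rb$features$feature[1], "GENE2_all")
  # all names unmatched is fatal with build advice
  expect_error(suppressWarnings(resolve_features("NOPE", genes, "all")),
               "genome")
  # region suffixes
  expect_equal(resolve_features("GENE2", genes, "gene_body")$features$feature,
               "GENE2_GB")
})

test_that("feature resolution preserves query order and is idempotent", {
  genes <- rbind(make_gene("A", tx_start = 10000L),
                 make_gene("B", tx_start = 50000L, tx_end = 52000L),
                 make_gene("C", tx_start = 90000L, tx_end = 92000L))
  r1 <- resolve_features(c("C", "A", "B"), genes, "gene_body")
  expect_equal(unique(r1$features$feature), c("C_GB", "A_GB", "B_GB"))
  r2 <- resolve_features(c("B", "A", "C"), genes, "gene_body")
  s1 <- r1$features[order(r1$features$feature), ]
  s2 <- r2$features[order(r2$features$feature), ]
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("rmsk dumps and RepeatMasker .out files load grouped by class", {
  d <- withr::local_tempdir()
  rmsk_line <- function(chrom, s, e, name, cls, fam, id)
    paste(c(585, 1000, 10, 5, 2, chrom, s, e, -100, "+", name, cls, fam,
            1, 500, 0, id), collapse = "\t")
  p <- file.path(d, "rmsk.txt")
  writeLines(c(rmsk_line("chr1", 1000, 7000, "L1PA2", "LINE", "L1", 1),
               rmsk_line("chr1", 9000, 9300, "AluY", "SINE", "Alu", 2),
               rmsk_line("chr2", 500, 6500, "L1MA4", "LINE", "L1", 3),
               rmsk_line("chr2", 500, 6500, "L1MA4", "LINE", "L1", 4)), p)
  reps <- load_repeatmasker(p)
  expect_setequal(names(reps), c("LINE", "SINE"))
  expect_equal(nrow(reps$LINE), 2)   # duplicated row collapsed
  expect_equal(nrow(reps$SINE), 1)
  expect_equal(reps$SINE$start, 9000L)

  # .out format: 1-based inclusive coordinates, class before the slash
  out <- file.path(d, "rm.out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family  begin end (left) ID",
    "",
    " 1000   10.0  5.0  2.0  chr1      1001  7000 (0) +  L1PA2  LINE/L1  1 500 (0) 1",
    "  500   12.0  1.0  1.0  chr1      9001  9300 (0) +  AluY   SINE/Alu 1 300 (0) 2"), out)
  reps2 <- load_repeatmasker(out)
  expect_equal(reps2$LINE$start, 1000L)
  expect_equal(reps2$LINE$end, 7000L)
  expect_equal(reps2$SINE$start, 9000L)
})

test_that("repeat-class queries resolve case-insensitively with dedupe", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(seed = 6)
  ann <- make_annotation(spec, d)
  reps <- load_repeatmasker(ann$rmsk_path)
  expect_setequal(names(reps), spec$classes)
  r <- resolve_repeat_features(c("LINE", "SINE"), reps)
  expect_equal(unique(r$features$feature), c("LINE", "SINE"))
  expect_equal(r$unmatched, character(0))
  expect_true(all(r$features$kind == "repeat_class"))
  # lower-case query matches
  rl <- resolve_repeat_features("line", reps)
  expect_equal(unique(rl$features$feature), "LINE")
  # the standard class list resolves with zero unmatched
  rall <- resolve_repeat_features(c("LINE", "SINE", "LTR", "Satellite",
                                    "Low_complexity", "Simple_repeat"), reps)
  expect_equal(rall$unmatched, character(0))
  expect_warning(ru <- resolve_repeat_features(c("LINE", "DNAX"), reps),
                 "DNAX")
  expect_equal(ru$unmatched, "DNAX")
})

test_that("query lists skip blanks and comments", {
  d <- withr::local_tempdir()
  p <- file.path(d, "q.txt")
  writeLines(c("# candidates", "GENE1", "", "  GENE2  ", "#skip"), p)
  expect_equal(read_query_list(p), c("GENE1", "GENE2"))
})
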