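test_that("mean-beta tracks scale betas to 1-1000 and skip missing values", {
  tb <- tiny_table(c(0.811, NA, 0.25), betas_ctl = c(0.5, 0.6, 0.7),
                   start = c(1000L, 1100L, 1200L))
  tr <- mean_beta_track(tb, "exp")
  expect_equal(tr$name, "Mean_beta_d8")
  expect_equal(tr$kind, "mean_beta")
  expect_equal(nrow(tr$lines), sum(!is.na(tb$beta_exp)))
  expect_equal(tr$lines$value[tr$lines$start == 1000L], 811)
  # control group has all three values
  expect_equal(nrow(mean_beta_track(tb, "WT")$lines), 3)
})

test_that("delta tracks stay on the -1..+1 scale and keep zero differences", {
  rec <- data.frame(cgid = c("cg1", "cg2"), chrom = "chrT",
                    start = c(1000L, 1100L), end = c(1001L, 1101L),
                    beta_exp = c(0.40, 0.5), beta_ctl = c(0.555, 0.5),
                    delta = c(-0.155, 0), fdr_q = NA_real_,
                    stringsAsFactors = FALSE)
  tb <- new_meth_comparison(rec, "d8", "WT")
  tr <- delta_track(tb)
  expect_equal(tr$name, "delta_d8vsWT")
  expect_equal(tr$lines$value, c(-0.155, 0))
  # conservation: the track total equals sum(beta_exp) - sum(beta_ctl)
  set.seed(17)
  big <- tiny_table(runif(100), betas_ctl = runif(100),
                    start = sample.int(100000L, 100))
  expect_equal(sum(delta_track(big)$lines$value),
               sum(big$beta_exp) - sum(big$beta_ctl))
})

test_that("FDR tracks keep sub-threshold probes at experimental-group methylation", {
  tb <- tiny_table(c(0.8, 0.3), betas_ctl = c(0.5, 0.5),
                   fdr = c(0.01, 0.2), start = c(1000L, 1100L))
  tr <- fdr_track(tb, 0.05)
  expect_equal(tr$name, "FDR_d8")
  expect_equal(nrow(tr$lines), 1)
  expect_equal(tr$lines$value, 800)
  expect_error(fdr_track(tb, 0), "\\(0, 1\\]")
  expect_error(fdr_track(tb, 1.5), "\\(0, 1\\]")
  # missing FDR values require the explicit flag
  nofdr <- tiny_table(c(0.8, 0.3), start = c(1000L, 1100L))
  expect_error(fdr_track(nofdr), "allow_missing_fdr")
  sent <- fdr_track(nofdr, allow_missing_fdr = TRUE)
  expect_equal(nrow(sent$lines), 0)
})

test_that("an all-nonsignificant table emits exactly the sentinel line", {
  tb <- tiny_table(c(0.8, 0.3, 0.6), betas_ctl = c(0.5, 0.5, 0.5),
                   fdr = c(0.06, 0.5, 0.9), start = c(1000L, 1100L, 1200L))
  tr <- fdr_track(tb, 0.05)
  expect_equal(nrow(tr$lines), 0)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  emit_bedgraph(tr, p)
  expect_identical(readLines(p), "#No FDR significant sites")
})

test_that("FDR-track probes are a subset of delta-track probes at any alpha", {
  set.seed(23)
  tb <- tiny_table(runif(80), betas_ctl = runif(80), fdr = runif(80),
                   start = sample.int(90000L, 80))
  dstarts <- delta_track(tb)$lines$start
  for (alpha in c(0.001, 0.05, 0.5, 0.999)) {
    fstarts <- fdr_track(tb, alpha)$lines$start
    expect_true(all(fstarts %in% dstarts))
  }
  # alpha just under 1 recovers every probe with a present q
  expect_equal(sort(fdr_track(tb, 0.9999999)$lines$start),
               sort(tb$start[!is.na(tb$fdr_q) & tb$fdr_q < 0.9999999]))
})

test_that("bedGraph emission writes a UCSC header and round-trips exactly", {
  tb <- tiny_table(c(0.811), start = 1000L)
  tr <- mean_beta_track(tb, "exp")
  p <- withr::local_tempfile(fileext = ".bedGraph")
  emit_bedgraph(tr, p)
  lines <- readLines(p)
  expect_length(lines, 2)   # header + one data line
  expect_match(lines[1],
               "^track type=bedGraph name=Mean_beta_d8 description=Mean_beta_d8 visibility=full")
  expect_equal(lines[2], "chrT\t1000\t1001\t811.000")
  back <- read_bedgraph(p)
  expect_equal(back, tr$lines[, c("chrom", "start", "end", "value")],
               ignore_attr = TRUE)
  # every data line has 4 tab-separated fields with a numeric value
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 4))
  expect_false(anyNA(as.numeric(vapply(fields, `[`, "", 4))))
})

test_that("delta headers set blue gains, red losses, autoscale; values are signed", {
  rec <- data.frame(cgid = c("cg1", "cg2"), chrom = "chrT",
                    start = c(1000L, 1100L), end = c(1001L, 1101L),
                    beta_exp = c(0.4, 0.7), beta_ctl = c(0.555, 0.5),
                    delta = c(-0.155, 0.2), fdr_q = NA_real_,
                    stringsAsFactors = FALSE)
  tb <- new_meth_comparison(rec, "d8", "WT")
  p <- withr::local_tempfile(fileext = ".bedGraph")
  emit_bedgraph(delta_track(tb), p)
  lines <- readLines(p)
  expect_match(lines[1], "color=0,0,255")
  expect_match(lines[1], "altColor=255,0,0")
  expect_match(lines[1], "autoScale=on")
  expect_equal(lines[2], "chrT\t1000\t1001\t-0.155")
  expect_equal(lines[3], "chrT\t1100\t1101\t+0.200")
})

test_that("track lines sort by natural chromosome order then start", {
  rec <- data.frame(cgid = paste0("cg", 1:4),
                    chrom = c("chr10", "chr2", "chr2", "chrX"),
                    start = c(50L, 900L, 100L, 5L),
                    end = c(51L, 901L, 101L, 6L),
                    beta_exp = rep(0.5, 4), beta_ctl = rep(0.4, 4),
                    delta = rep(0.1, 4), fdr_q = NA_real_,
                    stringsAsFactors = FALSE)
  tb <- new_meth_comparison(rec, "a", "b")
  tr <- mean_beta_track(tb, "exp")
  expect_equal(tr$lines$chrom, c("chr2", "chr2", "chr10", "chrX"))
  expect_equal(tr$lines$start, c(100L, 900L, 50L, 5L))
})

test_that("track emission is byte-deterministic", {
  set.seed(31)
  tb <- tiny_table(runif(50), betas_ctl = runif(50), fdr = runif(50),
                   start = sample.int(60000L, 50))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  emit_bedgraph(delta_track(tb), p1)
  emit_bedgraph(delta_track(tb), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("track sets cover each comparison and deduplicate shared controls", {
  mk <- function(exp, seed) {
    set.seed(seed)
    tiny_table(runif(10), betas_ctl = runif(10), fdr = runif(10),
               start = sample.int(5000L, 10), groups = c(exp, "WT"))
  }
  one <- build_trackset(list(mk("d8", 1)))
  expect_equal(names(one),
               c("Mean_beta_d8", "Mean_beta_WT", "delta_d8vsWT", "FDR_d8"))
  three <- build_trackset(list(mk("d8", 1), mk("d10", 2), mk("d16", 3)))
  expect_length(three, 10)   # 3+1 mean-beta, 3 delta, 3 FDR
  expect_setequal(names(three),
                  c("Mean_beta_d8", "Mean_beta_d10", "Mean_beta_d16",
                    "Mean_beta_WT", "delta_d8vsWT", "delta_d10vsWT",
                    "delta_d16vsWT", "FDR_d8", "FDR_d10", "FDR_d16"))
  expect_error(build_trackset(list()), "at least one")
})

test_that("group names are sanitized in track names", {
  tb <- tiny_table(c(0.5), start = 1000L, groups = c("day 8 (KD)", "WT"))
  expect_equal(mean_beta_track(tb, "exp")$name, "Mean_beta_day8KD")
  expect_equal(delta_track(tb)$name, "delta_day8KDvsWT")
})
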