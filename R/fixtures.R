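# Seeded synthetic-data generator: gene and repeat annotations plus
# differential-methylation tables with a ground-truth manifest, so every
# pipeline stage can be tested without external downloads.
#
# Design: one synthetic chromosome ("chrT") by default keeps sort order
# trivial; genes are packed left to right with gaps wide enough that no
# promoter can reach a neighbouring gene. Beta values are truncated-normal
# draws (only the moments matter to the validation tests, so a beta
# distribution would add nothing).

#' Specify a synthetic dataset
#'
#' Collects all knobs of the generator; the seed fixes every random draw, so
#' two generations from the same spec are byte-identical.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of synthetic genes.
#' @param probes_per_feature Probes placed inside each gene body.
#' @param beta_exp_mean,beta_ctl_mean Per-feature mean beta for the
#'   experimental / control group; either a scalar (all features), a vector
#'   of length `n_genes`, or `NULL` to draw each uniformly from
#'   `c(0.1, 0.9)`.
#' @param beta_sd Probe-level beta noise SD (truncated-normal around the
#'   feature mean).
#' @param n_background Probes placed outside every feature.
#' @param n_significant Probes given an FDR q below 0.05 (the rest get 0.5);
#'   chosen deterministically as the first placed probes.
#' @param classes Repeat classes to simulate.
#' @param n_repeats_per_class Intervals per repeat class.
#' @param chroms Chromosome names (features cycle across them).
#' @param gene_length,gap Gene-body length and inter-gene gap in bp.
#' @param groups Experimental / control group names.
#' @param genome_build Build tag written into outputs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L, probes_per_feature = 10L,
                         beta_exp_mean = NULL, beta_ctl_mean = NULL,
                         beta_sd = 0.05, n_background = 50L,
                         n_significant = 10L,
                         classes = c("LINE", "SINE", "LTR", "Satellite",
                                     "Low_complexity", "Simple_repeat"),
                         n_repeats_per_class = 5L,
                         chroms = "chrT", gene_length = 4000L, gap = 3000L,
                         groups = c("d8", "WT"), genome_build = "hg19") {
  stopifnot(n_genes >= 1L, probes_per_feature >= 1L, beta_sd >= 0,
            gap > 1000L, gene_length > 100L, length(groups) == 2L,
            groups[1] != groups[2])
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 probes_per_feature = as.integer(probes_per_feature),
                 beta_exp_mean = beta_exp_mean, beta_ctl_mean = beta_ctl_mean,
                 beta_sd = beta_sd, n_background = as.integer(n_background),
                 n_significant = as.integer(n_significant),
                 classes = classes,
                 n_repeats_per_class = as.integer(n_repeats_per_class),
                 chroms = chroms, gene_length = as.integer(gene_length),
                 gap = as.integer(gap), groups = groups,
                 genome_build = genome_build),
            class = "fixture_spec")
}

rtrunc01 <- function(n, mean, sd) {
  # rejection sampling of N(mean, sd) truncated to [0,1]
  if (sd == 0) return(rep(pmin(pmax(mean, 0), 1), length.out = n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 1])
  }
  out[seq_len(n)]
}

#' Generate synthetic gene and repeat annotation files
#'
#' Writes a refGene-style dump (with bin column) and an rmsk-style dump, and
#' returns a ground-truth manifest recording every interval so tests can
#' verify the pipeline against constructed truth.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return List: `refgene_path`, `rmsk_path`, `manifest_path`, `genes`
#'   (symbol, transcript, chrom, strand, tx_start, tx_end), `repeats`
#'   (class, chrom, start, end).
#' @export
make_annotation <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  n <- spec$n_genes
  per_chrom <- ceiling(n / length(spec$chroms))
  chrom <- rep(spec$chroms, each = per_chrom)[seq_len(n)]
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  tx_start <- as.integer(spec$gap + (idx_on_chrom - 1L) *
                           (spec$gene_length + spec$gap))
  tx_end <- tx_start + spec$gene_length
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- data.frame(
    symbol = sprintf("GENE%03d", seq_len(n)),
    transcript_id = sprintf("NM_%06d", seq_len(n)),
    chrom = chrom, strand = strand, tx_start = tx_start, tx_end = tx_end,
    stringsAsFactors = FALSE)

  # repeats live on a region beyond the genes of each chromosome
  rep_rows <- list()
  base <- max(tx_end) + 10 * spec$gap
  k <- 0L
  for (cl in spec$classes) {
    for (j in seq_len(spec$n_repeats_per_class)) {
      k <- k + 1L
      s <- base + (k - 1L) * 2000L
      rep_rows[[k]] <- data.frame(class = cl, chrom = spec$chroms[1],
                                  start = as.integer(s),
                                  end = as.integer(s + 500L),
                                  stringsAsFactors = FALSE)
    }
  }
  repeats <- do.call(rbind, rep_rows)

  refgene_path <- file.path(dir, "refgene.txt")
  exon_s <- paste0(genes$tx_start, ",")
  exon_e <- paste0(genes$tx_end, ",")
  writeLines(sprintf("%d\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%d\t%s",
                     0L, genes$transcript_id, genes$chrom, genes$strand,
                     genes$tx_start, genes$tx_end, genes$tx_start,
                     genes$tx_end, 1L, exon_s, exon_e, 0L, genes$symbol),
             refgene_path)

  rmsk_path <- file.path(dir, "rmsk.txt")
  writeLines(sprintf("%d\t%d\t%d\t%d\t%d\t%s\t%d\t%d\t%d\t%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d",
                     0L, 1000L, 0L, 0L, 0L, repeats$chrom, repeats$start,
                     repeats$end, 0L, "+",
                     paste0(repeats$class, "-elem"), repeats$class,
                     repeats$class, 1L, 500L, 0L, seq_len(nrow(repeats))),
             rmsk_path)

  manifest_path <- file.path(dir, "annotation_manifest.tsv")
  manifest <- rbind(
    data.frame(name = genes$symbol, kind = "gene", chrom = genes$chrom,
               start = genes$tx_start, end = genes$tx_end,
               strand = genes$strand, stringsAsFactors = FALSE),
    data.frame(name = repeats$class, kind = "repeat", chrom = repeats$chrom,
               start = repeats$start, end = repeats$end, strand = "+",
               stringsAsFactors = FALSE))
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(refgene_path = refgene_path, rmsk_path = rmsk_path,
       manifest_path = manifest_path, genes = genes, repeats = repeats)
}

.dialect_writers <- list(
  custom = function(truth, groups, path) {
    df <- data.frame(Chromosome = truth$chrom, Start = truth$pos1,
                     cgid = truth$cgid, stringsAsFactors = FALSE)
    df[[paste0("mean.", groups[1])]] <- truth$beta_exp
    df[[paste0("mean.", groups[2])]] <- truth$beta_ctl
    df$diff <- truth$delta
    df$fdr <- truth$fdr_q
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  },
  rnbeads = function(truth, groups, path) {
    df <- data.frame(cgid = truth$cgid, Chromosome = truth$chrom,
                     Start = truth$pos1, stringsAsFactors = FALSE)
    df[[paste0("mean.", groups[1])]] <- truth$beta_exp
    df[[paste0("mean.", groups[2])]] <- truth$beta_ctl
    df$mean.diff <- truth$delta
    df$diffmeth.p.adj.fdr <- truth$fdr_q
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  },
  champ = function(truth, groups, path) {
    df <- data.frame(cgid = truth$cgid, CHR = sub("^chr", "", truth$chrom),
                     MAPINFO = truth$pos1, stringsAsFactors = FALSE)
    df[[paste0(groups[1], "_AVG")]] <- truth$beta_exp
    df[[paste0(groups[2], "_AVG")]] <- truth$beta_ctl
    df$deltaBeta <- truth$delta
    df$adj.P.Val <- truth$fdr_q
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  })

#' Generate synthetic differential-methylation tables with ground truth
#'
#' Places `probes_per_feature` probes at distinct positions inside each gene
#' body, plus background probes outside every feature, draws per-group beta
#' values from truncated normals around the per-feature means, constructs
#' the FDR column so that a known probe subset passes 0.05, and writes one
#' file per requested dialect encoding the same records.
#'
#' @param spec A [fixture_spec()].
#' @param annotation Result of [make_annotation()] on the same spec.
#' @param dir Output directory.
#' @param dialects Dialects to emit (any of `"custom"`, `"rnbeads"`,
#'   `"champ"`).
#' @return List: `paths` (named by dialect), `truth` (ground-truth record
#'   data frame with `cgid`, `chrom`, `pos1` (1-based), `feature` (gene
#'   symbol or `NA` for background), `beta_exp`, `beta_ctl`, `delta`,
#'   `fdr_q`, `significant`), `feature_means` (per-gene specified means).
#' @export
make_tables <- function(spec, annotation, dir,
                        dialects = c("custom", "rnbeads", "champ")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dialects <- match.arg(dialects, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)

  genes <- annotation$genes
  n <- nrow(genes)
  expand <- function(x) {
    if (is.null(x)) stats::runif(n, 0.1, 0.9) else rep(x, length.out = n)
  }
  mu_exp <- expand(spec$beta_exp_mean)
  mu_ctl <- expand(spec$beta_ctl_mean)

  rows <- list()
  for (i in seq_len(n)) {
    k <- spec$probes_per_feature
    pos0 <- genes$tx_start[i] +
      sort(sample.int(genes$tx_end[i] - genes$tx_start[i], k)) - 1L
    rows[[i]] <- data.frame(
      chrom = genes$chrom[i], pos0 = pos0, feature = genes$symbol[i],
      beta_exp = rtrunc01(k, mu_exp[i], spec$beta_sd),
      beta_ctl = rtrunc01(k, mu_ctl[i], spec$beta_sd),
      stringsAsFactors = FALSE)
  }
  if (spec$n_background > 0L) {
    # background probes go far beyond genes and repeats
    far <- max(annotation$repeats$end) + 100000L
    pos0 <- far + sort(sample.int(10000000L, spec$n_background))
    rows[[n + 1L]] <- data.frame(
      chrom = spec$chroms[1], pos0 = pos0, feature = NA_character_,
      beta_exp = rtrunc01(spec$n_background, 0.5, 0.2),
      beta_ctl = rtrunc01(spec$n_background, 0.5, 0.2),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order_genomic(truth$chrom, truth$pos0), , drop = FALSE]
  truth$cgid <- sprintf("cg%08d", seq_len(nrow(truth)))
  truth$pos1 <- truth$pos0 + 1L
  truth$delta <- truth$beta_exp - truth$beta_ctl
  nsig <- min(spec$n_significant, nrow(truth))
  truth$significant <- seq_len(nrow(truth)) <= nsig
  truth$fdr_q <- ifelse(truth$significant, 0.01, 0.5)
  rownames(truth) <- NULL

  paths <- character(0)
  for (d in dialects) {
    p <- file.path(dir, paste0("table_", d, if (d == "champ") ".tsv" else ".csv"))
    .dialect_writers[[d]](truth, spec$groups, p)
    paths[d] <- p
  }

  list(paths = paths, truth = truth,
       feature_means = data.frame(symbol = genes$symbol, mu_exp = mu_exp,
                                  mu_ctl = mu_ctl, stringsAsFactors = FALSE))
}
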