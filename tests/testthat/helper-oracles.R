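# Independent oracles and small in-code fixtures shared across tests.

# Quadratic all-pairs overlap scan: the reference for probe-feature
# assignment. Intentionally naive and independent of the package's
# GenomicRanges-based implementation.
brute_assign <- function(table, features) {
  rows <- list()
  for (f in unique(features$feature)) {
    ivs <- features[features$feature == f, , drop = FALSE]
    for (i in seq_len(nrow(table))) {
      hit <- FALSE
      for (j in seq_len(nrow(ivs))) {
        if (table$chrom[i] == ivs$chrom[j] &&
            table$start[i] < ivs$end[j] && table$end[i] > ivs$start[j]) {
          hit <- TRUE; break
        }
      }
      if (hit) rows[[length(rows) + 1L]] <- data.frame(
        feature = f, cgid = table$cgid[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(feature = character(0),
                                       cgid = character(0)))
  do.call(rbind, rows)
}

# First-principles summary statistics on scaled values: median by sorting,
# sample SD from the definition.
brute_stats <- function(scaled) {
  n <- length(scaled)
  s <- sort(scaled)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  m <- sum(s) / n
  sdv <- if (n > 1) sqrt(sum((s - m)^2) / (n - 1)) else 0
  list(median = med, mean = m, sd = sdv, max = s[n], min = s[1])
}

# Build a small meth_comparison directly in code.
tiny_table <- function(betas_exp, betas_ctl = rev(betas_exp),
                       fdr = rep(NA_real_, length(betas_exp)),
                       chrom = "chrT", start = NULL,
                       groups = c("d8", "WT")) {
  n <- length(betas_exp)
  if (is.null(start)) start <- seq(1000L, by = 100L, length.out = n)
  rec <- data.frame(
    cgid = sprintf("cg%08d", seq_len(n)),
    chrom = rep(chrom, length.out = n), start = as.integer(start),
    end = as.integer(start) + 1L,
    beta_exp = betas_exp, beta_ctl = betas_ctl,
    delta = betas_exp - betas_ctl, fdr_q = fdr,
    stringsAsFactors = FALSE)
  new_meth_comparison(rec, groups[1], groups[2])
}

# Feature set literal.
tiny_features <- function(feature, chrom, start, end, kind = "gene_body") {
  structure(data.frame(feature = feature, kind = kind, chrom = chrom,
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("feature_set", "data.frame"))
}

# Write a custom-dialect table file from a data frame of 1-based rows.
write_custom_table <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

sorted_pairs <- function(asg) {
  asg <- asg[order(asg$feature, asg$cgid), c("feature", "cgid")]
  rownames(asg) <- NULL
  asg
}
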