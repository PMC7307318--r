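# Probe-to-feature assignment by genomic-interval overlap.
#
# Probes are strandless 1-bp (or 2-bp) half-open intervals; a probe belongs
# to a feature iff it overlaps any of the feature's intervals by >= 1 bp, and
# counts at most once per feature however many of that feature's intervals
# it hits. The overlap engine is GenomicRanges::findOverlaps.

#' Assign probes to features by interval overlap
#'
#' @param table A `meth_comparison`.
#' @param features A `feature_set` (from [resolve_features()] or
#'   [resolve_repeat_features()]), or the list those functions return.
#' @param genome_build Optional build tag of the feature set; a mismatch with
#'   the table's tag produces a warning, not an error.
#' @return Data frame of assignments: `feature`, `cgid`, one row per unique
#'   (feature, probe) pair, ordered by feature (query order) then probe
#'   position.
#' @export
assign_probes <- function(table, features, genome_build = NULL) {
  if (is.list(features) && !is.data.frame(features) && "features" %in% names(features))
    features <- features$features
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("empty feature set", call. = FALSE)
  if (!is.null(genome_build) &&
      !identical(genome_build, attr(table, "genome_build")))
    warning(sprintf("genome build mismatch: table %s vs features %s",
                    attr(table, "genome_build"), genome_build), call. = FALSE)

  probe_gr <- GenomicRanges::GRanges(
    seqnames = table$chrom,
    ranges = IRanges::IRanges(start = table$start + 1L, end = table$end))
  feat_gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end))

  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(probe_gr, feat_gr, minoverlap = 1L,
                                ignore.strand = TRUE))
  asg <- unique(data.frame(
    feature = features$feature[S4Vectors::subjectHits(hits)],
    cgid = table$cgid[S4Vectors::queryHits(hits)],
    .probe_row = S4Vectors::queryHits(hits),
    stringsAsFactors = FALSE))

  feat_order <- match(asg$feature, unique(features$feature))
  asg <- asg[order(feat_order, table$start[asg$.probe_row]), , drop = FALSE]
  rownames(asg) <- NULL
  attr(asg, "feature_names") <- unique(features$feature)
  asg
}

#' Per-feature probe coverage counts
#'
#' @param assignments Assignment data frame from [assign_probes()].
#' @param feature_names Optional character vector of all queried feature
#'   names (defaults to the attribute stored on the assignments); features
#'   with no assigned probe are reported with count 0.
#' @return Named integer vector of probe counts, in query order.
#' @export
coverage_counts <- function(assignments, feature_names = NULL) {
  if (is.null(feature_names)) feature_names <- attr(assignments, "feature_names")
  if (is.null(feature_names)) feature_names <- unique(assignments$feature)
  counts <- table(factor(assignments$feature, levels = feature_names))
  stats::setNames(as.integer(counts), feature_names)
}

#' Dump assignments as BED for debugging
#'
#' Writes one BED line per (feature, probe) pair with the feature name in the
#' name column.
#'
#' @param assignments Assignments from [assign_probes()].
#' @param table The `meth_comparison` the assignments came from.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_assignment_bed <- function(assignments, table, path) {
  i <- match(assignments$cgid, table$cgid)
  lines <- sprintf("%s\t%d\t%d\t%s", table$chrom[i], table$start[i],
                   table$end[i], assignments$feature)
  writeLines(lines, path)
  invisible(path)
}
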