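# bedGraph track construction and emission.
#
# Three track kinds per comparison:
#   mean_beta : absolute methylation per probe, beta x 1000 (1..1000 scale)
#   delta     : beta difference on the -1..+1 scale (blue gain / red loss)
#   fdr       : probes passing the FDR threshold, shown at the experimental
#               group's absolute methylation (p-values would not scale)
# Coordinates are 0-based half-open per the UCSC bedGraph standard.

FDR_SENTINEL <- "#No FDR significant sites"

new_track <- function(name, kind, lines) {
  name <- sanitize_name(name)
  if (!nzchar(name)) stop("empty track name", call. = FALSE)
  if (nrow(lines)) {
    o <- order_genomic(lines$chrom, lines$start)
    lines <- lines[o, , drop = FALSE]
    rownames(lines) <- NULL
  }
  structure(list(name = name, kind = kind, lines = lines),
            class = "meth_track")
}

#' @export
print.meth_track <- function(x, ...) {
  cat(sprintf("<meth_track> %s (%s): %d line(s)\n", x$name, x$kind,
              nrow(x$lines)))
  invisible(x)
}

.track_lines <- function(table, value, keep = rep(TRUE, nrow(table))) {
  keep <- keep & !is.na(value)
  data.frame(chrom = table$chrom[keep], start = table$start[keep],
             end = table$end[keep], value = value[keep],
             stringsAsFactors = FALSE)
}

#' Absolute-methylation (mean beta) track for one group
#'
#' One line per probe with a present beta for the group, at beta x 1000;
#' covers every probe in the table, not only the queried features, so the
#' genomic context around candidates stays visible.
#'
#' @param table A `meth_comparison`.
#' @param group `"exp"` or `"ctl"`, or a stored group name.
#' @return A `meth_track` named `Mean_beta_<group>`.
#' @export
mean_beta_track <- function(table, group = c("exp", "ctl")) {
  gexp <- attr(table, "group_exp"); gctl <- attr(table, "group_ctl")
  group <- if (group[1] %in% c("exp", "ctl")) match.arg(group)
           else if (identical(group[1], gexp)) "exp"
           else if (identical(group[1], gctl)) "ctl"
           else stop("unknown group label: ", group[1], call. = FALSE)
  beta <- if (group == "exp") table$beta_exp else table$beta_ctl
  gname <- if (group == "exp") gexp else gctl
  new_track(paste0("Mean_beta_", sanitize_name(gname)), "mean_beta",
            .track_lines(table, scale_to_thousand(beta)))
}

#' Differential-methylation (delta) track
#'
#' One line per probe at the beta-scale difference experimental minus
#' control, from -1 (complete loss) to +1 (complete gain); zero differences
#' are retained so that even the smallest changes are shown. Rendering uses
#' blue for gains, red for losses, autoscaled to the largest change in view.
#'
#' @param table A `meth_comparison`.
#' @return A `meth_track` named `delta_<exp>vs<ctl>`.
#' @export
delta_track <- function(table) {
  delta <- ifelse(is.na(table$delta),
                  table$beta_exp - table$beta_ctl, table$delta)
  new_track(paste0("delta_", comparison_id(table)), "delta",
            .track_lines(table, delta))
}

#' FDR-filtered significance track
#'
#' Keeps only probes whose FDR-adjusted p-value falls below `alpha` and shows
#' them at the experimental group's absolute methylation (beta x 1000), since
#' p-values themselves would not scale correctly for display. When no probe
#' passes, the emitted file consists solely of the comment line
#' `#No FDR significant sites`.
#'
#' @param table A `meth_comparison`; its `fdr_q` column must be present
#'   unless `allow_missing_fdr = TRUE`.
#' @param alpha FDR threshold in (0,1\], default 0.05.
#' @param allow_missing_fdr Permit a table with no FDR values (the track then
#'   degenerates to the sentinel).
#' @return A `meth_track` named `FDR_<exp>` (possibly with zero lines).
#' @export
fdr_track <- function(table, alpha = 0.05, allow_missing_fdr = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (all(is.na(table$fdr_q)) && !allow_missing_fdr)
    stop("table has no FDR values; pass allow_missing_fdr = TRUE to emit ",
         "the sentinel track anyway", call. = FALSE)
  pass <- !is.na(table$fdr_q) & table$fdr_q < alpha
  new_track(paste0("FDR_", sanitize_name(attr(table, "group_exp"))), "fdr",
            .track_lines(table, scale_to_thousand(table$beta_exp), keep = pass))
}

.track_header <- function(track) {
  base <- sprintf("track type=bedGraph name=%s description=%s visibility=full",
                  track$name, track$name)
  attrs <- switch(track$kind,
    delta = "color=0,0,255 altColor=255,0,0 autoScale=on",
    mean_beta = "color=49,49,49 autoScale=on",
    fdr = "color=0,128,0 autoScale=on")
  paste(base, attrs)
}

.format_value <- function(value, kind) {
  if (kind == "delta") sprintf("%+.3f", value) else sprintf("%.3f", value)
}

#' Write a track as a bedGraph file
#'
#' Emits the UCSC `track` header line followed by sorted
#' `chrom start end value` data lines (0-based half-open; values formatted
#' with 3 decimals, signed for delta tracks). An FDR track with no passing
#' probe is written as the single sentinel comment line.
#'
#' @param track A `meth_track`.
#' @param path Output path; a `.gz` extension gzip-compresses the file.
#' @return `path`, invisibly.
#' @export
emit_bedgraph <- function(track, path) {
  lines <- track$lines
  if (nrow(lines)) {
    o <- order_genomic(lines$chrom, lines$start)
    if (!identical(o, seq_len(nrow(lines))))
      stop("internal error: track lines not sorted", call. = FALSE)
    same <- lines$chrom[-1] == lines$chrom[-nrow(lines)]
    if (nrow(lines) > 1L && any(same & lines$start[-1] < lines$end[-nrow(lines)]))
      stop("internal error: overlapping track lines", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (track$kind == "fdr" && nrow(lines) == 0L) {
    writeLines(FDR_SENTINEL, con)
    return(invisible(path))
  }
  writeLines(c(.track_header(track),
               sprintf("%s\t%d\t%d\t%s", lines$chrom, lines$start, lines$end,
                       .format_value(lines$value, track$kind))), con)
  invisible(path)
}

#' Read a bedGraph file back into its data lines
#'
#' Round-trip helper (and verifier) for files written by [emit_bedgraph()];
#' header and comment lines are skipped.
#'
#' @param path bedGraph file path.
#' @return Data frame `chrom`, `start`, `end`, `value` (zero rows for a
#'   sentinel-only file).
#' @export
read_bedgraph <- function(path) {
  con <- .open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  data_lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(data_lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  m <- do.call(rbind, strsplit(data_lines, "\t", fixed = TRUE))
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), value = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Build the full track set for one or more comparisons
#'
#' Per comparison: `Mean_beta_<exp>`, `Mean_beta_<ctl>`,
#' `delta_<exp>vs<ctl>`, `FDR_<exp>`. A control group shared across
#' comparisons contributes its mean-beta track once, so a 3-vs-1 batch
#' yields 10 tracks.
#'
#' @param tables List of `meth_comparison` objects (e.g. from
#'   [read_meth_batch()]).
#' @param alpha FDR threshold for the FDR tracks.
#' @param allow_missing_fdr Passed to [fdr_track()].
#' @return Named list of `meth_track` objects; names are the track names.
#' @export
build_trackset <- function(tables, alpha = 0.05, allow_missing_fdr = FALSE) {
  if (length(tables) < 1L) stop("at least one comparison table required", call. = FALSE)
  tracks <- list()
  add <- function(tr) {
    if (!is.null(tracks[[tr$name]]))
      stop("internal error: duplicate track name ", tr$name, call. = FALSE)
    tracks[[tr$name]] <<- tr
  }
  seen_groups <- character(0)
  for (tb in tables) {
    for (g in c("exp", "ctl")) {
      gname <- sanitize_name(attr(tb, if (g == "exp") "group_exp" else "group_ctl"))
      if (!gname %in% seen_groups) {
        add(mean_beta_track(tb, g))
        seen_groups <- c(seen_groups, gname)
      }
    }
    add(delta_track(tb))
    add(fdr_track(tb, alpha, allow_missing_fdr))
  }
  tracks
}
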