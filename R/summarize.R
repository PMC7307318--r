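# Per-feature, per-group summary statistics on the 1-1000 display scale.

#' Scale a beta fraction to the 1-1000 display scale
#'
#' Array methylation is displayed as a number from 1 (no methylation) to
#' 1000 (fully methylated); internally this is just beta x 1000, unrounded
#' (3 decimals are applied only at output formatting).
#'
#' @param beta Numeric vector of beta fractions in \[0,1\].
#' @return `beta * 1000`.
#' @export
scale_to_thousand <- function(beta) {
  v <- beta[!is.na(beta)]
  if (any(v < 0 | v > 1))
    stop("beta values must lie in [0,1]", call. = FALSE)
  beta * 1000
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert a 1-1000 scaled value to percent methylation
#'
#' @param scaled Numeric vector in \[0,1000\].
#' @param digits Decimal places (default 1); rounding is half-away-from-zero.
#' @return Percent methylation, `scaled / 10` rounded.
#' @export
to_percent <- function(scaled, digits = 1L) {
  v <- scaled[!is.na(scaled)]
  if (any(v < 0 | v > 1000))
    stop("scaled values must lie in [0,1000]", call. = FALSE)
  round_half_up(scaled / 10, digits)
}

#' Percent difference between two scaled group medians
#'
#' E.g. per-group scaled medians 666.142 and 641.100 give a difference of
#' 25.042/1000 = 2.5 percent.
#'
#' @param median_a,median_b Scaled (1-1000) values, typically per-group
#'   medians of the same feature.
#' @return `(median_a - median_b) / 10` rounded half-away-from-zero to one
#'   decimal; the sign is preserved.
#' @export
group_difference_percent <- function(median_a, median_b) {
  if (any(c(median_a, median_b) < 0) || any(c(median_a, median_b) > 1000))
    stop("scaled medians must lie in [0,1000]", call. = FALSE)
  round_half_up((median_a - median_b) / 10, 1L)
}

#' Render a delta-track value as a percent change
#'
#' Delta tracks stay on the -1..+1 beta scale; for reporting, -0.155 is a
#' 15.5 percent loss.
#'
#' @param delta Beta-scale difference(s) in \[-1,1\].
#' @param digits Decimal places (default 1).
#' @return `delta * 100` rounded half-away-from-zero.
#' @export
delta_percent <- function(delta, digits = 1L) {
  v <- delta[!is.na(delta)]
  if (any(v < -1 | v > 1))
    stop("delta values must lie in [-1,1]", call. = FALSE)
  round_half_up(delta * 100, digits)
}

#' Summarize one group's methylation over the queried features
#'
#' For every queried feature (in query order) computes the probe count and
#' the median, mean, sample standard deviation, maximum and minimum of the
#' chosen group's beta values over the assigned probes, on the 1-1000 scale.
#' Probes with a missing beta for the group are excluded from the statistics
#' but not from the probe count. Features with zero assigned probes are kept
#' with `NA` statistics so coverage remains visible.
#'
#' @param table A `meth_comparison`.
#' @param assignments Assignments from [assign_probes()] on this table.
#' @param group `"exp"` or `"ctl"`, or the group's name as stored on the
#'   table.
#' @return Data frame with columns `feature`, `probes`, `median`, `mean`,
#'   `sd`, `max`, `min` and attribute `group` (the group name).
#' @export
summarize_group <- function(table, assignments, group = c("exp", "ctl")) {
  gexp <- attr(table, "group_exp"); gctl <- attr(table, "group_ctl")
  group <- if (group[1] %in% c("exp", "ctl")) match.arg(group)
           else if (identical(group[1], gexp)) "exp"
           else if (identical(group[1], gctl)) "ctl"
           else stop("unknown group label: ", group[1], call. = FALSE)
  beta_col <- if (group == "exp") "beta_exp" else "beta_ctl"
  gname <- if (group == "exp") gexp else gctl

  feat_names <- attr(assignments, "feature_names")
  if (is.null(feat_names)) feat_names <- unique(assignments$feature)

  rows <- lapply(feat_names, function(f) {
    ids <- assignments$cgid[assignments$feature == f]
    betas <- table[[beta_col]][match(ids, table$cgid)]
    n <- length(ids)
    vals <- scale_to_thousand(betas[!is.na(betas)])
    if (length(vals) == 0L) {
      data.frame(feature = f, probes = n, median = NA_real_, mean = NA_real_,
                 sd = NA_real_, max = NA_real_, min = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(feature = f, probes = n,
                 median = stats::median(vals),
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 max = max(vals), min = min(vals),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group") <- gname
  out
}

#' Write a feature-summary table as TSV
#'
#' Header `Feature Probes Median Mean SD Max Min`; scaled statistics are
#' formatted with 3 decimals; zero-probe features carry empty cells.
#'
#' @param summary Data frame from [summarize_group()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(summary, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  lines <- c(paste(c("Feature", "Probes", "Median", "Mean", "SD", "Max", "Min"),
                   collapse = "\t"),
             sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s",
                     summary$feature, summary$probes, fmt(summary$median),
                     fmt(summary$mean), fmt(summary$sd), fmt(summary$max),
                     fmt(summary$min)))
  writeLines(lines, path)
  invisible(path)
}
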