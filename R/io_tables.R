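# Canonical probe-record columns, in order. Coordinates are held internally
# as 0-based half-open; input positions are 1-based (R-ecosystem convention).
.record_cols <- c("cgid", "chrom", "start", "end",
                  "beta_exp", "beta_ctl", "delta", "fdr_q")

#' Default column maps for the supported table dialects
#'
#' Export column names drift between package versions, so each dialect's
#' defaults can be overridden through the `column_map` argument of
#' [read_meth_table()]. Per-group mean columns are matched by pattern
#' (`mean.<group>` for rnbeads/custom, `<group>_AVG` for champ) and supply
#' the group names.
#'
#' @param dialect One of `"rnbeads"`, `"champ"`, `"custom"`.
#' @return Named list mapping roles (`cgid`, `chrom`, `start`, `delta`,
#'   `fdr`, `group_mean_pattern`) to column names / regexes.
#' @export
default_column_map <- function(dialect) {
  dialect <- match.arg(dialect, c("rnbeads", "champ", "custom"))
  switch(dialect,
    rnbeads = list(cgid = "cgid", chrom = "Chromosome", start = "Start",
                   delta = "mean.diff", fdr = "diffmeth.p.adj.fdr",
                   group_mean_pattern = "^mean\\.(.+)$"),
    champ   = list(cgid = NA_character_, chrom = "CHR", start = "MAPINFO",
                   delta = "deltaBeta", fdr = "adj.P.Val",
                   group_mean_pattern = "^(.+)_AVG$"),
    custom  = list(cgid = "cgid", chrom = "Chromosome", start = "Start",
                   delta = NA_character_, fdr = NA_character_,
                   group_mean_pattern = "^mean\\.(.+)$")
  )
}

# Normalize chromosome names: bare 1..22/X/Y/M/MT get a "chr" prefix,
# "chrMT" becomes "chrM". Anything else is returned as-is (prefixed if bare).
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^MT$", "M", x)
  bare <- !grepl("^chr", x)
  x[bare] <- paste0("chr", x[bare])
  sub("^chrMT$", "chrM", x)
}

# Natural chromosome ordering: chr1 < chr2 < ... < chr22 < chrX < chrY < chrM,
# then anything else alphabetically.
chrom_rank <- function(chrom) {
  body <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(body))
  rank <- ifelse(!is.na(num), num,
                 ifelse(body == "X", 100,
                        ifelse(body == "Y", 101,
                               ifelse(body == "M", 102, 1000))))
  rank
}

order_genomic <- function(chrom, start) {
  order(chrom_rank(chrom), chrom, start)
}

#' Compute the exclusive end coordinate of a probe
#'
#' Each array probe interrogates a single CpG position; it is rendered as a
#' 1-bp interval by default (`width = 1`), or 2 bp to cover the CpG
#' dinucleotide.
#'
#' @param start 0-based start position(s), non-negative.
#' @param width Probe footprint in bp (1 or 2).
#' @return 0-based exclusive end, `start + width`.
#' @export
compute_end <- function(start, width = 1L) {
  if (any(is.na(start)) || any(start < 0))
    stop("probe start positions must be non-negative", call. = FALSE)
  if (!width %in% c(1L, 2L))
    stop("probe width must be 1 or 2 bp", call. = FALSE)
  as.integer(start) + as.integer(width)
}

# Open a path for reading, transparently handling gzip by extension.
.open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Sniff the delimiter from the header line: tab wins if present, else comma.
.sniff_sep <- function(path) {
  con <- .open_input(path)
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

.as_beta <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad))
    stop(sprintf("column '%s' in %s has %d value(s) outside [0,1]",
                 col, path, sum(bad)), call. = FALSE)
  v
}

#' Read one differential-methylation table
#'
#' Parses a site-level differential-methylation export in one of three
#' dialects (RnBeads comparison export, ChAMP DMP export, or a simple custom
#' schema: chromosome, position, probe id, two per-group mean beta columns,
#' their difference, and an FDR-adjusted p-value) and canonicalizes it into a
#' `meth_comparison` object. Input positions are taken as 1-based and stored
#' 0-based half-open; probe ends are derived with [compute_end()].
#'
#' @param path Path to a comma- or tab-delimited file (optionally gzipped).
#' @param dialect `"rnbeads"`, `"champ"` or `"custom"`.
#' @param column_map Optional named list overriding entries of
#'   [default_column_map()]. Roles `beta_exp` / `beta_ctl` may also be given
#'   explicitly to pin the per-group mean columns, with group names taken
#'   from the column names.
#' @param genome_build Genome build tag (e.g. `"hg19"`), carried through to
#'   outputs for consistency checks.
#' @param probe_width Probe footprint in bp passed to [compute_end()].
#' @return A `meth_comparison`: a data frame of probe records (`cgid`,
#'   `chrom`, `start`, `end`, `beta_exp`, `beta_ctl`, `delta`, `fdr_q`) with
#'   attributes `group_exp`, `group_ctl`, `dialect`, `genome_build` and a
#'   `parse_report`.
#' @export
read_meth_table <- function(path, dialect = c("rnbeads", "champ", "custom"),
                            column_map = NULL, genome_build = "hg19",
                            probe_width = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input table not found: ", path, call. = FALSE)
  cmap <- default_column_map(dialect)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  sep <- .sniff_sep(path)
  con <- .open_input(path)
  on.exit(close(con))
  raw <- utils::read.delim(con, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)

  need <- function(role) {
    col <- cmap[[role]]
    if (is.null(col) || is.na(col)) return(NULL)
    if (!col %in% names(raw))
      stop(sprintf("dialect '%s' requires column '%s' (role %s), not found in %s",
                   dialect, col, role, path), call. = FALSE)
    raw[[col]]
  }

  chrom_raw <- need("chrom")
  start_raw <- need("start")
  if (is.null(chrom_raw) || is.null(start_raw))
    stop("column map must resolve 'chrom' and 'start'", call. = FALSE)

  # Probe ids: ChAMP keeps them as row names or an unnamed first column.
  cg <- if (!is.null(cmap$cgid) && !is.na(cmap$cgid) && cmap$cgid %in% names(raw)) {
    as.character(raw[[cmap$cgid]])
  } else if (dialect == "champ") {
    rn <- rownames(raw)
    if (!is.null(rn) && !identical(rn, as.character(seq_len(nrow(raw)))))
      rn
    else if (names(raw)[1] %in% c("", "X", "probe", "Probe", "cgid"))
      as.character(raw[[1]])
    else
      stop("champ dialect: probe id column not resolvable (expected row names ",
           "or an unnamed first column)", call. = FALSE)
  } else {
    stop(sprintf("dialect '%s' requires column '%s' (role cgid), not found in %s",
                 dialect, cmap$cgid, path), call. = FALSE)
  }

  # Per-group mean columns: explicit override wins, else pattern match in
  # file order (first = experimental, second = control).
  if (!is.null(cmap$beta_exp) && !is.null(cmap$beta_ctl) &&
      !is.na(cmap$beta_exp) && !is.na(cmap$beta_ctl)) {
    gcols <- c(cmap$beta_exp, cmap$beta_ctl)
    missing_g <- setdiff(gcols, names(raw))
    if (length(missing_g))
      stop("group mean column not found: ", missing_g[1], call. = FALSE)
    groups <- gcols
    pat <- cmap$group_mean_pattern
    hit <- grepl(pat, gcols)
    groups[hit] <- sub(pat, "\\1", gcols[hit])
  } else {
    pat <- cmap$group_mean_pattern
    gcols <- grep(pat, names(raw), value = TRUE)
    if (length(gcols) < 2L)
      stop(sprintf("dialect '%s': expected two per-group mean columns matching '%s' in %s",
                   dialect, pat, path), call. = FALSE)
    gcols <- gcols[1:2]
    groups <- sub(pat, "\\1", gcols)
  }

  beta_exp <- .as_beta(raw[[gcols[1]]], gcols[1], path)
  beta_ctl <- .as_beta(raw[[gcols[2]]], gcols[2], path)

  delta <- if (!is.null(cmap$delta) && !is.na(cmap$delta) &&
               cmap$delta %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[cmap$delta]]))
  } else {
    # custom dialect: the difference column name is free-form; take the first
    # numeric column that is consistent with beta_exp - beta_ctl, else derive.
    rest <- setdiff(names(raw), c(cmap$cgid, cmap$chrom, cmap$start, gcols))
    cand <- NULL
    for (cn in rest) {
      v <- suppressWarnings(as.numeric(raw[[cn]]))
      ok <- !is.na(v) & !is.na(beta_exp) & !is.na(beta_ctl)
      if (any(ok) && all(abs(v[ok] - (beta_exp[ok] - beta_ctl[ok])) <= 1e-6)) {
        cand <- v; cmap$delta <- cn; break
      }
    }
    if (is.null(cand)) beta_exp - beta_ctl else cand
  }

  fdr <- if (!is.null(cmap$fdr) && !is.na(cmap$fdr) && cmap$fdr %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[cmap$fdr]]))
  } else if (dialect == "custom") {
    # last remaining numeric column in [0,1], if any, is taken as the FDR q
    rest <- setdiff(names(raw),
                    c(cmap$cgid, cmap$chrom, cmap$start, gcols, cmap$delta))
    q <- rep(NA_real_, nrow(raw))
    for (cn in rev(rest)) {
      v <- suppressWarnings(as.numeric(raw[[cn]]))
      if (any(!is.na(v)) && all(is.na(v) | (v >= 0 & v <= 1))) { q <- v; break }
    }
    q
  } else {
    stop(sprintf("dialect '%s' requires column '%s' (role fdr), not found in %s",
                 dialect, cmap$fdr, path), call. = FALSE)
  }

  pos1 <- suppressWarnings(as.numeric(start_raw))
  parseable <- !is.na(pos1) & pos1 >= 1 & !is.na(chrom_raw) & chrom_raw != ""
  n_read <- nrow(raw)
  n_dropped_pos <- sum(!parseable)
  if (!any(parseable))
    stop("no rows with parseable chromosome/position in ", path, call. = FALSE)

  keep <- which(parseable)
  start0 <- as.integer(pos1[keep] - 1)
  rec <- data.frame(
    cgid = cg[keep],
    chrom = normalize_chrom(chrom_raw[keep]),
    start = start0,
    end = compute_end(start0, probe_width),
    beta_exp = beta_exp[keep],
    beta_ctl = beta_ctl[keep],
    delta = delta[keep],
    fdr_q = fdr[keep],
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL

  dup <- duplicated(rec$cgid)
  if (any(dup))
    stop("duplicate probe id in ", path, ": ", rec$cgid[which(dup)[1]],
         call. = FALSE)

  report <- list(path = path, rows_read = n_read, records_kept = nrow(rec),
                 rows_dropped_position = n_dropped_pos,
                 records_missing_beta = sum(is.na(rec$beta_exp) |
                                              is.na(rec$beta_ctl)))

  new_meth_comparison(rec, group_exp = groups[1], group_ctl = groups[2],
                      dialect = dialect, genome_build = genome_build,
                      parse_report = report)
}

#' Construct a meth_comparison object
#'
#' Low-level constructor used by [read_meth_table()] and the synthetic-data
#' generator; validates the probe-record invariants.
#'
#' @param records Data frame with the canonical record columns.
#' @param group_exp,group_ctl Experimental / control group names.
#' @param dialect Source dialect tag.
#' @param genome_build Build tag.
#' @param parse_report Optional parse-report list.
#' @return A `meth_comparison` object.
#' @export
new_meth_comparison <- function(records, group_exp, group_ctl,
                                dialect = "custom", genome_build = "hg19",
                                parse_report = NULL) {
  stopifnot(is.data.frame(records), all(.record_cols %in% names(records)))
  if (identical(group_exp, group_ctl))
    stop("experimental and control group names must differ", call. = FALSE)
  if (anyDuplicated(records$cgid))
    stop("duplicate probe id: ",
         records$cgid[which(duplicated(records$cgid))[1]], call. = FALSE)
  with(records, {
    stopifnot(all(end > start))
    ok <- !is.na(beta_exp) & !is.na(beta_ctl) & !is.na(delta)
    if (any(abs(delta[ok] - (beta_exp[ok] - beta_ctl[ok])) > 1e-6))
      stop("delta column inconsistent with group means (tolerance 1e-6)",
           call. = FALSE)
  })
  structure(records[, .record_cols],
            group_exp = group_exp, group_ctl = group_ctl,
            dialect = dialect, genome_build = genome_build,
            parse_report = parse_report,
            class = c("meth_comparison", "data.frame"))
}

#' @export
print.meth_comparison <- function(x, ...) {
  cat(sprintf("<meth_comparison> %s vs %s (%s, %s): %d probes\n",
              attr(x, "group_exp"), attr(x, "group_ctl"),
              attr(x, "dialect"), attr(x, "genome_build"), nrow(x)))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Comparison identifier "<exp>vs<ctl>"
#' @param table A `meth_comparison`.
#' @return Character scalar, e.g. `"d8vsWT"`.
#' @export
comparison_id <- function(table) {
  paste0(sanitize_name(attr(table, "group_exp")), "vs",
         sanitize_name(attr(table, "group_ctl")))
}

#' Read a batch of differential-methylation tables
#'
#' Reads several comparison tables sharing one dialect (e.g. three knockdown
#' lines each against the same control) in one call. Comparison identifiers
#' are made unique across the batch by appending a numeric suffix on
#' collision.
#'
#' @inheritParams read_meth_table
#' @param paths Character vector of table paths (length >= 1).
#' @return Named list of `meth_comparison` objects, in input order; names are
#'   the unique comparison identifiers.
#' @export
read_meth_batch <- function(paths, dialect = c("rnbeads", "champ", "custom"),
                            column_map = NULL, genome_build = "hg19",
                            probe_width = 1L) {
  dialect <- match.arg(dialect)
  if (length(paths) < 1L) stop("at least one table path required", call. = FALSE)
  tables <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tables[[i]] <- tryCatch(
      read_meth_table(paths[i], dialect, column_map, genome_build, probe_width),
      error = function(e) stop("failed on ", paths[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  ids <- vapply(tables, comparison_id, character(1))
  ids <- make.unique(ids, sep = "_")
  names(tables) <- ids
  tables
}

#' Write a plain-text parse report
#' @param table A `meth_comparison`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parse_report <- function(table, path) {
  r <- attr(table, "parse_report")
  if (is.null(r)) r <- list(path = "<in-memory>", rows_read = nrow(table),
                            records_kept = nrow(table),
                            rows_dropped_position = 0L,
                            records_missing_beta = sum(is.na(table$beta_exp) |
                                                         is.na(table$beta_ctl)))
  lines <- c(
    sprintf("input: %s", r$path),
    sprintf("rows read: %d", r$rows_read),
    sprintf("records kept: %d", r$records_kept),
    sprintf("rows dropped (unparseable position): %d", r$rows_dropped_position),
    sprintf("records with missing beta (excluded from statistics): %d",
            r$records_missing_beta))
  writeLines(lines, path)
  invisible(path)
}

# Track/file-name sanitization: keep [A-Za-z0-9_.-] only.
sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "", x)
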