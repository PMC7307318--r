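# Gene-model and repeat annotation loading, and feature resolution.
#
# Gene models come from UCSC refGene-style table dumps (already 0-based
# half-open) or BED6; repeats from UCSC rmsk-style dumps or RepeatMasker
# .out files (1-based inclusive, converted on load).

.read_annotation_lines <- function(path) {
  con <- .open_input(path)
  on.exit(close(con))
  readLines(con)
}

#' Load gene models from a refGene-style dump or BED6 file
#'
#' Accepts a UCSC refGene-style tab-delimited table dump (with or without the
#' leading `bin` column, auto-detected) or a 6-column BED file whose name
#' column holds the gene symbol. refGene `txStart`/`txEnd` and BED
#' coordinates are both already 0-based half-open.
#'
#' @param path Annotation file path (optionally gzipped). Lines starting with
#'   `#` are ignored.
#' @return Data frame of gene models: `symbol`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` (one row per transcript).
#' @export
load_refgene <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- .read_annotation_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stop("ragged annotation file ", path, " (column counts ",
         paste(unique(ncols), collapse = "/"), ")", call. = FALSE)
  nc <- ncols[1]
  m <- do.call(rbind, fields)

  is_int <- function(x) !any(is.na(suppressWarnings(as.integer(x))))
  if (nc == 6L && is_int(m[, 2]) && is_int(m[, 3]) &&
      all(m[, 6] %in% c("+", "-"))) {
    # BED6: chrom start end name score strand
    out <- data.frame(symbol = m[, 4], transcript_id = m[, 4],
                      chrom = normalize_chrom(m[, 1]), strand = m[, 6],
                      tx_start = as.integer(m[, 2]),
                      tx_end = as.integer(m[, 3]),
                      stringsAsFactors = FALSE)
  } else if (nc >= 12L) {
    # refGene: [bin] name chrom strand txStart txEnd ... name2 at col 13/12
    off <- if (all(m[, 3] %in% c("+", "-"))) 0L
           else if (is_int(m[, 1]) && all(m[, 4] %in% c("+", "-"))) 1L
           else stop("unrecognized annotation layout in ", path, " (", nc,
                     " columns; strand column not found)", call. = FALSE)
    out <- data.frame(symbol = m[, 12L + off],
                      transcript_id = m[, 1L + off],
                      chrom = normalize_chrom(m[, 2L + off]),
                      strand = m[, 3L + off],
                      tx_start = as.integer(m[, 4L + off]),
                      tx_end = as.integer(m[, 5L + off]),
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognized annotation layout in ", path, " (detected ", nc,
         " columns; expected BED6 or refGene-style >=12)", call. = FALSE)
  }
  if (any(out$tx_end <= out$tx_start))
    stop("zero- or negative-length transcript in ", path, call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Promoter window of a gene model
#'
#' The promoter is the window from `upstream` bp upstream of the
#' transcription start site through the first transcribed base (-500 to +1 at
#' the default), strand-aware and clipped at position 0. Its length is
#' `upstream + 1` absent clipping and it always contains the TSS base.
#'
#' @param gene One-row gene-model data frame (or list) with `chrom`,
#'   `strand`, `tx_start`, `tx_end`.
#' @param upstream Upstream extent in bp (default 500).
#' @return Data frame row `(chrom, start, end)`, 0-based half-open.
#' @export
promoter_interval <- function(gene, upstream = 500L) {
  if (upstream < 0) stop("upstream extent must be >= 0", call. = FALSE)
  if (gene$strand == "+") {
    tss <- gene$tx_start            # 0-based TSS base
    s <- max(0L, tss - as.integer(upstream))
    e <- tss + 1L
  } else {
    tss <- gene$tx_end - 1L
    s <- tss
    e <- tss + 1L + as.integer(upstream)
  }
  data.frame(chrom = gene$chrom, start = as.integer(s), end = as.integer(e),
             stringsAsFactors = FALSE)
}

#' Gene-body interval (the full transcription unit)
#' @inheritParams promoter_interval
#' @return Data frame row `(chrom, start, end)`.
#' @export
gene_body_interval <- function(gene) {
  data.frame(chrom = gene$chrom, start = as.integer(gene$tx_start),
             end = as.integer(gene$tx_end), stringsAsFactors = FALSE)
}

.region_suffix <- c(promoter = "_P", gene_body = "_GB", all = "_all")

new_feature_set <- function(df) {
  # df: feature, kind, chrom, start, end
  rownames(df) <- NULL
  structure(df, class = c("feature_set", "data.frame"))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d feature(s), %d interval(s)\n",
              length(unique(x$feature)), nrow(x)))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Resolve gene-name queries into genomic features
#'
#' Matches query names case-insensitively against gene symbols and builds one
#' feature per query, named with the region-mode suffix (`_P` promoter, `_GB`
#' gene body, `_all` promoter plus gene body). Multi-isoform genes contribute
#' the union of their per-transcript intervals; exact duplicate intervals are
#' removed but overlapping intervals are kept unmerged (the probe-assignment
#' step counts a probe at most once per feature regardless).
#'
#' @param names Character vector of query gene symbols; blanks and duplicates
#'   are dropped.
#' @param genes Gene-model data frame from [load_refgene()].
#' @param mode Region mode: `"all"` (default), `"promoter"` or `"gene_body"`.
#' @param upstream Promoter upstream extent in bp.
#' @return List with `features` (a `feature_set` data frame: `feature`,
#'   `kind`, `chrom`, `start`, `end`, in query order) and `unmatched`
#'   (character vector of names with no annotation match).
#' @export
resolve_features <- function(names, genes, mode = c("all", "promoter", "gene_body"),
                             upstream = 500L) {
  mode <- match.arg(mode)
  names <- unique(trimws(names))
  names <- names[nzchar(names)]
  if (!length(names)) stop("no feature names after stripping blanks", call. = FALSE)

  sym_lc <- tolower(genes$symbol)
  rows <- list(); unmatched <- character(0)
  for (nm in names) {
    hits <- which(sym_lc == tolower(nm))
    if (!length(hits)) { unmatched <- c(unmatched, nm); next }
    ivs <- do.call(rbind, lapply(hits, function(i) {
      g <- genes[i, ]
      switch(mode,
             promoter  = promoter_interval(g, upstream),
             gene_body = gene_body_interval(g),
             all       = rbind(promoter_interval(g, upstream),
                               gene_body_interval(g)))
    }))
    ivs <- unique(ivs)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = paste0(nm, .region_suffix[[mode]]),
      kind = mode, ivs, stringsAsFactors = FALSE)
  }
  if (length(unmatched))
    warning("unmatched feature name(s): ", paste(unmatched, collapse = ", "),
            call. = FALSE)
  if (!length(rows))
    stop("none of the queried names matched the annotation; check the gene ",
         "symbols and genome build", call. = FALSE)
  list(features = new_feature_set(do.call(rbind, rows)), unmatched = unmatched)
}

#' Load repeat intervals grouped by RepeatMasker class
#'
#' Accepts a UCSC rmsk-style tab-delimited dump (with or without the leading
#' `bin` column; `genoStart`/`genoEnd` already 0-based half-open) or a
#' RepeatMasker `.out` file (whitespace-separated, 1-based inclusive query
#' coordinates, converted on load; class taken from the `class/family`
#' field's part before the slash).
#'
#' @param path Repeat annotation file path (optionally gzipped).
#' @return Named list, one element per repeat class (e.g. `LINE`, `SINE`,
#'   `LTR`, `Satellite`), each a deduplicated data frame of
#'   `(chrom, start, end)` intervals.
#' @export
load_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("repeat annotation not found: ", path, call. = FALSE)
  lines <- .read_annotation_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no repeat rows in ", path, call. = FALSE)

  if (grepl("\t", lines[1])) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)[1]
    m <- do.call(rbind, fields)
    # rmsk dump: [bin] swScore milliDiv milliIns milliDel genoName genoStart
    #            genoEnd genoLeft strand repName repClass repFamily ...
    off <- if (nc >= 17L) 1L else 0L
    if (nc < 13L + off)
      stop("unrecognized repeat-annotation layout in ", path,
           " (", nc, " columns)", call. = FALSE)
    df <- data.frame(chrom = normalize_chrom(m[, 5L + off]),
                     start = as.integer(m[, 6L + off]),
                     end = as.integer(m[, 7L + off]),
                     class = m[, 11L + off],
                     stringsAsFactors = FALSE)
  } else {
    # RepeatMasker .out: skip the two header lines and blank separator
    body <- lines[!grepl("^\\s*(SW|score)\\b", lines)]
    fields <- strsplit(trimws(body), "\\s+")
    keep <- lengths(fields) >= 11L
    if (!any(keep))
      stop("unrecognized repeat-annotation layout in ", path, call. = FALSE)
    m <- do.call(rbind, fields[keep])
    df <- data.frame(chrom = normalize_chrom(m[, 5]),
                     start = as.integer(m[, 6]) - 1L,   # 1-based inclusive
                     end = as.integer(m[, 7]),
                     class = sub("/.*$", "", m[, 11]),
                     stringsAsFactors = FALSE)
  }
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("unparseable repeat coordinates in ", path, call. = FALSE)
  split_df <- split(df[, c("chrom", "start", "end")], df$class)
  lapply(split_df, function(d) { d <- unique(d); rownames(d) <- NULL; d })
}

#' Resolve repeat-class queries into features
#'
#' Case-insensitive matching of query names against RepeatMasker class names;
#' each matched class becomes one feature (no region suffix) holding all of
#' its deduplicated intervals.
#'
#' @param names Character vector of repeat-class names (e.g. `"LINE"`).
#' @param repeats Class-keyed interval list from [load_repeatmasker()].
#' @return List with `features` (a `feature_set`) and `unmatched`, as in
#'   [resolve_features()].
#' @export
resolve_repeat_features <- function(names, repeats) {
  names <- unique(trimws(names))
  names <- names[nzchar(names)]
  if (!length(names)) stop("no repeat-class names after stripping blanks", call. = FALSE)
  cls_lc <- tolower(names(repeats))
  rows <- list(); unmatched <- character(0)
  for (nm in names) {
    i <- match(tolower(nm), cls_lc)
    if (is.na(i)) { unmatched <- c(unmatched, nm); next }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = names(repeats)[i], kind = "repeat_class",
      repeats[[i]], stringsAsFactors = FALSE)
  }
  if (length(unmatched))
    warning("unmatched repeat class(es): ", paste(unmatched, collapse = ", "),
            call. = FALSE)
  if (!length(rows))
    stop("none of the queried repeat classes matched the annotation",
         call. = FALSE)
  list(features = new_feature_set(do.call(rbind, rows)), unmatched = unmatched)
}

#' Read a feature-query list file
#'
#' Plain text, one feature name per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path Query-list file path.
#' @return Character vector of query names.
#' @export
read_query_list <- function(path) {
  if (!file.exists(path)) stop("query list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("query list ", path, " contains no names", call. = FALSE)
  lines
}
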