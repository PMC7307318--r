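# Single-call orchestration: tables -> features -> assignment -> summaries
# and tracks, with a dry-run validator. The thin command-line wrapper in
# inst/scripts/methmap.R parses flags into run_config() and calls these.

#' Build and validate a pipeline run configuration
#'
#' @param tables Character vector of differential-methylation table paths.
#' @param dialect Table dialect: `"rnbeads"`, `"champ"` or `"custom"`.
#' @param query Path to the feature-name list (one name per line) or a
#'   character vector of names.
#' @param refgene Path to gene annotation (refGene-style or BED6); required
#'   for gene region modes.
#' @param rmsk Path to repeat annotation; required for `region = "repeat"`.
#' @param region Region mode: `"all"` (default; promoter plus gene body),
#'   `"promoter"`, `"gene_body"`, or `"repeat"`.
#' @param genome_build Genome build tag.
#' @param upstream Promoter upstream extent in bp (default 500).
#' @param alpha FDR threshold for the FDR tracks (default 0.05).
#' @param allow_missing_fdr Emit the sentinel FDR track even when the input
#'   carries no FDR column.
#' @param column_map Optional column-map override for [read_meth_table()].
#' @param outdir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(tables, dialect = "custom", query,
                       refgene = NULL, rmsk = NULL,
                       region = c("all", "promoter", "gene_body", "repeat"),
                       genome_build = "hg19", upstream = 500L, alpha = 0.05,
                       allow_missing_fdr = FALSE, column_map = NULL,
                       outdir = ".") {
  region <- match.arg(region)
  if (region == "repeat" && is.null(rmsk))
    stop("region 'repeat' requires an rmsk annotation path", call. = FALSE)
  if (region != "repeat" && is.null(refgene))
    stop("gene region modes require a refgene annotation path", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (upstream < 0) stop("upstream must be >= 0", call. = FALSE)
  structure(list(tables = tables, dialect = dialect, query = query,
                 refgene = refgene, rmsk = rmsk, region = region,
                 genome_build = genome_build, upstream = as.integer(upstream),
                 alpha = alpha, allow_missing_fdr = allow_missing_fdr,
                 column_map = column_map, outdir = outdir),
            class = "run_config")
}

#' Dry-run validation of a run configuration
#'
#' Checks file existence and column resolvability without running the
#' pipeline; problems are returned as findings, never raised.
#'
#' @param config A [run_config()].
#' @return Character vector of findings (empty when the config looks clean).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  for (p in config$tables) {
    if (!file.exists(p)) { findings <- c(findings, paste("table not found:", p)); next }
    err <- tryCatch({ read_meth_table(p, config$dialect, config$column_map,
                                      config$genome_build); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) findings <- c(findings, paste0(p, ": ", err))
  }
  ann <- if (config$region == "repeat") config$rmsk else config$refgene
  if (!file.exists(ann))
    findings <- c(findings, paste("annotation not found:", ann))
  if (is.character(config$query) && length(config$query) == 1L &&
      !file.exists(config$query) && grepl("[/.]", config$query))
    findings <- c(findings, paste("query list not found:", config$query))
  findings
}

.query_names <- function(query) {
  if (length(query) == 1L && file.exists(query)) read_query_list(query)
  else as.character(query)
}

#' Run the full pipeline
#'
#' Reads the comparison tables, resolves the queried features against the
#' annotation, assigns probes, and writes per-comparison outputs into
#' `outdir`: two results TSVs (experimental and control group), the four
#' bedGraph tracks (shared-control mean-beta tracks deduplicated across a
#' batch), a track index, parse reports, and a run log noting unmatched
#' feature names, dropped rows, and any empty-FDR sentinel. Unmatched names
#' and empty FDR tracks are logged, never fatal.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summaries` (per comparison and group),
#'   `tracks`, `unmatched`, and `files` (all paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  tables <- read_meth_batch(config$tables, config$dialect, config$column_map,
                            config$genome_build)
  for (id in names(tables)) {
    r <- attr(tables[[id]], "parse_report")
    note("[%s] read %d rows, kept %d records (%d dropped, %d missing beta)",
         id, r$rows_read, r$records_kept, r$rows_dropped_position,
         r$records_missing_beta)
  }

  qnames <- .query_names(config$query)
  if (config$region == "repeat") {
    repeats <- load_repeatmasker(config$rmsk)
    res <- withCallingHandlers(
      resolve_repeat_features(qnames, repeats),
      warning = function(w) { note("%s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  } else {
    genes <- load_refgene(config$refgene)
    res <- withCallingHandlers(
      resolve_features(qnames, genes, config$region, config$upstream),
      warning = function(w) { note("%s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  }

  files <- character(0)
  summaries <- list()
  region_tag <- config$region
  for (id in names(tables)) {
    tb <- tables[[id]]
    asg <- assign_probes(tb, res$features, config$genome_build)
    for (g in c("exp", "ctl")) {
      sm <- summarize_group(tb, asg, g)
      gname <- sanitize_name(attr(sm, "group"))
      p <- file.path(config$outdir,
                     sprintf("%s_%s_%s_results.tsv", id, gname, region_tag))
      write_results_tsv(sm, p)
      files <- c(files, p)
      summaries[[paste0(id, "_", gname)]] <- sm
    }
    rp <- file.path(config$outdir, sprintf("%s_parse_report.txt", id))
    write_parse_report(tb, rp)
    files <- c(files, rp)
  }

  tracks <- build_trackset(tables, config$alpha, config$allow_missing_fdr)
  index <- character(0)
  for (tr in tracks) {
    p <- file.path(config$outdir, paste0(tr$name, ".bedGraph"))
    emit_bedgraph(tr, p)
    files <- c(files, p)
    index <- c(index, sprintf("%s\t%s\t%s", tr$name, tr$kind, basename(p)))
    if (tr$kind == "fdr" && nrow(tr$lines) == 0L)
      note("track %s: no probe passed FDR < %g; sentinel emitted",
           tr$name, config$alpha)
  }
  idx_path <- file.path(config$outdir, "track_index.tsv")
  writeLines(index, idx_path)
  files <- c(files, idx_path)

  log_path <- file.path(config$outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)

  invisible(list(summaries = summaries, tracks = tracks,
                 unmatched = res$unmatched, files = files))
}
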