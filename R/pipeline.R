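## write via a temporary file in the target directory, then rename:
## readers never see a partial artifact
.atomicWrite <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot move temporary file onto ", path)
  ok <- TRUE
  invisible(path)
}

.thresholdRecord <- function(tr) {
  xd <- tr@xDistribution
  cfg <- tr@config
  list(threshold = tr@threshold, mode = cfg@mode, fdr = cfg@fdr,
       window = cfg@window, permutations = cfg@nPermutations,
       top_percentile = cfg@topPercentile, seed = cfg@seed,
       n_mappable_fragments = tr@diagnostics$nMappable,
       x_min = if (length(xd)) min(xd) else NA,
       x_median = if (length(xd)) stats::median(xd) else NA,
       x_max = if (length(xd)) max(xd) else NA)
}

#' Write a per-chromosome threshold report as JSON
#'
#' One record per chromosome: the final threshold, the full configuration
#' echo (including the seed), and summary statistics of the
#' per-permutation cutoff distribution.
#'
#' @param thresholds a named list of [ThresholdResult-class] objects (as
#'   in `S4Vectors::metadata(callInteractions(...))$thresholds`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeThresholdJson <- function(thresholds, path) {
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(lapply(thresholds, .thresholdRecord), tmp,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Write interactions as BED6+3
#'
#' Columns: chrom, start, end, `INT<n>:<category>` name, score (total
#' reads capped at 1000), strand `.`, then `category_number`,
#' `n_windows`, `threshold`. Coordinates 0-based half-open; `#` header
#' lines echo the configuration, including the seed.
#'
#' @param interactions a `GRanges` from [callInteractions()].
#' @param path output path.
#' @param config optional named list echoed into the `#` header.
#' @return `path`, invisibly.
#' @export
writeInteractionsBed <- function(interactions, path, config = list()) {
  mc <- S4Vectors::mcols(interactions)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(interactions)),
    start = GenomicRanges::start(interactions) - 1L,
    end = GenomicRanges::end(interactions),
    name = sprintf("INT%d:%s", seq_along(interactions), mc$categoryName),
    score = pmin(1000, round(mc$totalReads)),
    strand = ".",
    category_number = mc$category, n_windows = mc$nWindows,
    threshold = mc$threshold)
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c("# fourCcall interactions (BED6+3); coordinates 0-based half-open",
                 .configHeader(config)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  })
}

#' @rdname writeInteractionsBed
#' @export
readInteractionsBed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "category_number", "n_windows", "threshold")
  df <- .readTabTable(path, cols)
  start <- .parseIntColumn(df, "start", path)
  end <- .parseIntColumn(df, "end", path)
  cat <- .parseIntColumn(df, "category_number", path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start + 1L, end),
                               category = cat, categoryName = categoryName(cat),
                               totalReads = as.numeric(df$score),
                               nWindows = .parseIntColumn(df, "n_windows", path),
                               threshold = .parseIntColumn(df, "threshold", path))
  names(gr) <- df$name
  gr
}

#' Write per-fragment counts as bedGraph
#'
#' For genome-browser display of the observed read distribution. Only
#' fragments with nonzero counts are emitted.
#'
#' @param table a [CountTable-class].
#' @param path output path.
#' @param config optional named list echoed into the `#` header.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(table, path, config = list()) {
  gr <- table@fmap@frags
  keep <- table@counts > 0L
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[keep],
                   start = GenomicRanges::start(gr)[keep] - 1L,
                   end = GenomicRanges::end(gr)[keep],
                   count = table@counts[keep])
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c("# fourCcall per-fragment counts; coordinates 0-based half-open",
                 .configHeader(config),
                 "track type=bedGraph"), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  })
}

#' Read a key=value run-configuration file
#'
#' Plain text, one `key=value` per line, `#` comments and blank lines
#' ignored. Values from `overrides` (e.g. command-line flags) win.
#'
#' @param path config file path, or `NULL` for overrides only.
#' @param overrides named list merged over the file contents.
#' @return A named list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 1L) stop("malformed config line (expected key=value): ", ln)
      cfg[[trimws(substr(ln, 1L, eq - 1L))]] <- trimws(substring(ln, eq + 1L))
    }
  }
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  cfg
}

.logmsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full calling pipeline
#'
#' Reads one or more retab count tables, applies masks/region
#' restriction, computes per-chromosome thresholds, calls and prioritizes
#' interactions, optionally intersects replicates, and writes all
#' artifacts atomically: `<prefix>.<replicate>.thresholds.json`,
#' `<prefix>.<replicate>.interactions.bed`, optionally
#' `<prefix>.<replicate>.bedgraph`, `<prefix>.intersection.tsv` (when
#' two or more inputs are given), and `<prefix>.summary.json`. Progress
#' is logged to standard error; every artifact header echoes the
#' configuration and seed, and a rerun with an identical configuration
#' produces byte-identical artifacts.
#'
#' @param config a named list (see [readRunConfig()]): `retab`
#'   (character vector of input paths), `window`, `fdr`, `permutations`,
#'   `topPercentile`, `seed`, `mode`, `shuffleUnit`, optional `mask`
#'   (BED path), `region` (`chr:start-end` string, restriction),
#'   `bedgraph` (logical), and `outPrefix`.
#' @return Invisibly, a list with the artifact paths and the summary.
#' @export
runPipeline <- function(config) {
  retabs <- config$retab
  if (is.null(retabs) || length(retabs) == 0L)
    stop("config must name at least one retab input")
  missing <- retabs[!file.exists(retabs)]
  if (length(missing)) stop("input file not found: ", missing[1L])
  if (is.null(config$outPrefix)) stop("config must set outPrefix")
  num <- function(k, d) as.numeric(if (is.null(config[[k]])) d else config[[k]])
  tcfg <- thresholdConfig(
    window = num("window", 5), fdr = num("fdr", 0.01),
    nPermutations = num("permutations", 1000),
    topPercentile = num("topPercentile", 5),
    mode = if (is.null(config$mode)) "percentile" else config$mode,
    shuffleUnit = if (is.null(config$shuffleUnit)) "vector" else config$shuffleUnit,
    seed = num("seed", 1))
  echo <- list(window = tcfg@window, fdr = tcfg@fdr,
               permutations = tcfg@nPermutations,
               top_percentile = tcfg@topPercentile, mode = tcfg@mode,
               shuffle_unit = tcfg@shuffleUnit, seed = tcfg@seed)
  if (!is.null(config$mask)) echo$mask <- config$mask
  if (!is.null(config$region)) echo$region <- config$region
  prefix <- config$outPrefix
  artifacts <- character()
  cleanup <- function() unlink(artifacts[file.exists(artifacts)])
  summary <- list(config = echo, replicates = list())
  callSets <- list()
  tryCatch({
    for (path in retabs) {
      tab <- readRetab(path)
      label <- if (nzchar(tab@replicate)) tab@replicate else
        tools::file_path_sans_ext(basename(path))
      if (label %in% names(callSets))
        label <- tools::file_path_sans_ext(basename(path))
      if (label %in% names(callSets))
        label <- paste0(label, "_", length(callSets) + 1L)
      .logmsg("replicate ", label, ": ", sum(tab@counts), " reads on ",
              nFragments(tab), " fragments")
      if (!is.null(config$mask))
        tab <- applyMask(tab, readBedRegions(config$mask), keepInside = FALSE)
      if (!is.null(config$region))
        tab <- applyMask(tab, parseRegion(config$region), keepInside = TRUE)
      ints <- callInteractions(tab, tcfg)
      thresholds <- S4Vectors::metadata(ints)$thresholds
      for (chr in names(thresholds))
        .logmsg(label, " ", chr, ": T = ", thresholds[[chr]]@threshold,
                " reads/window")
      base <- paste0(prefix, ".", label)
      artifacts <- c(artifacts,
                     writeThresholdJson(thresholds,
                                        paste0(base, ".thresholds.json")),
                     writeInteractionsBed(ints,
                                          paste0(base, ".interactions.bed"),
                                          config = echo))
      if (isTRUE(as.logical(config$bedgraph)))
        artifacts <- c(artifacts,
                       writeBedGraph(tab, paste0(base, ".bedgraph"),
                                     config = echo))
      counts <- table(factor(S4Vectors::mcols(ints)$categoryName,
                             levels = c("Broad", "Intermediate", "Narrow")))
      .logmsg(label, ": ", length(ints), " interactions (",
              paste(names(counts), as.integer(counts), collapse = ", "), ")")
      summary$replicates[[label]] <- list(
        input = path, n_interactions = length(ints),
        categories = as.list(counts),
        thresholds = lapply(thresholds, function(tr) tr@threshold))
      callSets[[label]] <- fragmentCalls(ints, tab)
    }
    if (length(callSets) >= 2L) {
      xs <- intersectReplicates(callSets)
      ipath <- paste0(prefix, ".intersection.tsv")
      .atomicWrite(ipath, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(c("# fourCcall replicate intersection; coordinates 0-based half-open",
                     .configHeader(echo),
                     paste(c("chrom", "start", "end", "category_retained",
                             names(callSets)), collapse = "\t")), con)
        df <- xs$intersection
        write.table(df[c("chrom", "start", "end", "category",
                         names(callSets))], con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
      })
      artifacts <- c(artifacts, ipath)
      summary$intersection <- list(
        n_fragments = nrow(xs$intersection),
        unique_per_replicate = as.list(xs$uniqueCounts))
      .logmsg("intersection: ", nrow(xs$intersection),
              " fragments common to all ", length(callSets), " replicates")
    }
    spath <- paste0(prefix, ".summary.json")
    .atomicWrite(spath, function(tmp)
      jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    artifacts <- c(artifacts, spath)
  }, error = function(e) {
    cleanup()
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(list(artifacts = artifacts, summary = summary))
}
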