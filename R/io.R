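## Tabular input/output: generic N x 4 / N x 5 breakpoint files, fusion-caller
## native outputs behind a format registry, and the ranked report.

.isIntegerField <- function(x) grepl("^[0-9]+$", x)

#' Parse a generic breakpoint file
#'
#' Reads a tab-separated file with one fusion per row: chromosome and
#' coordinate of the 5' end, chromosome and coordinate of the 3' end, plus a
#' fifth 0/1 oncogenicity label column when `labeled = TRUE`. A header row is
#' detected by non-numeric coordinate fields in the first row and skipped.
#' Columns are positional.
#'
#' @param path path to a TSV file.
#' @param labeled whether a fifth 0/1 label column is required.
#' @return a data.frame with columns `chrom5`, `pos5`, `chrom3`, `pos3`,
#'   (`label`,) and `sourceRow` (0-based input order).
#' @export
parseFusions <- function(path, labeled = FALSE) {
  if (!file.exists(path))
    stop("fusion file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nCols <- if (labeled) 5L else 4L
  if (length(lines) == 0)
    return(.emptyFusionFrame(labeled))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hasHeader <- {
    f1 <- fields[[1]]
    length(f1) >= 4 && (!.isIntegerField(f1[2]) || !.isIntegerField(f1[4]))
  }
  dataRows <- if (hasHeader) fields[-1] else fields
  if (length(dataRows) == 0)
    return(.emptyFusionFrame(labeled))
  out <- vector("list", length(dataRows))
  for (i in seq_along(dataRows)) {
    f <- dataRows[[i]]
    rowNo <- i + as.integer(hasHeader)
    if (length(f) != nCols)
      stop(sprintf("row %d: expected %d tab-separated fields, found %d",
                   rowNo, nCols, length(f)))
    if (!.isIntegerField(f[2]) || !.isIntegerField(f[4]))
      stop(sprintf("row %d: coordinates must be positive integers", rowNo))
    rec <- data.frame(chrom5 = f[1], pos5 = as.integer(f[2]),
                      chrom3 = f[3], pos3 = as.integer(f[4]),
                      stringsAsFactors = FALSE)
    if (labeled) {
      if (!f[5] %in% c("0", "1"))
        stop(sprintf("row %d: label must be 0 or 1, found '%s'", rowNo, f[5]))
      rec$label <- as.integer(f[5])
    }
    rec$sourceRow <- i - 1L
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.emptyFusionFrame <- function(labeled) {
  f <- data.frame(chrom5 = character(0), pos5 = integer(0),
                  chrom3 = character(0), pos3 = integer(0),
                  stringsAsFactors = FALSE)
  if (labeled) f$label <- integer(0)
  f$sourceRow <- integer(0)
  f
}

## ---- caller-format registry ------------------------------------------------

.callerRegistry <- new.env(parent = emptyenv())

#' Register a fusion-caller input format
#'
#' The registry maps a format name to a parser function `function(path)`
#' returning the same data.frame layout as [parseFusions()] (optionally with
#' a `metadata` list-column of caller-specific key-value pairs). Adding
#' support for another detection tool is a data-only change.
#'
#' @param name format name (e.g. `"star-fusion"`).
#' @param parser function of one argument (the file path).
#' @export
registerCallerFormat <- function(name, parser) {
  stopifnot(is.character(name), length(name) == 1, is.function(parser))
  assign(name, parser, envir = .callerRegistry)
  invisible(name)
}

#' Registered caller formats
#' @return character vector of registered format names.
#' @export
listCallerFormats <- function() sort(ls(.callerRegistry))

.parseStarFusion <- function(path) {
  if (!file.exists(path))
    stop("fusion file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty caller file (missing header): ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  need <- c("LeftBreakpoint", "RightBreakpoint")
  if (!all(need %in% header))
    stop("star-fusion file must contain LeftBreakpoint and RightBreakpoint columns")
  dataLines <- lines[-1]
  if (length(dataLines) == 0)
    return(.emptyFusionFrame(FALSE))
  out <- vector("list", length(dataLines))
  meta <- vector("list", length(dataLines))
  for (i in seq_along(dataLines)) {
    f <- strsplit(dataLines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("row %d: expected %d fields, found %d",
                   i + 1L, length(header), length(f)))
    names(f) <- header
    lb <- strsplit(f[["LeftBreakpoint"]], ":", fixed = TRUE)[[1]]
    rb <- strsplit(f[["RightBreakpoint"]], ":", fixed = TRUE)[[1]]
    if (length(lb) < 2 || length(rb) < 2 ||
        !.isIntegerField(lb[2]) || !.isIntegerField(rb[2]))
      stop(sprintf("row %d: breakpoints must look like chr:pos[:strand]", i + 1L))
    out[[i]] <- data.frame(chrom5 = lb[1], pos5 = as.integer(lb[2]),
                           chrom3 = rb[1], pos3 = as.integer(rb[2]),
                           stringsAsFactors = FALSE)
    out[[i]]$sourceRow <- i - 1L
    meta[[i]] <- f[setdiff(header, need)]
  }
  res <- do.call(rbind, out)
  res$metadata <- meta
  rownames(res) <- NULL
  res
}

registerCallerFormat("star-fusion", .parseStarFusion)

#' Parse a fusion-caller native output file
#'
#' @param path path to the caller output.
#' @param formatName a registered format name (see [listCallerFormats()]).
#' @return a data.frame as from [parseFusions()], with caller metadata in a
#'   `metadata` list-column.
#' @export
parseCallerFusions <- function(path, formatName) {
  if (!exists(formatName, envir = .callerRegistry, inherits = FALSE))
    stop("unknown caller format '", formatName, "'; registered formats: ",
         paste(listCallerFormats(), collapse = ", "))
  get(formatName, envir = .callerRegistry)(path)
}

## ---- ranked report ---------------------------------------------------------

.REPORT_HEADER <- c("FusionPair", "OncogenicProbability",
                    "Gene5pId", "Gene5pName", "Gene5pDescription",
                    "Gene3pId", "Gene3pName", "Gene3pDescription",
                    "MainProteinLength", "TruncatedProtein",
                    "Gene5pComplete", "Gene3pComplete",
                    "NumCandidates", "MainProtein")

.yesNo <- function(x) ifelse(is.na(x), "NA", ifelse(x, "Yes", "No"))

#' Write the ranked fusion report
#'
#' Tab-separated, one row per fusion result, with the fixed 14-column header
#' `FusionPair, OncogenicProbability, Gene5pId, Gene5pName,
#' Gene5pDescription, Gene3pId, Gene3pName, Gene3pDescription,
#' MainProteinLength, TruncatedProtein, Gene5pComplete, Gene3pComplete,
#' NumCandidates, MainProtein`. Probabilities are printed with two decimals
#' (`NA` for fusions with no buildable protein); flags are rendered Yes/No.
#' `results` is expected to be already ranked (see [rankResults()]).
#'
#' @param results data.frame of fusion results from [prioritizeFusions()].
#' @param path output file path.
#' @export
writeFusionReport <- function(results, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write report to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(.REPORT_HEADER, collapse = "\t"), con)
  if (nrow(results) > 0) {
    rows <- vapply(seq_len(nrow(results)), function(i) {
      r <- results[i, ]
      paste(c(
        r$fusionPair,
        if (is.na(r$oncProb)) "NA" else sprintf("%.2f", r$oncProb),
        r$gene5Id, r$gene5Name, r$gene5Description,
        r$gene3Id, r$gene3Name, r$gene3Description,
        as.character(r$mainProteinLength),
        .yesNo(r$truncated), .yesNo(r$fivePrimeComplete),
        .yesNo(r$threePrimeComplete),
        as.character(r$nCandidates), r$mainProtein
      ), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read back a fusion report
#'
#' Inverse of [writeFusionReport()] for round-tripping and downstream use.
#'
#' @param path report file path.
#' @return data.frame with the report's columns, probabilities numeric and
#'   flags logical.
#' @export
readFusionReport <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 ||
      !identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]], .REPORT_HEADER))
    stop("not a fusion report (header mismatch): ", path)
  if (length(lines) == 1)
    lines <- character(0)
  else
    lines <- lines[-1]
  f <- strsplit(lines, "\t", fixed = TRUE)
  toLog <- function(x) ifelse(x == "NA", NA, x == "Yes")
  # strsplit drops a trailing empty field (e.g. an absent main protein)
  get <- function(j) vapply(f, function(r) if (length(r) >= j) r[j] else "",
                            character(1))
  data.frame(
    fusionPair = get(1),
    oncProb = suppressWarnings(as.numeric(get(2))),
    gene5Id = get(3), gene5Name = get(4), gene5Description = get(5),
    gene3Id = get(6), gene3Name = get(7), gene3Description = get(8),
    mainProteinLength = as.integer(get(9)),
    truncated = toLog(get(10)),
    fivePrimeComplete = toLog(get(11)),
    threePrimeComplete = toLog(get(12)),
    nCandidates = as.integer(get(13)),
    mainProtein = get(14),
    stringsAsFactors = FALSE
  )
}
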