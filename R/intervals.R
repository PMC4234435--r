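#' Genomic intervals
#'
#' Intervals throughout the package are 1-based and inclusive at both ends
#' (closed intervals), matching array-coordinate conventions. Two length
#' notions coexist deliberately:
#'
#' * the *reported length* of a CNVR is `end - start` (see [cnvr_length()]),
#'   which is how published CNVR tables in this field print lengths;
#' * the *overlap* between two intervals is a base count on closed intervals,
#'   `max(0, min(end) - max(start) + 1)` (see [overlap_bp()]).
#'
#' An interval table is a plain `data.frame` with columns `chrom` (character,
#' autosome label "1".."38"), `start` and `end` (integer-valued, `start <= end`).
#'
#' @name intervals
NULL

#' Construct an interval table
#'
#' @param chrom chromosome labels (coerced to character, "chr" prefix stripped).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param ... further equal-length attribute columns (e.g. `breed`, `source`).
#' @return `data.frame` with columns `chrom`, `start`, `end`, then `...`.
#' @export
interval_table <- function(chrom, start, end, ...) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    .stopf("interval coordinates must be numeric and non-missing")
  }
  if (any(start > end)) {
    .stopf("interval with start > end (first offender: %s:%s-%s)",
           chrom[start > end][1], start[start > end][1], end[start > end][1])
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df[order(suppressWarnings(as.integer(df$chrom)), df$start, df$end), ,
     drop = FALSE]
}

#' Inclusive overlap between two single intervals
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @return shared base count, `0` when disjoint or on different chromosomes.
#' @export
overlap_bp <- function(a, b) {
  if (normalize_chrom(a$chrom) != normalize_chrom(b$chrom)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
}

#' Reported CNVR length
#'
#' CNVR length is reported as `end - start` (not `+ 1`), the convention of
#' published CNVR tables this package interoperates with.
#'
#' @param start,end coordinates, or a data.frame with `start`/`end` as `start`.
#' @return numeric length(s) in bp.
#' @export
cnvr_length <- function(start, end = NULL) {
  if (is.null(end)) {
    end <- start$end
    start <- start$start
  }
  end - start
}

#' Convert an interval table to GRanges
#' @param df interval table.
#' @return `GRanges` with closed 1-based ranges.
#' @keywords internal
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Overlap hits between two interval tables
#'
#' [GenomicRanges::findOverlaps()] on harmonised sequence levels (the two
#' tables may cover different chromosome subsets).
#'
#' @param a,b interval tables.
#' @param ... passed to `findOverlaps` (e.g. `minoverlap`, `type`).
#' @return a `Hits` object.
#' @keywords internal
find_interval_overlaps <- function(a, b, ...) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  GenomicRanges::findOverlaps(ga, gb, ...)
}

#' Read a BED-like interval file
#'
#' Reads a tab-separated interval file with at least three columns
#' (chrom, start, end) and optional attribute columns (column 4 is taken as
#' `breed`, column 5 as `source` when present). The dialect is 1-based
#' inclusive by default, since all coordinates this package consumes are
#' printed 1-based; pass `zero_based = TRUE` for standard half-open BED,
#' in which case `start` is incremented on load.
#'
#' Lines with `start > end` are an error (reported with the line number);
#' non-autosomal chromosomes are skipped with a warning.
#'
#' @param path file path.
#' @param zero_based interpret input as half-open 0-based BED.
#' @return interval table sorted by (chrom, start).
#' @export
load_intervals <- function(path, zero_based = FALSE) {
  if (!file.exists(path)) .stopf("interval file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(interval_table(character(), numeric(), numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    .stopf("line %d: expected >=3 tab-separated columns",
           which(ncols < 3)[1])
  }
  chrom <- normalize_chrom(vapply(parts, `[[`, "", 1))
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (any(is.na(start) | is.na(end))) {
    .stopf("line %d: non-numeric coordinates", which(is.na(start) | is.na(end))[1])
  }
  if (zero_based) start <- start + 1
  bad <- which(start > end)
  if (length(bad) > 0) {
    .stopf("line %d: start > end (%s:%s-%s)", bad[1], chrom[bad[1]],
           start[bad[1]], end[bad[1]])
  }
  keep <- is_autosome(chrom)
  if (any(!keep)) {
    .warnf("skipping %d non-autosomal interval(s) (chrom %s)",
           sum(!keep), paste(unique(chrom[!keep]), collapse = ","))
  }
  breed <- if (max(ncols) >= 4) {
    vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")
  } else NULL
  src <- if (max(ncols) >= 5) {
    vapply(parts, function(p) if (length(p) >= 5) p[[5]] else NA_character_, "")
  } else NULL
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(breed)) df$breed <- breed
  if (!is.null(src)) df$source <- src
  df <- df[keep, , drop = FALSE]
  df <- df[order(suppressWarnings(as.integer(df$chrom)), df$start, df$end), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an interval table as a BED-like file (1-based inclusive dialect)
#' @param df interval table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "breed", "source"), names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
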