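#' Construct a table of genomic intervals
#'
#' The package-wide interval container: a data.frame with columns `chrom`,
#' `start`, `end` (0-based half-open), `strand` and optional `score`.
#'
#' @param chrom character vector of chromosome names (passed through
#'   verbatim; no "chr" normalization is attempted).
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand "+", "-" or "." (unstranded); recycled.
#' @param score optional numeric score.
#' @return data.frame of class `genomic_intervals`, sorted by
#'   (chrom, start, end).
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", score = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1) chrom <- rep_len(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (n > 0 && (any(is.na(chrom)) || any(!nzchar(chrom))))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  if (any(start < 0)) stop("invalid interval: negative start")
  strand <- rep_len(as.character(strand), n)
  if (n > 0 && !all(strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- rep_len(as.numeric(score), n)
  df <- sort_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Sort an interval table by (chrom, start, end)
#' @param x interval data.frame.
#' @return sorted data.frame, row names reset.
#' @export
sort_intervals <- function(x) {
  o <- order(x$chrom, x$start, x$end)
  x <- x[o, , drop = FALSE]
  rownames(x) <- NULL
  x
}

# Internal: interval data.frame -> IRangesList keyed by chrom (1-based closed).
.as_irl <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) {
    list(idx = i,
         ir = IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
  })
}

#' Which intervals in `x` overlap any interval in `y`?
#'
#' Overlap means at least 1 bp in common on the same chromosome; strand is
#' ignored throughout the peak algebra.
#'
#' @param x,y interval data.frames.
#' @return logical vector along rows of `x`.
#' @export
overlaps_any <- function(x, y) {
  hit <- logical(nrow(x))
  if (nrow(x) == 0 || nrow(y) == 0) return(hit)
  xs <- .as_irl(x)
  ys <- .as_irl(y)
  for (ch in intersect(names(xs), names(ys))) {
    ov <- IRanges::overlapsAny(xs[[ch]]$ir, ys[[ch]]$ir)
    hit[xs[[ch]]$idx] <- ov
  }
  hit
}

# Internal: all overlapping row pairs between x and y, with overlap width.
.overlap_pairs <- function(x, y) {
  out <- list()
  if (nrow(x) == 0 || nrow(y) == 0)
    return(data.frame(qi = integer(), si = integer(), width = integer()))
  xs <- .as_irl(x)
  ys <- .as_irl(y)
  for (ch in intersect(names(xs), names(ys))) {
    h <- IRanges::findOverlaps(xs[[ch]]$ir, ys[[ch]]$ir)
    if (length(h) == 0) next
    qi <- xs[[ch]]$idx[S4Vectors::queryHits(h)]
    si <- ys[[ch]]$idx[S4Vectors::subjectHits(h)]
    w <- pmin(x$end[qi], y$end[si]) - pmax(x$start[qi], y$start[si])
    out[[ch]] <- data.frame(qi = qi, si = si, width = w)
  }
  if (length(out) == 0)
    return(data.frame(qi = integer(), si = integer(), width = integer()))
  do.call(rbind, out)
}
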