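#' Merge peaks separated by less than a maximum gap
#'
#' Narrow-mark peak harmonization: any two peaks whose gap is strictly less
#' than `max_gap` (including touching or overlapping peaks) are fused into
#' their union, transitively. Broad marks (H3K36me3, H3K27me3) are
#' conventionally not merged; callers apply this to narrow marks only.
#'
#' @param peaks interval data.frame (sorted or not).
#' @param max_gap merge peaks with gap < `max_gap` bp (default 350).
#' @return merged `genomic_intervals`; under the gap rule no two output
#'   peaks are closer than `max_gap`.
#' @export
merge_close <- function(peaks, max_gap = 350) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  x <- sort_intervals(as.data.frame(peaks))
  if (nrow(x) <= 1)
    return(genomic_intervals(x$chrom, x$start, x$end))
  out <- list()
  k <- 0
  cur_ch <- x$chrom[1]; cur_s <- x$start[1]; cur_e <- x$end[1]
  for (i in 2:nrow(x)) {
    same <- x$chrom[i] == cur_ch
    gap <- x$start[i] - cur_e
    if (same && gap < max_gap) {
      cur_e <- max(cur_e, x$end[i])
    } else {
      k <- k + 1
      out[[k]] <- list(cur_ch, cur_s, cur_e)
      cur_ch <- x$chrom[i]; cur_s <- x$start[i]; cur_e <- x$end[i]
    }
  }
  out[[k + 1]] <- list(cur_ch, cur_s, cur_e)
  genomic_intervals(vapply(out, `[[`, "", 1),
                    vapply(out, function(z) z[[2]], 0),
                    vapply(out, function(z) z[[3]], 0))
}

#' Replicate-common peaks by reciprocal-overlap rule
#'
#' Two peaks are common when their overlap is at least `min_frac` of the
#' length of the shorter peak; qualifying pairs are replaced by the union of
#' their coordinates ("extended coordinates maintained"). Chains of
#' qualifying pairs (a peak qualifying with several partners) collapse into
#' a single union via connected components over the qualifying-pair graph.
#'
#' @param a,b interval data.frames (replicate peak sets of the same mark).
#' @param min_frac minimum overlap as a fraction of the shortest peak,
#'   in (0, 1]; "at least" so equality passes. Default 0.5.
#' @return `genomic_intervals` of union intervals, sorted.
#' @export
common_peaks <- function(a, b, min_frac = 0.5) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]")
  a <- sort_intervals(as.data.frame(a))
  b <- sort_intervals(as.data.frame(b))
  pr <- .overlap_pairs(a, b)
  if (nrow(pr) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  la <- a$end[pr$qi] - a$start[pr$qi]
  lb <- b$end[pr$si] - b$start[pr$si]
  keep <- pr$width >= min_frac * pmin(la, lb)
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  # union-find over nodes (a-peaks 1..nA, b-peaks nA+1..nA+nB)
  nA <- nrow(a)
  parent <- seq_len(nA + nrow(b))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pr))) {
    ri <- find(pr$qi[r]); rj <- find(nA + pr$si[r])
    if (ri != rj) parent[ri] <- rj
  }
  nodes <- unique(c(pr$qi, nA + pr$si))
  comp <- vapply(nodes, find, 0L)
  starts <- c(a$start, b$start)[nodes]
  ends <- c(a$end, b$end)[nodes]
  chroms <- c(a$chrom, b$chrom)[nodes]
  agg_s <- tapply(starts, comp, min)
  agg_e <- tapply(ends, comp, max)
  agg_c <- tapply(chroms, comp, function(z) z[1])
  u <- unique(data.frame(chrom = as.character(agg_c),
                         start = as.integer(agg_s),
                         end = as.integer(agg_e)))
  genomic_intervals(u$chrom, u$start, u$end)
}

#' Fold replicate-common peaks across several samples
#'
#' Pairwise `common_peaks` folded left-to-right in the order given,
#' re-sorting between folds; the result is the peaks supported, under the
#' shortest-peak overlap rule, by every sample.
#'
#' @param peaksets list of >= 2 interval data.frames.
#' @param min_frac passed to [common_peaks()].
#' @return `genomic_intervals`.
#' @export
common_peaks_all <- function(peaksets, min_frac = 0.5) {
  if (length(peaksets) < 2) stop("need at least two peak sets")
  Reduce(function(x, y) common_peaks(x, y, min_frac = min_frac), peaksets)
}

#' Remove peaks overlapping a blacklist
#'
#' A peak with any overlap (>= 1 bp) with a blacklisted region is removed
#' whole, never trimmed.
#'
#' @param peaks interval data.frame.
#' @param blacklist interval data.frame of excluded regions.
#' @return subset of `peaks` (sorted).
#' @export
filter_blacklist <- function(peaks, blacklist) {
  x <- sort_intervals(as.data.frame(peaks))
  if (nrow(x) == 0 || is.null(blacklist) || nrow(blacklist) == 0) return(x)
  x[!overlaps_any(x, as.data.frame(blacklist)), , drop = FALSE]
}

#' Assign peaks to genes
#'
#' A peak is assigned to every gene whose body (gene span) or TSS window
#' (TSS +/- `tss_window` bp) it overlaps; multi-assignment is allowed.
#' Peaks touching no gene are labeled intergenic (`gene_id` NA).
#'
#' @param peaks interval data.frame.
#' @param ann `gene_annotation` (or a precomputed [gene_table()]).
#' @param tss_window bp around the TSS (default 2000).
#' @return data.frame with one row per (peak, gene) assignment: `peak` (row
#'   index into the sorted peaks), `chrom`, `start`, `end`, `gene_id`.
#' @export
annotate_peaks <- function(peaks, ann, tss_window = 2000) {
  gt <- if (inherits(ann, "gene_annotation")) gene_table(ann) else ann
  x <- sort_intervals(as.data.frame(peaks))
  reg_s <- pmax(0L, pmin(gt$start, gt$tss - tss_window))
  reg_e <- pmax(gt$end, gt$tss + tss_window + 1L)
  regions <- data.frame(chrom = gt$chrom, start = reg_s, end = reg_e)
  pr <- .overlap_pairs(x, regions)
  assigned <- data.frame(peak = pr$qi, gene_id = gt$gene_id[pr$si],
                         stringsAsFactors = FALSE)
  inter <- setdiff(seq_len(nrow(x)), unique(pr$qi))
  if (length(inter))
    assigned <- rbind(assigned,
                      data.frame(peak = inter, gene_id = NA_character_))
  assigned <- assigned[order(assigned$peak, assigned$gene_id), , drop = FALSE]
  out <- data.frame(peak = assigned$peak,
                    chrom = x$chrom[assigned$peak],
                    start = x$start[assigned$peak],
                    end = x$end[assigned$peak],
                    gene_id = assigned$gene_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count peaks overlapping a segment set
#'
#' Number of peaks with >= 1 bp overlap with any segment; each peak counts
#' at most once however many segments it touches.
#'
#' @param peaks interval data.frame.
#' @param segments interval data.frame.
#' @return integer count.
#' @export
count_in_segments <- function(peaks, segments) {
  x <- as.data.frame(peaks)
  if (nrow(x) == 0) return(0L)
  sum(overlaps_any(x, as.data.frame(segments)))
}
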