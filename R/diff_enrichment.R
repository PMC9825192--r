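#' Consensus peaks present in a minimum number of samples
#'
#' All samples' peaks are unioned into merged intervals (overlap or
#' adjacency fuses); a merged interval is retained when peaks from at least
#' `min_samples` distinct samples overlap it.
#'
#' @param peaksets list of interval data.frames, one per sample.
#' @param min_samples minimum supporting samples, default 2.
#' @return `genomic_intervals` of consensus regions.
#' @export
consensus_peaks <- function(peaksets, min_samples = 2) {
  if (min_samples > length(peaksets))
    stop("min_samples exceeds number of samples")
  allp <- do.call(rbind, lapply(peaksets, function(p)
    data.frame(chrom = p$chrom, start = p$start, end = p$end)))
  if (is.null(allp) || nrow(allp) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  merged <- merge_close(allp, max_gap = 1)   # fuse overlap and adjacency only
  support <- rep(0L, nrow(merged))
  for (p in peaksets)
    support <- support + as.integer(overlaps_any(merged, as.data.frame(p)))
  out <- merged[support >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count track signal over consensus peaks
#'
#' Per peak and sample, the summed per-bin track values within the peak
#' (bins overlapping the peak interval).
#'
#' @param tracks named list of `signal_track`s, one per sample.
#' @param consensus interval data.frame.
#' @return integer-valued matrix peaks x samples; rownames
#'   "chrom:start-end".
#' @export
count_fragments <- function(tracks, consensus) {
  x <- sort_intervals(as.data.frame(consensus))
  out <- sapply(tracks, function(tr) {
    bs <- tr$bin_size
    vapply(seq_len(nrow(x)), function(i) {
      v <- tr$values[[x$chrom[i]]]
      if (is.null(v)) return(0)
      b0 <- x$start[i] %/% bs + 1L
      b1 <- min(length(v), as.integer(ceiling(x$end[i] / bs)))
      if (b1 < b0) 0 else sum(v[b0:b1])
    }, 0)
  })
  out <- as.matrix(out)
  rownames(out) <- sprintf("%s:%d-%d", x$chrom, x$start, x$end)
  out
}

# DESeq-style median-of-ratios size factors
.size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) return(colSums(counts) / mean(colSums(counts)))
  apply(counts, 2, function(cc) exp(median((log(cc) - lg)[ok])))
}

#' Negative-binomial Wald test for differential enrichment
#'
#' A documented simplification of the DiffBind/DESeq2 stage: median-of-
#' ratios library-size normalization over consensus-peak counts, per-peak
#' method-of-moments dispersion shrunk toward a parametric mean-dispersion
#' trend (a1/mu + a0), and a Wald test on the log2 fold change (knockdown
#' vs control) under the NB variance, with Benjamini-Hochberg correction.
#' No outlier filtering or posterior LFC shrinkage is attempted.
#'
#' @param counts peaks x samples non-negative count matrix.
#' @param condition character/factor per sample; must have 2 levels.
#' @param control level treated as the reference (default "control").
#' @param shrink weight pulling the log-dispersion toward the trend,
#'   in \[0, 1\] (default 0.9; with few replicates the per-peak moment
#'   estimate carries little information).
#' @param fdr_cutoff significance cutoff on BH-adjusted p (default 0.05).
#' @return data.frame per peak: `peak`, `base_mean`, `log2fc` (kd vs
#'   control), `se`, `p`, `fdr`, `direction` in
#'   {"enriched_in_KD", "depleted_in_KD", "ns"}; all-zero peaks get NA
#'   statistics and direction "ns".
#' @export
nb_difftest <- function(counts, condition, control = "control",
                        shrink = 0.9, fdr_cutoff = 0.05) {
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2) stop("condition must have exactly 2 levels")
  if (!control %in% lv) stop("control level '", control, "' absent")
  kd <- setdiff(lv, control)
  if (sum(condition == control) < 2 || sum(condition == kd) < 2)
    stop("need >= 2 samples per condition")
  counts <- as.matrix(counts)
  sf <- .size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  nonzero <- rowSums(counts) > 0
  iC <- condition == control; iK <- condition == kd
  n0 <- sum(iC); n1 <- sum(iK)
  m0 <- rowMeans(nc[, iC, drop = FALSE])
  m1 <- rowMeans(nc[, iK, drop = FALSE])
  mu <- (n0 * m0 + n1 * m1) / (n0 + n1)
  # method-of-moments dispersion from within-group variances
  v0 <- apply(nc[, iC, drop = FALSE], 1, var)
  v1 <- apply(nc[, iK, drop = FALSE], 1, var)
  vw <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  alpha_mom <- pmax((vw - mu) / mu^2, 1e-8)
  # parametric trend alpha(mu) = a1/mu + a0 fit on moment estimates
  fitidx <- nonzero & mu > 0 & is.finite(alpha_mom)
  a0 <- 0.01; a1 <- 1
  if (sum(fitidx) >= 10) {
    for (it in 1:5) {
      pred <- a1 / mu[fitidx] + a0
      w <- 1 / pred^2
      X <- cbind(1, 1 / mu[fitidx])
      cf <- tryCatch(solve(crossprod(X * sqrt(w)),
                           crossprod(X * sqrt(w), alpha_mom[fitidx] * sqrt(w))),
                     error = function(e) c(a0, a1))
      a0 <- max(cf[1], 1e-8); a1 <- max(cf[2], 0)
    }
  }
  alpha_tr <- a1 / pmax(mu, 1e-8) + a0
  # arithmetic shrinkage: a log-scale blend would explode on the many
  # near-zero moment estimates that two replicates produce
  alpha <- (1 - shrink) * pmax(alpha_mom, 0) + shrink * alpha_tr
  eps <- 0.5
  lfc <- log2((m1 + eps) / (m0 + eps))
  se <- sqrt((1 / (m0 + eps) + alpha) / n0 +
             (1 / (m1 + eps) + alpha) / n1) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  p[!nonzero] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[nonzero] <- p.adjust(p[nonzero], method = "BH")
  dir <- rep("ns", length(p))
  sig <- !is.na(fdr) & fdr < fdr_cutoff
  dir[sig & lfc > 0] <- "enriched_in_KD"
  dir[sig & lfc < 0] <- "depleted_in_KD"
  data.frame(peak = rownames(counts) %||% as.character(seq_along(p)),
             base_mean = mu, log2fc = ifelse(nonzero, lfc, NA),
             se = ifelse(nonzero, se, NA), p = p, fdr = fdr,
             direction = dir, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
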