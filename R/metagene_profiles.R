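#' Signal extraction scaling (SES) normalization factors
#'
#' Estimates the background scaling between a ChIP track and its matched
#' input: bins are sorted by ChIP signal ascending, the cumulative signal
#' fractions of ChIP and input are compared, and the bin index maximizing
#' their difference defines the background partition (bins at or below it).
#' Scale factors equalize the two tracks' totals over that background, so
#' that after scaling the log2 ChIP/input ratio is centred at 0 in
#' unenriched regions.
#'
#' @param chip,input `signal_track`s with identical binning.
#' @param sample_bins optional number of bins to subsample (evenly spaced)
#'   for speed; default uses all bins.
#' @return list of class `norm_factors`: `sf_chip` (fixed at 1),
#'   `sf_input`, `background_fraction`.
#' @export
ses_factors <- function(chip, input, sample_bins = NULL) {
  if (chip$bin_size != input$bin_size)
    stop("chip and input must share bin size")
  x <- unlist(chip$values, use.names = FALSE)
  y <- unlist(input$values, use.names = FALSE)
  if (length(x) != length(y)) stop("chip and input must share binning")
  if (!is.null(sample_bins) && sample_bins < length(x)) {
    idx <- round(seq(1, length(x), length.out = sample_bins))
    x <- x[idx]; y <- y[idx]
  }
  if (sum(y) == 0) {
    warning("zero-signal input track; falling back to total-count scaling")
    sf <- if (sum(x) > 0) 1 else 1   # nothing to equalize
    return(structure(list(sf_chip = 1, sf_input = sf,
                          background_fraction = NA_real_),
                     class = "norm_factors"))
  }
  o <- order(x)
  cx <- cumsum(x[o]) / max(sum(x), .Machine$double.eps)
  cy <- cumsum(y[o]) / sum(y)
  j <- which.max(cy - cx)
  # flat difference curve: no detectable enrichment, whole genome is
  # background
  if (max(cy - cx) < 1e-12) j <- length(x)
  bg <- o[seq_len(j)]
  chip_bg <- sum(x[bg]); input_bg <- sum(y[bg])
  if (input_bg == 0 || chip_bg == 0) {
    warning("degenerate background partition; total-count scaling")
    sf_input <- sum(x) / sum(y)
  } else {
    sf_input <- chip_bg / input_bg
  }
  structure(list(sf_chip = 1, sf_input = sf_input,
                 background_fraction = j / length(x)),
            class = "norm_factors")
}

#' Stringent gene filter for metagene profiling
#'
#' Keeps genes with span length >= `min_len`, with no other gene span within
#' `min_dist` on the same chromosome (either neighbor closer than the cutoff
#' disqualifies both; overlap counts as distance < 0), and with no gene on
#' the opposite strand overlapping the span.
#'
#' @param ann `gene_annotation` or [gene_table()] output.
#' @param min_len minimum gene span, default 2000 bp.
#' @param min_dist minimum end-to-start gap to any other gene, default
#'   4000 bp.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(ann, min_len = 2000, min_dist = 4000) {
  gt <- if (inherits(ann, "gene_annotation")) gene_table(ann) else ann
  keep <- (gt$end - gt$start) >= min_len
  # pairwise distance on the same chromosome
  for (ch in unique(gt$chrom)) {
    i <- which(gt$chrom == ch)
    if (length(i) < 2) next
    o <- i[order(gt$start[i])]
    gaps <- gt$start[o][-1] - gt$end[o][-length(o)]
    # a gap below min_dist disqualifies both flanking genes; overlapping
    # genes elsewhere in the sorted order are caught by the opposite/any
    # overlap check below
    bad <- which(gaps < min_dist)
    keep[o[bad]] <- FALSE
    keep[o[bad + 1]] <- FALSE
    # any overlap with another gene (same or opposite strand)
    spans <- data.frame(chrom = gt$chrom[i], start = gt$start[i],
                        end = gt$end[i])
    pr <- .overlap_pairs(spans, spans)
    pr <- pr[pr$qi != pr$si, , drop = FALSE]
    keep[i[unique(pr$qi)]] <- FALSE
  }
  gt$gene_id[keep]
}

# log2((chip*sf_c + eps) / (input*sf_i + eps)) per 10 bp bin, one chromosome
.ratio_vec <- function(chip_v, input_v, nf, eps) {
  log2((chip_v * nf$sf_chip + eps) / (input_v * nf$sf_input + eps))
}

#' Input-normalized metagene matrix over scaled gene bodies
#'
#' Per retained gene, the log2(ChIP/input) ratio in 10 bp bins is laid out
#' strand-aware as 200 upstream bins (2 kbp), the gene body linearly
#' resampled to 500 bins (a 5 kbp equivalent), and 200 downstream bins:
#' 900 columns, 5' to 3' in transcription direction. Genes whose ratio is 0
#' in every bin (no enrichment anywhere) are dropped. Flank bins beyond a
#' chromosome edge are NA.
#'
#' @param chip,input `signal_track`s (same binning, typically 10 bp).
#' @param nf [ses_factors()] output (or any list with `sf_chip`,
#'   `sf_input`).
#' @param ann annotation (`gene_annotation` or gene table).
#' @param gene_ids genes to profile (e.g. from [filter_genes()]).
#' @param flank flank width bp (default 2000).
#' @param body_bins resampled body bins (default 500).
#' @param pseudocount added to both scaled tracks before the ratio
#'   (default 1).
#' @param resample "interpolate" (linear, deepTools-like; default) or
#'   "average" (bin averaging).
#' @return matrix genes x (2*flank/binsize + body_bins) of log2 ratios,
#'   rownames = gene ids.
#' @export
metagene_matrix <- function(chip, input, nf, ann, gene_ids,
                            flank = 2000, body_bins = 500, pseudocount = 1,
                            resample = c("interpolate", "average")) {
  resample <- match.arg(resample)
  gt <- if (inherits(ann, "gene_annotation")) gene_table(ann) else ann
  gt <- gt[match(gene_ids, gt$gene_id), , drop = FALSE]
  bs <- chip$bin_size
  fb <- flank %/% bs
  ncol_out <- 2L * fb + body_bins
  ratio <- lapply(names(chip$values), function(ch)
    .ratio_vec(chip$values[[ch]], input$values[[ch]], nf, pseudocount))
  names(ratio) <- names(chip$values)
  rows <- matrix(NA_real_, nrow(gt), ncol_out,
                 dimnames = list(gt$gene_id, NULL))
  for (i in seq_len(nrow(gt))) {
    rv <- ratio[[gt$chrom[i]]]
    if (is.null(rv)) next
    n <- length(rv)
    b0 <- gt$start[i] %/% bs            # first body bin (0-based)
    b1 <- as.integer(ceiling(gt$end[i] / bs)) - 1L
    grab <- function(from, to) {        # 0-based bin range, NA off the edge
      idx <- from:to
      out <- rep(NA_real_, length(idx))
      ok <- idx >= 0 & idx < n
      out[ok] <- rv[idx[ok] + 1L]
      out
    }
    up <- grab(b0 - fb, b0 - 1L)
    body <- grab(b0, b1)
    down <- grab(b1 + 1L, b1 + fb)
    if (length(body) != body_bins) {
      xi <- seq(1, length(body), length.out = body_bins)
      body <- if (resample == "interpolate" && length(body) > 1) {
        approx(seq_along(body), body, xout = xi)$y
      } else {
        idx <- pmin(length(body), pmax(1, round(xi)))
        body[idx]
      }
    }
    prof <- c(up, body, down)
    if (gt$strand[i] == "-") prof <- rev(prof)
    rows[i, ] <- prof
  }
  nz <- apply(rows, 1, function(r) any(r != 0, na.rm = TRUE))
  rows[nz, , drop = FALSE]
}

#' k-means clustering of enrichment profiles
#'
#' Groups genes by binding-enrichment level around the TSS (Euclidean
#' distance on the raw log2-ratio profiles, no per-gene scaling, so clusters
#' separate by level). Clusters are relabeled 1..k by mean enrichment
#' descending, making ids a deterministic function of the data.
#'
#' @param mat metagene matrix restricted to the columns of interest (e.g.
#'   TSS +/- 2 kbp).
#' @param k number of clusters, default 3.
#' @param seed RNG seed; k-means uses 10 restarts.
#' @return list of class `profile_clusters`: `cluster` (named integer),
#'   `centers`, `means` (per-cluster mean enrichment, descending).
#' @export
kmeans_profiles <- function(mat, k = 3, seed = 1) {
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (k > nrow(mat)) stop("k exceeds number of genes")
  km <- with_seed(seed, kmeans(mat, centers = k, nstart = 10, iter.max = 100))
  lvl <- tapply(rowMeans(mat), km$cluster, mean)
  ord <- order(lvl, decreasing = TRUE)          # cluster 1 = highest
  relab <- integer(k); relab[as.integer(names(lvl))[ord]] <- seq_len(k)
  cl <- relab[km$cluster]
  names(cl) <- rownames(mat)
  structure(list(cluster = cl,
                 centers = km$centers[as.integer(names(lvl))[ord], , drop = FALSE],
                 means = as.numeric(lvl[ord])),
            class = "profile_clusters")
}

#' Paired Cohen's d profile with simultaneous confidence intervals
#'
#' Per bin, the paired effect size d = mean(A - B) / sd(A - B) over genes,
#' with a normal-approximation CI, SE(d) = sqrt(1/n + d^2/(2n)), at a
#' Bonferroni-adjusted per-bin level so that the whole profile's intervals
#' hold simultaneously (FWER control): per-bin two-sided alpha =
#' (1 - level) / n_bins.
#'
#' @param A,B metagene matrices with identical genes (rows, paired) and
#'   bins.
#' @param level simultaneous confidence level, default 0.99.
#' @return data.frame per bin: `bin`, `d`, `ci_lower`, `ci_upper`, `n`;
#'   attribute `affected` is TRUE when any bin's CI excludes 0. Zero-variance
#'   bins get signed-infinite d and NA CIs.
#' @export
paired_cohens_d <- function(A, B, level = 0.99) {
  if (!identical(dim(A), dim(B)) || !identical(rownames(A), rownames(B)))
    stop("A and B must be paired: same genes and bins")
  ok <- stats::complete.cases(A) & stats::complete.cases(B)
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  n <- nrow(A)
  if (n < 3) stop("need at least 3 paired genes")
  D <- A - B
  mu <- colMeans(D)
  s <- apply(D, 2, sd)
  d <- ifelse(s > 0, mu / s, ifelse(mu == 0, 0, sign(mu) * Inf))
  alpha_bin <- (1 - level) / ncol(A)
  z <- qnorm(1 - alpha_bin / 2)
  se <- sqrt(1 / n + d^2 / (2 * n))
  lo <- d - z * se; hi <- d + z * se
  lo[!is.finite(d)] <- NA; hi[!is.finite(d)] <- NA
  out <- data.frame(bin = seq_along(d), d = d, ci_lower = lo, ci_upper = hi,
                    n = n)
  attr(out, "affected") <- any(lo > 0 | hi < 0, na.rm = TRUE)
  attr(out, "alpha_per_bin") <- alpha_bin
  out
}
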