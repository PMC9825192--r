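# PWM scanning of exon flank sequences with a dual threshold: a relative
# log-odds similarity cutoff and an exact false-positive-rate cutoff
# computed by dynamic programming over the discretized score distribution.

#' Construct a position probability matrix object
#'
#' @param mat 4 x W matrix of position probabilities, rows A, C, G, T
#'   (RNA motifs are handled by U/T identification); each column must sum
#'   to 1.
#' @param motif_id motif identifier.
#' @param family RBP family label (default the motif id).
#' @param background length-4 nucleotide background distribution (default
#'   uniform).
#' @param pseudo probability mass mixed in to keep log-odds finite
#'   (default 1e-3).
#' @return object of class `pwm`.
#' @export
pwm <- function(mat, motif_id, family = motif_id,
                background = rep(0.25, 4), pseudo = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 3) stop("PWM width must be >= 3")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  p <- sweep(mat + pseudo, 2, 1 + 4 * pseudo, "/")
  lo <- log2(p / background)
  structure(list(motif_id = motif_id, family = family, ppm = mat,
                 log_odds = lo, background = background),
            class = "pwm")
}

#' Read position-probability matrices from a TSV file
#'
#' CISBP-RNA-like layout: blocks separated by lines starting with ">",
#' `>motif_id<TAB>family`; each following line gives the A C G T (or
#' A C G U) probabilities of one motif position.
#'
#' @param path TSV file.
#' @param background shared background distribution.
#' @return list of `pwm` objects.
#' @export
read_pwms <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PWM records (expected '>' headers)")
  bounds <- c(heads, length(lines) + 1)
  lapply(seq_along(heads), function(i) {
    hd <- strsplit(sub("^>", "", lines[heads[i]]), "\t")[[1]]
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    m <- t(vapply(block, function(l)
      as.numeric(strsplit(l, "\t")[[1]]), numeric(4)))
    dimnames(m) <- NULL
    pwm(t(m), motif_id = hd[1],
        family = if (length(hd) > 1) hd[2] else hd[1],
        background = background)
  })
}

#' Write PWMs in the TSV layout read by [read_pwms()]
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s\t%s", p$motif_id, p$family), con)
    for (j in seq_len(ncol(p$ppm)))
      writeLines(paste(format(p$ppm[, j], digits = 10), collapse = "\t"), con)
  }
  invisible(path)
}

#' Dual similarity / false-positive-rate score threshold
#'
#' The scanning threshold is the stricter of two cutoffs on the log-odds
#' scale: T_sim = S_min + rel_similarity * (S_max - S_min), and T_fpr, the
#' smallest score whose upper-tail probability under iid background
#' sequence is <= `fpr`, computed exactly by dynamic programming over the
#' per-position score distribution discretized at `step` log-odds units.
#'
#' @param pwm `pwm` object.
#' @param rel_similarity relative score cutoff in \[0, 1\] (default 0.95).
#' @param fpr false-positive rate in (0, 1) (default 0.001).
#' @param step discretization of the DP (default 0.01).
#' @return list: `threshold` (the max), `t_sim`, `t_fpr`, `s_min`, `s_max`.
#' @export
score_threshold <- function(pwm, rel_similarity = 0.95, fpr = 0.001,
                            step = 0.01) {
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  if (rel_similarity < 0 || rel_similarity > 1)
    stop("rel_similarity must be in [0, 1]")
  lo <- pwm$log_odds
  s_min <- sum(apply(lo, 2, min))
  s_max <- sum(apply(lo, 2, max))
  t_sim <- s_min + rel_similarity * (s_max - s_min)
  # exact tail by convolution of discretized per-position distributions
  q <- round(lo / step)
  offset <- sum(apply(q, 2, min))
  width <- sum(apply(q, 2, max)) - offset
  dist <- 1
  for (j in seq_len(ncol(q))) {
    col_q <- q[, j] - min(q[, j])
    nd <- numeric(length(dist) + max(col_q))
    for (b in 1:4) {
      idx <- seq_along(dist) + col_q[b]
      nd[idx] <- nd[idx] + dist * pwm$background[b]
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))
  scores <- (offset + seq_along(dist) - 1) * step
  ok <- which(tail_p <= fpr)
  t_fpr <- if (length(ok)) scores[min(ok)] else s_max + step
  list(threshold = max(t_sim, t_fpr), t_sim = t_sim, t_fpr = t_fpr,
       s_min = s_min, s_max = s_max)
}

# integer-encode a DNA/RNA string; non-ACGT(U) -> NA
.seq_codes <- function(s) {
  v <- match(strsplit(toupper(chartr("U", "T", s)), "")[[1]],
             c("A", "C", "G", "T"))
  v
}

#' Scan sequences with a PWM at a score threshold
#'
#' Strandless scan of the given (sense) sequences; RNA motifs are applied
#' with U and T identified. Windows containing ambiguous bases are skipped.
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of sequences.
#' @param pwm `pwm` object.
#' @param threshold minimum log-odds score (e.g.
#'   `score_threshold(pwm)$threshold`).
#' @return data.frame `sequence_id`, `motif_id`, `offset` (1-based window
#'   start), `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold) {
  if (inherits(sequences, "XStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences)))
    names(sequences) <- as.character(seq_along(sequences))
  lo <- pwm$log_odds
  W <- ncol(lo)
  hits <- list()
  for (sid in names(sequences)) {
    v <- .seq_codes(sequences[[sid]])
    L <- length(v)
    if (L < W) next
    npos <- L - W + 1
    sc <- numeric(npos)
    bad <- logical(npos)
    for (j in seq_len(W)) {
      b <- v[j:(j + npos - 1)]
      na <- is.na(b)
      bad <- bad | na
      b[na] <- 1L
      sc <- sc + lo[cbind(b, j)]
    }
    sel <- which(!bad & sc >= threshold)
    if (length(sel))
      hits[[length(hits) + 1]] <- data.frame(
        sequence_id = sid, motif_id = pwm$motif_id, offset = sel,
        score = sc[sel], stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(sequence_id = character(0), motif_id = character(0),
                      offset = integer(0), score = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Extract exon flank sequences for motif scanning
#'
#' For each defining exon of each event, the `flank` nt immediately
#' upstream and downstream in the genome; for minus-strand genes the
#' sequences are reverse-complemented and the flank roles swapped so that
#' every sequence reads 5' to 3' on the transcribed strand. Flanks running
#' off a chromosome end are truncated and flagged.
#'
#' @param events `splicing_events`.
#' @param genome named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences.
#' @param flank flank width nt (default 100).
#' @return list: `sequences` (named character vector; names
#'   `event|exon_index|upstream/downstream`), `meta` (data.frame with
#'   `event_id`, `role`, `side`, `truncated`).
#' @export
extract_flanks <- function(events, genome, flank = 100) {
  if (inherits(genome, "XStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  ex <- events$exons
  seqs <- character(0)
  meta <- list()
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (i in seq_len(nrow(ex))) {
    chrom_seq <- genome[[ex$chrom[i]]]
    if (is.null(chrom_seq)) stop("chromosome absent from genome: ", ex$chrom[i])
    L <- nchar(chrom_seq)
    left0 <- max(0L, ex$start[i] - flank)
    left <- substr(chrom_seq, left0 + 1, ex$start[i])
    right1 <- min(L, ex$end[i] + flank)
    right <- substr(chrom_seq, ex$end[i] + 1, right1)
    trunc_l <- nchar(left) < flank
    trunc_r <- nchar(right) < flank
    if (ex$strand[i] == "+") {
      up <- left; dn <- right; tu <- trunc_l; td <- trunc_r
    } else {
      up <- rc(right); dn <- rc(left); tu <- trunc_r; td <- trunc_l
    }
    for (side in c("upstream", "downstream")) {
      s <- if (side == "upstream") up else dn
      nmq <- sprintf("%s|%d|%s", ex$event_id[i], i, side)
      seqs[nmq] <- s
      meta[[length(meta) + 1]] <- data.frame(
        name = nmq, event_id = ex$event_id[i], role = ex$role[i],
        side = side,
        truncated = if (side == "upstream") tu else td,
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = seqs, meta = do.call(rbind, meta))
}

#' Per-family fraction of sequences with at least one motif match
#'
#' @param matches [scan_pwm()] output (possibly rbind-ed over motifs).
#' @param sequence_ids ids of all sequences scanned (denominator).
#' @param family_map named character vector motif_id -> family.
#' @return data.frame `family`, `n_matched`, `n_sequences`, `fraction`.
#' @export
family_match_fraction <- function(matches, sequence_ids, family_map) {
  if (!length(sequence_ids)) stop("empty sequence set")
  fams <- unique(family_map)
  rows <- lapply(fams, function(f) {
    motifs <- names(family_map)[family_map == f]
    hit <- unique(matches$sequence_id[matches$motif_id %in% motifs])
    data.frame(family = f, n_matched = length(intersect(hit, sequence_ids)),
               n_sequences = length(sequence_ids),
               fraction = length(intersect(hit, sequence_ids)) /
                 length(sequence_ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
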