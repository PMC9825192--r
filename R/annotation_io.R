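#' Build a gene annotation from an exon table
#'
#' The annotation container used throughout the package: one row per exon,
#' grouped by transcript and gene. Coordinates are 0-based half-open. Genes
#' must be stranded; exons of a transcript must be non-overlapping and share
#' chrom and strand.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` ("+"/"-"), `start`, `end` and optionally `gene_type`
#'   (default "protein_coding").
#' @return data.frame of class `gene_annotation`, exons sorted genomically
#'   within transcript.
#' @export
gene_annotation <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(exons$gene_type)) exons$gene_type <- "protein_coding"
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  o <- order(exons$gene_id, exons$transcript_id, exons$start, exons$end)
  exons <- exons[o, c(need, "gene_type")]
  rownames(exons) <- NULL
  # per-transcript validation: single chrom/strand, non-overlapping exons
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (i in sp) {
    if (length(unique(exons$chrom[i])) != 1 ||
        length(unique(exons$strand[i])) != 1)
      stop("transcript ", exons$transcript_id[i[1]],
           ": exons must share chrom and strand")
    if (length(i) > 1) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1] < e[-length(e)]))
        stop("transcript ", exons$transcript_id[i[1]],
             ": overlapping exons")
    }
  }
  class(exons) <- c("gene_annotation", "data.frame")
  exons
}

#' Per-gene summary of an annotation
#'
#' @param ann `gene_annotation`.
#' @return data.frame with one row per gene: `gene_id`, `gene_type`, `chrom`,
#'   `strand`, `start`, `end` (gene span over all transcripts), `tss`, `tes`
#'   (strand-aware 0-based positions), `n_transcripts`, `max_exons` (largest
#'   per-transcript exon count).
#' @export
gene_table <- function(ann) {
  sp <- split(seq_len(nrow(ann)), ann$gene_id)
  rows <- lapply(names(sp), function(g) {
    i <- sp[[g]]
    s <- min(ann$start[i]); e <- max(ann$end[i])
    strand <- ann$strand[i[1]]
    nx <- table(ann$transcript_id[i])
    data.frame(gene_id = g, gene_type = ann$gene_type[i[1]],
               chrom = ann$chrom[i[1]], strand = strand,
               start = s, end = e,
               tss = if (strand == "+") s else e - 1L,
               tes = if (strand == "+") e - 1L else s,
               n_transcripts = length(nx), max_exons = max(nx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-body regions downstream of the promoter zone
#'
#' The gene body in the H3K36me3 sense: the gene span minus the first
#' `clearance` bp downstream of the TSS (strand-aware), where
#' promoter-associated chromatin dominates. Genes shorter than
#' `clearance + 600` keep their full span.
#'
#' @param gt [gene_table()] output (or a `gene_annotation`).
#' @param clearance promoter clearance in bp (default 1000).
#' @return data.frame `chrom`, `start`, `end`, `gene_id`.
#' @export
gene_bodies <- function(gt, clearance = 1000) {
  if (inherits(gt, "gene_annotation")) gt <- gene_table(gt)
  s <- ifelse(gt$strand == "+", gt$start + clearance, gt$start)
  e <- ifelse(gt$strand == "+", gt$end, gt$end - clearance)
  short <- e - s < 600
  s[short] <- gt$start[short]; e[short] <- gt$end[short]
  data.frame(chrom = gt$chrom, start = as.integer(s), end = as.integer(e),
             gene_id = gt$gene_id, stringsAsFactors = FALSE)
}

#' Read a GENCODE-dialect GTF into a gene annotation
#'
#' GTF is 1-based closed on disk; coordinates are shifted to the internal
#' 0-based half-open convention on read (start decremented by exactly 1).
#'
#' @param path GTF file.
#' @return `gene_annotation`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("GTF contains no exon records")
  if (is.null(ex$gene_id) || is.null(ex$transcript_id))
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  gene_annotation(data.frame(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = ex$start - 1L, end = ex$end,
    gene_type = if (is.null(ex$gene_type)) "protein_coding" else ex$gene_type,
    stringsAsFactors = FALSE))
}

#' Write a gene annotation as GTF
#'
#' Emits gene, transcript and exon rows with `gene_id`, `transcript_id` and
#' `gene_type` attributes; internal 0-based half-open coordinates are
#' converted back to GTF 1-based closed.
#'
#' @param ann `gene_annotation`.
#' @param path output file.
#' @export
write_gtf <- function(ann, path) {
  gt <- gene_table(ann)
  fmt <- function(chrom, src, type, s0, e0, strand, attr)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, s0 + 1L, e0, strand, attr)
  lines <- character(0)
  sp <- split(seq_len(nrow(ann)), ann$gene_id)
  for (g in gt$gene_id) {
    gi <- gt[gt$gene_id == g, ]
    ga <- sprintf('gene_id "%s"; gene_type "%s";', g, gi$gene_type)
    lines <- c(lines, fmt(gi$chrom, "chromsplice", "gene", gi$start, gi$end,
                          gi$strand, ga))
    i <- sp[[g]]
    for (tx in unique(ann$transcript_id[i])) {
      j <- i[ann$transcript_id[i] == tx]
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                    g, tx, gi$gene_type)
      lines <- c(lines, fmt(gi$chrom, "chromsplice", "transcript",
                            min(ann$start[j]), max(ann$end[j]), gi$strand, ta))
      lines <- c(lines, fmt(ann$chrom[j], "chromsplice", "exon",
                            ann$start[j], ann$end[j], ann$strand[j], ta))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read BED or narrowPeak intervals
#'
#' @param path BED file (0-based half-open on disk, the internal convention).
#' @param dialect "bed" (3-6 columns) or "narrowPeak" (10 columns; the
#'   signalValue column is carried as `score`).
#' @return `genomic_intervals`, sorted.
#' @export
read_bed <- function(path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (any(dt[[2]] >= dt[[3]])) stop("BED record with start >= end")
  if (dialect == "narrowPeak") {
    if (ncol(dt) < 10) stop("narrowPeak requires 10 columns")
    genomic_intervals(dt[[1]], dt[[2]], dt[[3]],
                      strand = ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "."),
                      score = dt[[7]])
  } else {
    strand <- if (ncol(dt) >= 6) ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], ".") else "."
    score <- if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]])) else NULL
    genomic_intervals(dt[[1]], dt[[2]], dt[[3]], strand = strand,
                      score = score)
  }
}

#' Write intervals as BED
#'
#' BED3 when all strands are "." and no score is present, otherwise BED6
#' (name ".", score 0 when absent). Output is sorted.
#'
#' @param intervals interval data.frame.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  x <- sort_intervals(as.data.frame(intervals))
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  plain <- all(x$strand == ".") && is.null(x$score)
  if (plain) {
    lines <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  } else {
    sc <- if (is.null(x$score)) rep(0, nrow(x)) else x$score
    lines <- sprintf("%s\t%d\t%d\t.\t%s\t%s", x$chrom, x$start, x$end,
                     format(sc, trim = TRUE, scientific = FALSE), x$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a binned signal track
#'
#' @param values named list (one numeric vector per chromosome) of
#'   non-negative per-bin signal; bin `i` covers
#'   `[(i-1)*bin_size, i*bin_size)`.
#' @param bin_size bin width in bp.
#' @param chrom_lengths optional named integer vector; defaults to
#'   `length(values[[chrom]]) * bin_size`.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_lengths = NULL) {
  if (!is.list(values) || is.null(names(values)))
    stop("values must be a named list of per-chromosome vectors")
  for (v in values) if (any(v < 0)) stop("signal values must be >= 0")
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(values, length, 0L) * as.integer(bin_size)
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths),
            class = "signal_track")
}

#' Write a signal track as bedGraph
#' @param track `signal_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    n <- length(v)
    if (n == 0) next
    # run-length encode equal consecutive values
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, s * bs,
                       pmin(e * bs, track$chrom_lengths[[ch]]),
                       format(r$values, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph into a fixed-bin signal track
#'
#' Record boundaries must align to the bin grid; uncovered bins are 0.
#'
#' @param path bedGraph file.
#' @param bin_size target bin width (bp).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return `signal_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  vals <- lapply(names(chrom_lengths), function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / bin_size)
    v <- numeric(n)
    d <- dt[dt$chrom == ch, , drop = FALSE]
    if (nrow(d)) {
      if (any(d$start %% bin_size != 0))
        stop("bedGraph record not aligned to ", bin_size, " bp grid")
      for (i in seq_len(nrow(d))) {
        b0 <- d$start[i] %/% bin_size + 1L
        b1 <- min(n, as.integer(ceiling(d$end[i] / bin_size)))
        v[b0:b1] <- d$value[i]
      }
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, bin_size, chrom_lengths)
}

#' Read a GMT gene-set collection
#' @param path GMT file (set name, description, then gene ids, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV transcript-abundance (TPM) matrix
#' @param path TSV with first column transcript ids, remaining columns samples.
#' @return numeric matrix, rownames = transcript ids.
#' @export
read_tpm <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write a TPM matrix as TSV
#' @param tpm numeric matrix with rownames.
#' @param path output file.
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(transcript_id = rownames(tpm), tpm, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
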