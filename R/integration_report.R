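#' One-tailed Fisher overlap test between two gene sets
#'
#' Exact hypergeometric test of the overlap of two sets within a universe.
#' The one-tailed p under `alternative = "greater"` is the hypergeometric
#' upper tail P(X >= k); the odds ratio is ad/bc from the 2x2 table, with
#' the Haldane-Anscombe 0.5 correction applied only when a cell is zero
#' (the p-value always comes from the uncorrected exact tail).
#'
#' @param set_a,set_b character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe character vector, the gene universe.
#' @param alternative "greater" (enrichment, default) or "less".
#' @return one-row data.frame: `k` (overlap), `n_a`, `n_b`, `n_universe`,
#'   `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); N <- length(universe)
  p <- if (alternative == "greater")
    phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  else
    phyper(k, n_a, N - n_a, n_b, lower.tail = TRUE)
  a <- k; b <- n_a - k; cc <- n_b - k; d <- N - n_a - n_b + k
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                               cc <- cc + 0.5; d <- d + 0.5 }
  data.frame(k = k, n_a = n_a, n_b = n_b, n_universe = N,
             odds_ratio = (a * d) / (b * cc), p = p)
}

#' Over-representation analysis over a GMT collection
#'
#' Per term, a one-tailed hypergeometric enrichment p of the query set
#' within the universe, Benjamini-Hochberg corrected across terms. Terms
#' with no overlap with the universe are skipped with a warning.
#'
#' @param query character vector of gene ids.
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe gene universe.
#' @param q_cutoff BH-adjusted cutoff flagged in `significant`
#'   (default 0.05).
#' @param p_cutoff_raw optional raw-p rule flagged in `significant_raw`
#'   (default 0.01, the custom-set convention).
#' @return data.frame per term: `term`, `k`, `n_term`, `n_query`,
#'   `n_universe`, `odds_ratio`, `p`, `q`, `significant`,
#'   `significant_raw`, sorted by p.
#' @export
ora <- function(query, collection, universe, q_cutoff = 0.05,
                p_cutoff_raw = 0.01) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- list()
  for (term in names(collection)) {
    genes <- intersect(unique(collection[[term]]), universe)
    if (!length(genes)) {
      warning("term with zero universe overlap skipped: ", term)
      next
    }
    r <- fisher_overlap(genes, query, universe)
    rows[[term]] <- data.frame(term = term, k = r$k, n_term = r$n_a,
                               n_query = r$n_b, n_universe = r$n_universe,
                               odds_ratio = r$odds_ratio, p = r$p,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(0), k = integer(0),
                      n_term = integer(0), n_query = integer(0),
                      n_universe = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), significant_raw = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_cutoff
  out$significant_raw <- out$p < p_cutoff_raw
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Gene length and exon-count contrast between two gene sets
#'
#' Per gene, the span length (bp) and the exon count of the
#' exon-richest transcript; per feature a two-sided Welch t-test between
#' the sets.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param ann `gene_annotation` or [gene_table()] output.
#' @return data.frame with one row per feature (`length`, `exons`): means
#'   per set and Welch `p`.
#' @export
gene_feature_contrast <- function(set_a, set_b, ann) {
  gt <- if (inherits(ann, "gene_annotation")) gene_table(ann) else ann
  if (!length(set_a) || !length(set_b)) stop("gene sets must be non-empty")
  fa <- gt[gt$gene_id %in% set_a, ]
  fb <- gt[gt$gene_id %in% set_b, ]
  feat <- function(name, va, vb) {
    p <- if (length(va) > 1 && length(vb) > 1 &&
             (var(va) > 0 || var(vb) > 0))
      t.test(va, vb)$p.value else NA_real_
    data.frame(feature = name, mean_a = mean(va), mean_b = mean(vb), p = p,
               stringsAsFactors = FALSE)
  }
  rbind(feat("length", fa$end - fa$start, fb$end - fb$start),
        feat("exons", fa$max_exons, fb$max_exons))
}

#' Expressed protein-coding gene universe
#'
#' Gene-level TPM is the sum of the gene's transcript TPMs; genes are kept
#' when their mean TPM over the control samples exceeds `min_tpm`
#' (strictly) and their type is protein_coding.
#'
#' @param tpm transcripts x samples TPM matrix.
#' @param ann `gene_annotation`.
#' @param condition character per sample column.
#' @param control control label (default "control").
#' @param min_tpm strict lower TPM bound (default 2).
#' @return character vector of gene ids.
#' @export
expressed_universe <- function(tpm, ann, condition, control = "control",
                               min_tpm = 2) {
  tx2g <- unique(data.frame(tx = ann$transcript_id, gene = ann$gene_id,
                            type = ann$gene_type, stringsAsFactors = FALSE))
  tx2g <- tx2g[tx2g$tx %in% rownames(tpm), ]
  ctrl <- tpm[tx2g$tx, condition == control, drop = FALSE]
  gene_tpm <- tapply(rowMeans(ctrl), tx2g$gene, sum)
  coding <- unique(tx2g$gene[tx2g$type == "protein_coding"])
  names(gene_tpm)[gene_tpm > min_tpm & names(gene_tpm) %in% coding]
}
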