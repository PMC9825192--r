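# AP-MS interactor scoring: peptide intensity normalization, IgG
# subtraction, per-protein fold change with a Welch t-test, a one-sample
# rule for single-replicate designs, and the stringent two-antibody
# intersection.

#' Normalize peptide intensities within samples
#'
#' A sample is one (antibody, channel, replicate) run. Default mode
#' `sample_mean` divides each intensity by the mean of all non-missing
#' intensities in its sample (global per-sample centering, making
#' downstream fold changes invariant to per-sample scaling). Mode
#' `protein_mean` divides by the mean of the same protein's peptides within
#' the sample instead. Missing intensities are imputed as half the sample's
#' minimum non-missing intensity before normalization.
#'
#' @param table data.frame with columns `protein_id`, `peptide_id`,
#'   `antibody`, `channel` ("IP"/"IgG"), `replicate`, `intensity`
#'   (NA = missing).
#' @param mode "sample_mean" (default) or "protein_mean".
#' @return the table with columns `intensity` (imputed raw), `norm`
#'   (normalized) and `imputed`.
#' @export
normalize_intensities <- function(table, mode = c("sample_mean",
                                                  "protein_mean")) {
  mode <- match.arg(mode)
  need <- c("protein_id", "peptide_id", "antibody", "channel", "replicate",
            "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(table$intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  sample_key <- paste(table$antibody, table$channel, table$replicate,
                      sep = "|")
  table$imputed <- is.na(table$intensity)
  table$norm <- NA_real_
  for (s in unique(sample_key)) {
    i <- sample_key == s
    v <- table$intensity[i]
    if (all(is.na(v))) stop("sample with no observed intensities: ", s)
    v[is.na(v)] <- min(v, na.rm = TRUE) / 2
    table$intensity[i] <- v
    if (mode == "sample_mean") {
      table$norm[i] <- v / mean(v)
    } else {
      pm <- tapply(v, table$protein_id[i], mean)
      table$norm[i] <- v / pm[table$protein_id[i]]
    }
  }
  table
}

# long table -> per-peptide log2 means by channel for one antibody
.peptide_log2 <- function(norm, antibody) {
  d <- norm[norm$antibody == antibody, , drop = FALSE]
  if (!nrow(d)) stop("no rows for antibody ", antibody)
  d$l2 <- log2(d$norm)
  d
}

#' Per-peptide log2 fold change, IP over IgG
#'
#' Log2-normalized intensities are averaged over replicates within each
#' channel and the IgG mean is subtracted from the IP mean.
#'
#' @param norm [normalize_intensities()] output.
#' @param antibody antibody label to analyze.
#' @return data.frame `protein_id`, `peptide_id`, `fc` (log2 IP - log2 IgG).
#' @export
peptide_fc <- function(norm, antibody) {
  d <- .peptide_log2(norm, antibody)
  key <- paste(d$protein_id, d$peptide_id, sep = "|")
  ip <- tapply(d$l2[d$channel == "IP"], key[d$channel == "IP"], mean)
  ig <- tapply(d$l2[d$channel == "IgG"], key[d$channel == "IgG"], mean)
  common <- intersect(names(ip), names(ig))
  if (!length(common)) stop("no peptides observed in both channels")
  parts <- strsplit(common, "|", fixed = TRUE)
  data.frame(protein_id = vapply(parts, `[[`, "", 1),
             peptide_id = vapply(parts, `[[`, "", 2),
             fc = as.numeric(ip[common] - ig[common]),
             stringsAsFactors = FALSE)
}

#' Per-protein fold-change enrichment with Welch t-test
#'
#' Protein fold change = mean of its peptides' log2 IP/IgG fold changes; p
#' from a two-tailed Welch (unequal-variance) t-test comparing the
#' protein's per-(peptide, replicate) log2 IP intensities against its log2
#' IgG intensities. The observation unit is peptide x replicate within a
#' channel; a protein observed as a single peptide in a single replicate
#' pair gets a missing p. Significant = p < `alpha` and FC > 0.
#'
#' @param norm [normalize_intensities()] output.
#' @param antibody antibody label.
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame of class `interactor_table`: `protein_id`,
#'   `n_peptides`, `fc`, `p`, `significant`.
#' @export
protein_fc_test <- function(norm, antibody, alpha = 0.05) {
  pf <- peptide_fc(norm, antibody)
  d <- .peptide_log2(norm, antibody)
  fc <- tapply(pf$fc, pf$protein_id, mean)
  npep <- tapply(pf$peptide_id, pf$protein_id, function(x) length(unique(x)))
  prots <- names(fc)
  p <- vapply(prots, function(pr) {
    x <- d$l2[d$protein_id == pr & d$channel == "IP"]
    y <- d$l2[d$protein_id == pr & d$channel == "IgG"]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    tryCatch(t.test(x, y, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, 0)
  out <- data.frame(protein_id = prots,
                    n_peptides = as.integer(npep[prots]),
                    fc = as.numeric(fc),
                    p = p,
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < alpha & out$fc > 0
  rownames(out) <- NULL
  class(out) <- c("interactor_table", "data.frame")
  out
}

#' Single-replicate enrichment rule
#'
#' With only one replicate per channel, each peptide's enrichment is the
#' difference of log2-normalized intensities (IP minus IgG); the protein
#' fold change is the mean over peptides and the p-value a two-tailed
#' one-sample t-test of the peptide differences against 0 (missing for
#' single-peptide proteins).
#'
#' @param norm [normalize_intensities()] output.
#' @param antibody antibody label.
#' @param replicate replicate id to use.
#' @param alpha significance cutoff (default 0.05).
#' @return `interactor_table` as in [protein_fc_test()].
#' @export
single_replicate_enrichment <- function(norm, antibody, replicate,
                                        alpha = 0.05) {
  d <- .peptide_log2(norm, antibody)
  d <- d[d$replicate == replicate, , drop = FALSE]
  if (!nrow(d)) stop("no rows for replicate ", replicate)
  key <- paste(d$protein_id, d$peptide_id, sep = "|")
  ip <- tapply(d$l2[d$channel == "IP"], key[d$channel == "IP"], mean)
  ig <- tapply(d$l2[d$channel == "IgG"], key[d$channel == "IgG"], mean)
  common <- intersect(names(ip), names(ig))
  diff <- as.numeric(ip[common] - ig[common])
  prot <- vapply(strsplit(common, "|", fixed = TRUE), `[[`, "", 1)
  fc <- tapply(diff, prot, mean)
  p <- vapply(names(fc), function(pr) {
    x <- diff[prot == pr]
    if (length(x) < 2 || sd(x) == 0)
      return(if (length(x) >= 2 && all(x == 0)) 1 else NA_real_)
    t.test(x, mu = 0)$p.value
  }, 0)
  out <- data.frame(protein_id = names(fc),
                    n_peptides = as.integer(table(prot)[names(fc)]),
                    fc = as.numeric(fc), p = p, stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < alpha & out$fc > 0
  rownames(out) <- NULL
  class(out) <- c("interactor_table", "data.frame")
  out
}

#' Stringent interactors supported by two antibodies
#'
#' Proteins significantly enriched (p < alpha and FC > 0) in the analyses
#' of both antibodies; the bait itself is removed from the reported set.
#'
#' @param table_a,table_b `interactor_table`s from two antibodies.
#' @param bait optional bait protein id to exclude.
#' @return character vector of protein ids, sorted.
#' @export
stringent_interactors <- function(table_a, table_b, bait = NULL) {
  sa <- table_a$protein_id[table_a$significant]
  sb <- table_b$protein_id[table_b$significant]
  out <- sort(intersect(sa, sb))
  if (!is.null(bait)) out <- setdiff(out, bait)
  out
}
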