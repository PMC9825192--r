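# Alternative-splicing event extraction from transcript structures, PSI
# computation from transcript abundances, and an empirical differential test.
#
# Event types follow the SUPPA conventions: SE skipped exon, RI retained
# intron, MX mutually exclusive exons, A5/A3 alternative 5'/3' splice site
# (strand-aware), AF/AL alternative first/last exon sharing an internal
# splice site. PSI(e, s) = sum TPM(inclusion) / sum TPM(inclusion + exclusion).

# junction key helpers: a junction is the genomic intron (donor_end,
# acceptor_start) between consecutive exons of a transcript
.jkey <- function(e, s) paste(e, s, sep = "|")

.tx_structs <- function(ann) {
  sp <- split(seq_len(nrow(ann)), ann$transcript_id)
  lapply(sp, function(i) {
    o <- i[order(ann$start[i])]
    list(s = ann$start[o], e = ann$end[o],
         chrom = ann$chrom[o[1]], strand = ann$strand[o[1]],
         gene = ann$gene_id[o[1]])
  })
}

# events between one ordered transcript pair; t1/t2 are .tx_structs entries
.pair_events <- function(t1, t2, id1, id2) {
  out <- list()
  strand <- t1$strand
  ex1 <- paste(t1$s, t1$e); ex2 <- paste(t2$s, t2$e)
  j1 <- if (length(t1$s) > 1) .jkey(t1$e[-length(t1$e)], t1$s[-1]) else character(0)
  j2 <- if (length(t2$s) > 1) .jkey(t2$e[-length(t2$e)], t2$s[-1]) else character(0)
  add <- function(type, coord, inc, exc, exons) {
    out[[length(out) + 1]] <<- list(type = type, coord = coord, inc = inc,
                                    exc = exc, exons = exons)
  }
  n1 <- length(t1$s)
  # SE: cassette exon in t1 skipped by a direct junction in t2
  if (n1 >= 3) for (k in 2:(n1 - 1)) {
    if (paste(t1$s[k], t1$e[k]) %in% ex2) next
    up <- .jkey(t1$e[k - 1], t1$s[k]); dn <- .jkey(t1$e[k], t1$s[k + 1])
    skip <- .jkey(t1$e[k - 1], t1$s[k + 1])
    if (up %in% j1 && dn %in% j1 && skip %in% j2) {
      add("SE", c(t1$e[k - 1], t1$s[k], t1$e[k], t1$s[k + 1]), id1, id2,
          data.frame(start = c(t1$s[k - 1], t1$s[k], t1$s[k + 1]),
                     end = c(t1$e[k - 1], t1$e[k], t1$e[k + 1]),
                     role = c("flank_up", "alternative", "flank_down")))
    }
  }
  # RI: t2 exon spans two consecutive t1 exons and their intron
  if (n1 >= 2) for (k in 1:(n1 - 1)) {
    if (paste(t1$s[k], t1$e[k + 1]) %in% ex2 &&
        .jkey(t1$e[k], t1$s[k + 1]) %in% j1) {
      # inclusion = the retention form (t2)
      add("RI", c(t1$s[k], t1$e[k], t1$s[k + 1], t1$e[k + 1]), id2, id1,
          data.frame(start = c(t1$s[k], t1$e[k], t1$s[k + 1]),
                     end = c(t1$e[k], t1$s[k + 1], t1$e[k + 1]),
                     role = c("flank_up", "alternative", "flank_down")))
    }
  }
  # MX: mutually exclusive cassettes sharing both flanking junction sites
  n2 <- length(t2$s)
  if (n1 >= 3 && n2 >= 3) for (k in 2:(n1 - 1)) {
    a_s <- t1$s[k]; a_e <- t1$e[k]
    if (paste(a_s, a_e) %in% ex2) next
    for (m in 2:(n2 - 1)) {
      b_s <- t2$s[m]; b_e <- t2$e[m]
      if (paste(b_s, b_e) %in% ex1) next
      if (b_s < a_e && a_s < b_e) next        # must not overlap
      c1e <- t1$e[k - 1]; c2s <- t1$s[k + 1]
      if (t2$e[m - 1] != c1e || t2$s[m + 1] != c2s) next
      if (!(.jkey(c1e, a_s) %in% j1 && .jkey(a_e, c2s) %in% j1 &&
            .jkey(c1e, b_s) %in% j2 && .jkey(b_e, c2s) %in% j2)) next
      # canonical order: genomic-left cassette first; inclusion = transcript
      # carrying the transcriptionally 5'-proximal cassette
      left_first <- a_s < b_s
      cs <- if (left_first) c(c1e, a_s, a_e, b_s, b_e, c2s)
            else c(c1e, b_s, b_e, a_s, a_e, c2s)
      prox1 <- if (strand == "+") a_s < b_s else a_e > b_e
      add("MX", cs, if (prox1) id1 else id2, if (prox1) id2 else id1,
          data.frame(start = c(a_s, b_s), end = c(a_e, b_e),
                     role = c("alternative", "alternative")))
    }
  }
  # A5/A3: junctions sharing one boundary, alternative exons overlapping
  if (length(j1) && length(j2)) {
    p1 <- cbind(t1$e[-n1], t1$s[-1])
    p2 <- cbind(t2$e[-n2], t2$s[-1])
    for (a in seq_len(nrow(p1))) for (b in seq_len(nrow(p2))) {
      d1 <- p1[a, 1]; a1 <- p1[a, 2]; d2 <- p2[b, 1]; a2 <- p2[b, 2]
      if (a1 == a2 && d1 != d2) {
        # shared acceptor, differing donor-side boundary; the two upstream
        # exons must overlap (otherwise this is an AF/AL situation)
        if (t1$s[a] < t2$e[b] && t2$s[b] < t1$e[a]) {
          type <- if (strand == "+") "A5" else "A3"
          inc1 <- d1 > d2   # more exonic sequence = inclusion
          add(type, c(min(d1, d2), max(d1, d2), a1),
              if (inc1) id1 else id2, if (inc1) id2 else id1,
              data.frame(start = c(min(t1$s[a], t2$s[b])),
                         end = c(max(d1, d2)), role = "alternative"))
        }
      } else if (d1 == d2 && a1 != a2) {
        if (t1$s[a + 1] < t2$e[b + 1] && t2$s[b + 1] < t1$e[a + 1]) {
          type <- if (strand == "+") "A3" else "A5"
          inc1 <- a1 < a2
          add(type, c(d1, min(a1, a2), max(a1, a2)),
              if (inc1) id1 else id2, if (inc1) id2 else id1,
              data.frame(start = c(min(a1, a2)),
                         end = c(max(t1$e[a + 1], t2$e[b + 1])),
                         role = "alternative"))
        }
      }
    }
  }
  # AF/AL: distinct non-overlapping terminal exons sharing the splice site
  # of the neighboring shared exon
  if (n1 >= 2 && n2 >= 2) {
    # genomic-left terminal exons, shared acceptor to the right
    f1s <- t1$s[1]; f1e <- t1$e[1]; f2s <- t2$s[1]; f2e <- t2$e[1]
    if (!(f2s < f1e && f1s < f2e) &&          # non-overlapping
        t1$s[2] == t2$s[2]) {                 # shared downstream acceptor
      type <- if (strand == "+") "AF" else "AL"
      # inclusion = the more distal terminal exon (5'-most TSS on +,
      # 3'-most TES mirrored on -)
      inc1 <- f1s < f2s
      cs <- c(min(f1s, f2s), if (f1s < f2s) f1e else f2e,
              max(f1s, f2s), if (f1s < f2s) f2e else f1e, t1$s[2])
      add(type, cs, if (inc1) id1 else id2, if (inc1) id2 else id1,
          data.frame(start = c(f1s, f2s), end = c(f1e, f2e),
                     role = c("alternative", "alternative")))
    }
    # genomic-right terminal exons, shared donor to the left
    l1s <- t1$s[n1]; l1e <- t1$e[n1]; l2s <- t2$s[n2]; l2e <- t2$e[n2]
    if (!(l2s < l1e && l1s < l2e) &&
        t1$e[n1 - 1] == t2$e[n2 - 1]) {
      type <- if (strand == "+") "AL" else "AF"
      inc1 <- l1e > l2e
      cs <- c(t1$e[n1 - 1], min(l1s, l2s), if (l1s < l2s) l1e else l2e,
              max(l1s, l2s), max(l1e, l2e))
      add(type, cs, if (inc1) id1 else id2, if (inc1) id2 else id1,
          data.frame(start = c(l1s, l2s), end = c(l1e, l2e),
                     role = c("alternative", "alternative")))
    }
  }
  out
}

#' Extract alternative-splicing events from an annotation
#'
#' All transcript pairs within each gene are compared; local structural
#' differences are classified into the seven canonical event types and
#' deduplicated by coordinates, accumulating the inclusion- and
#' exclusion-form transcript sets. Single-transcript genes yield no events.
#'
#' @param ann `gene_annotation`.
#' @return object of class `splicing_events`: list with `events` (data.frame
#'   `event_id`, `gene_id`, `type`, `chrom`, `strand`, `coord`,
#'   `inclusion`, `exclusion`; transcript lists comma-joined) and `exons`
#'   (data.frame `event_id`, `chrom`, `start`, `end`, `strand`, `role` of
#'   the defining exons).
#' @export
extract_events <- function(ann) {
  txs <- .tx_structs(ann)
  genes <- split(names(txs), vapply(txs, `[[`, "", "gene"))
  reg <- new.env(parent = emptyenv())
  for (g in names(genes)) {
    ids <- genes[[g]]
    if (length(ids) < 2) next
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      evs <- .pair_events(txs[[ids[i]]], txs[[ids[j]]], ids[i], ids[j])
      evs <- c(evs, .pair_events(txs[[ids[j]]], txs[[ids[i]]], ids[j], ids[i]))
      for (ev in evs) {
        key <- paste(g, ev$type, txs[[ids[i]]]$chrom,
                     paste(ev$coord, collapse = "-"),
                     txs[[ids[i]]]$strand, sep = ";")
        cur <- if (!is.null(reg[[key]])) reg[[key]] else
          list(gene = g, type = ev$type, chrom = txs[[ids[i]]]$chrom,
               strand = txs[[ids[i]]]$strand,
               coord = paste(ev$coord, collapse = "-"),
               inc = character(0), exc = character(0), exons = ev$exons)
        cur$inc <- union(cur$inc, ev$inc)
        cur$exc <- union(cur$exc, ev$exc)
        reg[[key]] <- cur
      }
    }
  }
  keys <- ls(reg)
  if (length(keys) == 0) {
    return(structure(list(
      events = data.frame(event_id = character(0), gene_id = character(0),
                          type = character(0), chrom = character(0),
                          strand = character(0), coord = character(0),
                          inclusion = character(0), exclusion = character(0)),
      exons = data.frame(event_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), role = character(0))),
      class = "splicing_events"))
  }
  evs <- lapply(keys, function(k) reg[[k]])
  bad <- vapply(evs, function(x) length(intersect(x$inc, x$exc)) > 0, TRUE)
  evs <- evs[!bad]
  events <- do.call(rbind, lapply(evs, function(x)
    data.frame(gene_id = x$gene, type = x$type, chrom = x$chrom,
               strand = x$strand, coord = x$coord,
               inclusion = paste(sort(x$inc), collapse = ","),
               exclusion = paste(sort(x$exc), collapse = ","),
               stringsAsFactors = FALSE)))
  events$event_id <- sprintf("%s;%s:%s:%s:%s", events$gene_id, events$type,
                             events$chrom, events$coord, events$strand)
  events <- events[order(events$gene_id, events$type, events$coord), ]
  rownames(events) <- NULL
  exons <- do.call(rbind, lapply(seq_along(evs), function(i) {
    x <- evs[[i]]
    data.frame(event_id = sprintf("%s;%s:%s:%s:%s", x$gene, x$type, x$chrom,
                                  x$coord, x$strand),
               chrom = x$chrom, start = x$exons$start, end = x$exons$end,
               strand = x$strand, role = x$exons$role,
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL
  structure(list(events = events[, c("event_id", "gene_id", "type", "chrom",
                                     "strand", "coord", "inclusion",
                                     "exclusion")],
                 exons = exons),
            class = "splicing_events")
}

#' Percent spliced-in from transcript abundances
#'
#' PSI(event, sample) = sum of inclusion-transcript TPM divided by the
#' total TPM of inclusion plus exclusion transcripts; undefined (NA) when
#' the event's total abundance is 0. Scaling all TPMs leaves PSI unchanged.
#'
#' @param events `splicing_events`.
#' @param tpm transcripts x samples matrix with transcript-id rownames.
#' @return matrix events x samples of PSI in \[0, 1\] or NA, rownames =
#'   event ids.
#' @export
psi <- function(events, tpm) {
  ev <- events$events
  all_tx <- unique(unlist(strsplit(paste(ev$inclusion, ev$exclusion, sep = ","),
                                   ",", fixed = TRUE)))
  miss <- setdiff(all_tx, rownames(tpm))
  if (length(miss))
    stop("transcripts absent from TPM matrix: ",
         paste(head(miss, 5), collapse = ", "))
  out <- matrix(NA_real_, nrow(ev), ncol(tpm),
                dimnames = list(ev$event_id, colnames(tpm)))
  for (i in seq_len(nrow(ev))) {
    inc <- strsplit(ev$inclusion[i], ",", fixed = TRUE)[[1]]
    exc <- strsplit(ev$exclusion[i], ",", fixed = TRUE)[[1]]
    num <- colSums(tpm[inc, , drop = FALSE])
    den <- num + colSums(tpm[exc, , drop = FALSE])
    out[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Empirical differential-splicing test on PSI
#'
#' Observed effect per event: dPSI = mean control PSI minus mean knockdown
#' PSI. The null distribution is built from biological variability alone:
#' absolute between-replicate PSI differences within each condition, pooled
#' over events falling in the same event-abundance bin (deciles of
#' log10(total event TPM + 1)). The empirical p is the add-one-smoothed
#' fraction of null values at least as large as |dPSI|. An event is called
#' significant when p < `alpha` and |dPSI| > `min_dpsi` (both signs pass
#' the magnitude filter).
#'
#' @param events `splicing_events`.
#' @param psi_mat [psi()] output.
#' @param tpm transcripts x samples TPM matrix (for event abundance).
#' @param condition character per sample column.
#' @param control control condition label (default "control").
#' @param n_expr_bins abundance bins for the null (default 10).
#' @param alpha p cutoff (default 0.05).
#' @param min_dpsi |dPSI| cutoff (default 0.2).
#' @return data.frame per event: `event_id`, `gene_id`, `type`, `dpsi`,
#'   `p`, `significant`; events with missing PSI in any sample get NA
#'   statistics.
#' @export
diff_psi_empirical <- function(events, psi_mat, tpm, condition,
                               control = "control", n_expr_bins = 10,
                               alpha = 0.05, min_dpsi = 0.2) {
  ev <- events$events
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2 || !control %in% lv)
    stop("need two conditions including '", control, "'")
  kd <- setdiff(lv, control)
  iC <- which(condition == control); iK <- which(condition == kd)
  if (length(iC) < 2 || length(iK) < 2)
    stop("need >= 2 replicates per condition")
  usable <- stats::complete.cases(psi_mat)
  dpsi <- rowMeans(psi_mat[, iC, drop = FALSE]) -
          rowMeans(psi_mat[, iK, drop = FALSE])
  # event abundance: log10(total event TPM + 1), mean over samples
  ab <- vapply(seq_len(nrow(ev)), function(i) {
    tx <- strsplit(paste(ev$inclusion[i], ev$exclusion[i], sep = ","),
                   ",", fixed = TRUE)[[1]]
    log10(mean(colSums(tpm[tx, , drop = FALSE])) + 1)
  }, 0)
  qs <- quantile(ab[usable], probs = seq(0, 1, length.out = n_expr_bins + 1),
                 na.rm = TRUE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(ab, qs, labels = FALSE)
  # null: between-replicate |dPSI| within condition, pooled per bin
  null_of <- function(i) {
    vals <- c()
    for (idx in list(iC, iK)) {
      cmb <- utils::combn(idx, 2)
      for (cc in seq_len(ncol(cmb)))
        vals <- c(vals, abs(psi_mat[i, cmb[1, cc]] - psi_mat[i, cmb[2, cc]]))
    }
    vals
  }
  null_by_bin <- lapply(seq_len(n_expr_bins), function(b) {
    i <- which(usable & bin == b)
    if (!length(i)) return(numeric(0))
    unlist(lapply(i, null_of))
  })
  p <- rep(NA_real_, nrow(ev))
  for (i in which(usable)) {
    nv <- null_by_bin[[bin[i]]]
    p[i] <- (1 + sum(nv >= abs(dpsi[i]))) / (1 + length(nv))
  }
  dpsi[!usable] <- NA
  data.frame(event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
             dpsi = dpsi, p = p,
             significant = !is.na(p) & p < alpha & abs(dpsi) > min_dpsi,
             stringsAsFactors = FALSE)
}

#' Event-type and dPSI-sign census
#'
#' @param results data.frame with columns `dpsi` and optionally `type`
#'   (e.g. [diff_psi_empirical()] output, typically pre-filtered to
#'   significant events).
#' @return list with `by_type` (count and percent per event type) and
#'   `by_sign` (count and percent of positive / negative dPSI among events
#'   with nonzero dPSI).
#' @export
event_type_summary <- function(results) {
  by_type <- NULL
  if (!is.null(results$type)) {
    tab <- table(results$type)
    by_type <- data.frame(type = names(tab), count = as.integer(tab),
                          percent = 100 * as.integer(tab) / sum(tab),
                          stringsAsFactors = FALSE)
  }
  d <- results$dpsi[!is.na(results$dpsi) & results$dpsi != 0]
  np <- sum(d > 0); nn <- sum(d < 0)
  by_sign <- data.frame(sign = c("positive", "negative"),
                        count = c(np, nn),
                        percent = if (np + nn > 0)
                          100 * c(np, nn) / (np + nn) else c(NA, NA),
                        stringsAsFactors = FALSE)
  list(by_type = by_type, by_sign = by_sign)
}

#' Flag events whose defining exons overlap a peak set
#'
#' @param events `splicing_events`.
#' @param peaks interval data.frame (e.g. lost H3K36me3 peaks).
#' @return data.frame `event_id`, `overlaps` (any defining exon with >= 1 bp
#'   overlap).
#' @export
intersect_events_peaks <- function(events, peaks) {
  ex <- events$exons
  hit <- overlaps_any(ex, as.data.frame(peaks))
  ov <- tapply(hit, ex$event_id, any)
  ids <- events$events$event_id
  data.frame(event_id = ids,
             overlaps = as.logical(ov[ids]) %in% TRUE,
             stringsAsFactors = FALSE)
}

#' PSI from gel-band intensities
#'
#' in / (in + out), the densitometry analogue of percent spliced-in.
#'
#' @param in_intensity,out_intensity non-negative band intensities, not
#'   both zero.
#' @return PSI in \[0, 1\].
#' @export
psi_from_band_intensities <- function(in_intensity, out_intensity) {
  if (any(in_intensity < 0) || any(out_intensity < 0))
    stop("intensities must be >= 0")
  if (any(in_intensity + out_intensity == 0))
    stop("both intensities zero: PSI undefined")
  in_intensity / (in_intensity + out_intensity)
}
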