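# Deterministic synthetic-data generator. Every pipeline input is simulated
# with planted, machine-readable ground truth: a compact two-chromosome
# genome with multi-isoform genes covering all seven splicing event types;
# histone-mark and remodeler peak sets in two conditions with H3K36me3 loss
# planted over a subset of remodeler-bound gene bodies; Poisson ChIP and
# input coverage tracks; transcript TPMs with planted PSI shifts; AP-MS
# peptide intensities with planted true interactors; and exon-flank
# sequences with a planted RBP motif.
#
# Each artifact derives its own RNG stream from the master seed plus a
# stable label, so generating one output never perturbs another.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 2 x 5 Mb genome, 300 genes, 60 remodeler-bound genes of which
#' half lose gene-body H3K36me3 in knockdown, 80 splicing events shifted by
#' |dPSI| = 0.35, 2 ChIP and 3 RNA replicates per condition, and AP-MS
#' interactors shifted by 2 log2 units with 0.3 log2 noise.
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes (>= 7 so all event types occur).
#' @param frac_expressed fraction of genes expressed (with gene-body
#'   H3K36me3 in control).
#' @param n_chd8_bound remodeler-bound genes (subset of expressed).
#' @param fraction_bound_losing_k36 fraction f of bound genes losing body
#'   H3K36me3 in knockdown.
#' @param n_as_events_shifted events with a planted PSI shift.
#' @param planted_delta_psi |dPSI| planted (control minus knockdown sign
#'   chosen per event so PSI stays in range).
#' @param frac_shifted_in_lost fraction of shifted events placed in
#'   K36-losing genes (capped by availability).
#' @param n_replicates_chip,n_replicates_rna replicates per condition.
#' @param psi_replicate_sd replicate noise on PSI.
#' @param expr_meanlog,expr_sdlog,expr_rep_sd gene-expression lognormal
#'   parameters and replicate jitter (log scale).
#' @param chip_rate,bg_rate,input_rate Poisson rates per 10 bp track bin
#'   inside peaks, outside peaks, and in the input.
#' @param track_bin track bin size (bp).
#' @param peak_jitter replicate jitter on peak edges (bp).
#' @param n_noise_peaks,noise_peak_width minor consistent binding sites per
#'   mark outside the planted architecture.
#' @param n_enhancers,enhancer_width enhancer elements (H3K4me1/H3K27ac).
#' @param n_proteins,n_true_interactors,interactor_log2_shift,
#'   peptide_noise_sd,ms_replicates,igg_missing_frac,peptides_range AP-MS
#'   design.
#' @param motif_plant_rate fraction of flank sequences carrying the planted
#'   motif consensus.
#' @param flank_len flank length (nt).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42,
                       n_chroms = 2, chrom_length = 5e6,
                       n_genes = 300, frac_expressed = 0.8,
                       n_chd8_bound = 60,
                       fraction_bound_losing_k36 = 0.5,
                       n_as_events_shifted = 80,
                       planted_delta_psi = 0.35,
                       frac_shifted_in_lost = 0.5,
                       n_replicates_chip = 2, n_replicates_rna = 3,
                       psi_replicate_sd = 0.02,
                       expr_meanlog = log(50), expr_sdlog = 0.8,
                       expr_rep_sd = 0.15,
                       chip_rate = 2, bg_rate = 0.2, input_rate = 0.25,
                       track_bin = 10, peak_jitter = 200,
                       n_noise_peaks = 40, noise_peak_width = 400,
                       n_enhancers = 150, enhancer_width = 600,
                       n_proteins = 400, n_true_interactors = 20,
                       interactor_log2_shift = 2, peptide_noise_sd = 0.3,
                       ms_replicates = 3, igg_missing_frac = 0.1,
                       peptides_range = c(2, 10),
                       motif_plant_rate = 0.4, flank_len = 100) {
  cfg <- as.list(environment())
  if (cfg$fraction_bound_losing_k36 < 0 || cfg$fraction_bound_losing_k36 > 1)
    stop("fraction_bound_losing_k36 must be in [0, 1]")
  if (abs(cfg$planted_delta_psi) > 1) stop("|planted_delta_psi| must be <= 1")
  if (cfg$n_genes < 7) stop("need at least 7 genes (one per event type)")
  if (cfg$n_chd8_bound > cfg$n_genes * cfg$frac_expressed)
    stop("n_chd8_bound exceeds expressed genes")
  class(cfg) <- "sim_config"
  cfg
}

.event_cycle <- c("SE", "RI", "MX", "A5", "A3", "AF", "AL")

# one gene template on the plus orientation in local coordinates;
# returns exon tables for T1/T2 and the planted event type
.gene_template <- function(type) {
  n_ex <- sample(5:7, 1)
  ex_len <- 10 * sample(15:35, n_ex, replace = TRUE)
  int_len <- 10 * sample(50:150, n_ex - 1, replace = TRUE)
  if (type == "A5") int_len[2] <- max(int_len[2], 400)
  if (type == "A3") int_len[2] <- max(int_len[2], 400)
  if (type == "MX") int_len[3] <- max(int_len[3], 1200)
  s <- cumsum(c(0, head(ex_len, -1) + int_len))
  e <- s + ex_len
  t1 <- cbind(s, e)
  t2 <- NULL
  extra <- NULL
  if (type == "SE") {
    t2 <- t1[-3, , drop = FALSE]
  } else if (type == "RI") {
    t2 <- rbind(t1[1, ], c(t1[2, 1], t1[3, 2]), t1[-(1:3), , drop = FALSE])
  } else if (type == "MX") {
    # cassette B inside the (enlarged) intron after exon 3; A = exon 3
    b_s <- e[3] + 300; b_e <- b_s + 200
    stopifnot(b_e + 100 <= s[4])
    t1mx <- t1
    t2 <- rbind(t1[1:2, ], c(b_s, b_e), t1[4:n_ex, , drop = FALSE])
    t1 <- t1mx
  } else if (type == "A5") {
    t2 <- t1; t2[2, 2] <- t2[2, 2] + 100          # donor of exon 2 extended
  } else if (type == "A3") {
    t2 <- t1; t2[3, 1] <- t2[3, 1] - 100          # acceptor of exon 3 earlier
  } else if (type == "AF") {
    f_len <- 200; gap <- 600
    extra <- c(-(gap + f_len), -gap)              # alt first exon upstream
    t2 <- rbind(extra, t1[-1, , drop = FALSE])
  } else if (type == "AL") {
    l_len <- 200; gap <- 600
    alt <- c(e[n_ex] + gap, e[n_ex] + gap + l_len)
    t2 <- rbind(t1[-n_ex, , drop = FALSE], alt)
  }
  list(t1 = t1, t2 = t2)
}

#' Simulate a gene annotation with engineered splicing events
#'
#' Genes are placed with generous spacing (>= 4 kbp gaps) and lengths above
#' the metagene filters' 2 kbp minimum; each gene carries two transcripts
#' engineered to produce exactly one splicing event, with the seven event
#' types cycled across genes so every type is represented. Coordinates are
#' aligned to a 10 bp grid to match the track binning.
#'
#' @param config `sim_config`.
#' @return list: `annotation` (`gene_annotation`), `gene_types` (data.frame
#'   `gene_id`, `event_type`, `strand`), `chrom_lengths` (named vector).
#' @export
simulate_annotation <- function(config) {
  with_seed(derive_seed(config$seed, "annotation"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    per_chrom <- ceiling(config$n_genes / config$n_chroms)
    rows <- list()
    meta <- list()
    gi <- 0
    for (ch in chroms) {
      cursor <- 20000
      for (k in seq_len(per_chrom)) {
        gi <- gi + 1
        if (gi > config$n_genes) break
        type <- .event_cycle[(gi - 1) %% 7 + 1]
        tpl <- .gene_template(type)
        all_xy <- rbind(tpl$t1, tpl$t2)
        off <- -min(all_xy)                        # shift so local min = 0
        span <- max(all_xy) + off
        strand <- sample(c("+", "-"), 1)
        gap <- 10 * sample(600:1200, 1)
        if (cursor + span + gap > config$chrom_length - 20000)
          stop("genome too small for requested gene count")
        place <- function(m) {
          m <- m + off
          if (strand == "-") m <- cbind(span - m[, 2], span - m[, 1])
          m + cursor
        }
        g <- sprintf("G%03d", gi)
        gene_type <- if (gi %% 29 == 0) "lncRNA" else "protein_coding"
        for (tx in c("T1", "T2")) {
          m <- place(if (tx == "T1") tpl$t1 else tpl$t2)
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, transcript_id = paste(g, tx, sep = "."),
            chrom = ch, strand = strand,
            start = as.integer(m[, 1]), end = as.integer(m[, 2]),
            gene_type = gene_type, stringsAsFactors = FALSE)
        }
        meta[[gi]] <- data.frame(gene_id = g, event_type = type,
                                 strand = strand, stringsAsFactors = FALSE)
        cursor <- cursor + span + gap
      }
    }
    cl <- stats::setNames(rep(as.integer(config$chrom_length),
                              length(chroms)), chroms)
    list(annotation = gene_annotation(do.call(rbind, rows)),
         gene_types = do.call(rbind, meta), chrom_lengths = cl)
  })
}

#' Draw the planted ground truth
#'
#' @param config `sim_config`.
#' @param sim [simulate_annotation()] output.
#' @return list of class `ground_truth`: `genes` (data.frame with
#'   `expressed`, `chd8_bound`, `k36_loss` flags), `events` (data.frame
#'   `gene_id`, `event_type`, `psi_ctrl`, `delta_psi` for shifted events),
#'   `interactors` (planted true-interactor protein ids).
#' @export
simulate_truth <- function(config, sim) {
  with_seed(derive_seed(config$seed, "truth"), {
    gt <- sim$gene_types
    n <- nrow(gt)
    expressed <- sort(sample(n, round(config$frac_expressed * n)))
    bound <- sort(sample(expressed, config$n_chd8_bound))
    loss <- sort(sample(bound,
                        round(config$fraction_bound_losing_k36 *
                                length(bound))))
    n_sh <- min(config$n_as_events_shifted, length(expressed))
    n_in_loss <- min(length(loss),
                     round(config$frac_shifted_in_lost * n_sh))
    sh_loss <- sort(sample(loss, n_in_loss))
    pool <- setdiff(expressed, loss)
    sh_other <- sort(sample(pool, n_sh - n_in_loss))
    shifted <- c(sh_loss, sh_other)
    psi0 <- runif(n_sh, 0.45, 0.60)
    sgn <- ifelse(runif(n_sh) < 0.5, 1, -1)
    genes <- data.frame(gene_id = gt$gene_id,
                        event_type = gt$event_type,
                        expressed = seq_len(n) %in% expressed,
                        chd8_bound = seq_len(n) %in% bound,
                        k36_loss = seq_len(n) %in% loss,
                        stringsAsFactors = FALSE)
    events <- data.frame(gene_id = gt$gene_id[shifted],
                         event_type = gt$event_type[shifted],
                         psi_ctrl = psi0,
                         delta_psi = sgn * config$planted_delta_psi,
                         stringsAsFactors = FALSE)
    interactors <- sprintf("P%04d", seq_len(config$n_true_interactors))
    structure(list(genes = genes, events = events,
                   interactors = interactors),
              class = "ground_truth")
  })
}

.snap <- function(x, grid = 200) as.integer(round(x / grid) * grid)

# planted peak architecture (condition-independent base coordinates)
.peak_architecture <- function(config, sim, truth) {
  gt <- gene_table(sim$annotation)
  gt <- gt[match(truth$genes$gene_id, gt$gene_id), ]
  tg <- truth$genes
  cl <- sim$chrom_lengths
  tss_peak <- function(idx, half) {
    i <- which(idx)
    data.frame(chrom = gt$chrom[i],
               start = pmax(0L, .snap(gt$tss[i] - half)),
               end = .snap(gt$tss[i] + half),
               gene_id = gt$gene_id[i], stringsAsFactors = FALSE)
  }
  body_peak <- function(idx) {
    b <- gene_bodies(gt[idx, , drop = FALSE])
    data.frame(chrom = b$chrom, start = .snap(b$start), end = .snap(b$end),
               gene_id = b$gene_id, stringsAsFactors = FALSE)
  }
  # promoter-proximal H3K36me3, retained in knockdown: deposition over the
  # 5' kilobase is initiation-coupled, unlike the elongation-coupled body
  # signal that the knockdown removes
  prom_k36 <- function(idx) {
    i <- which(idx)
    s <- ifelse(gt$strand[i] == "+", gt$tss[i] - 200, gt$tss[i] - 400)
    data.frame(chrom = gt$chrom[i], start = pmax(0L, .snap(s)),
               end = .snap(s + 600),
               gene_id = gt$gene_id[i], stringsAsFactors = FALSE)
  }
  # intergenic region sampler: minor binding sites and enhancers are kept
  # clear of gene spans (+/- 1 kb) so planted gene-body effects stay clean
  rand_regions <- function(nper, width, label) {
    out <- lapply(names(cl), function(ch) {
      gs <- gt[gt$chrom == ch, ]
      cand <- .snap(runif(nper * 5, 30000, cl[[ch]] - 30000))
      ok <- !vapply(cand, function(s)
        any(gs$start - 1000 < s + width & s < gs$end + 1000), TRUE)
      s <- head(cand[ok], nper)
      data.frame(chrom = ch, start = s, end = s + as.integer(width),
                 gene_id = NA_character_, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  arch <- list()
  arch$H3K4me3 <- tss_peak(tg$expressed, 400)
  arch$H3K4me2 <- tss_peak(tg$expressed, 600)
  arch$CHD8 <- tss_peak(tg$chd8_bound, 200)
  arch$H3K36me3 <- body_peak(tg$expressed)
  arch$H3K27me3 <- rbind(body_peak(!tg$expressed),
                         rand_regions(15, 2000, "domain"))
  enh <- rand_regions(ceiling(config$n_enhancers / length(cl)),
                      config$enhancer_width, "enh")
  arch$H3K4me1 <- enh
  arch$H3K27ac <- enh
  for (m in names(arch)) {
    noise <- rand_regions(ceiling(config$n_noise_peaks / length(cl)),
                          config$noise_peak_width, "noise")
    arch[[m]] <- rbind(arch[[m]], noise)
    arch[[m]]$kd_retained <- FALSE
  }
  prom <- prom_k36(tg$expressed)
  prom$kd_retained <- TRUE
  arch$H3K36me3 <- rbind(arch$H3K36me3, prom)
  arch
}

#' Simulate per-sample peak sets and coverage tracks
#'
#' Control samples carry gene-body H3K36me3 over expressed genes; knockdown
#' samples lack those peaks over the planted-loss gene set. Promoter marks
#' sit at TSSs of expressed genes, the remodeler at bound-gene TSSs,
#' enhancer marks at shared enhancer elements, and the repressive mark over
#' silent gene bodies and random domains, with consistent minor noise sites
#' per mark. Replicates jitter peak edges. Tracks are Poisson draws around
#' a peak-shaped mean (`chip_rate` inside peaks over `bg_rate` background,
#' per 10 bp bin); inputs are flat Poisson.
#'
#' @param config `sim_config`.
#' @param sim [simulate_annotation()] output.
#' @param truth [simulate_truth()] output.
#' @param tracks generate coverage tracks too (default TRUE; peak sets are
#'   cheap, tracks dominate memory).
#' @return list: `peaksets` (list of `list(mark, condition, sample_id,
#'   peaks)`), `tracks` (`tracks[[sample_id]][[mark]]`), `inputs`
#'   (`inputs[[sample_id]]`), `chrom_lengths`.
#' @export
simulate_peaks_and_tracks <- function(config, sim, truth, tracks = TRUE) {
  arch <- with_seed(derive_seed(config$seed, "architecture"),
                    .peak_architecture(config, sim, truth))
  loss_genes <- truth$genes$gene_id[truth$genes$k36_loss]
  cl <- sim$chrom_lengths
  peaksets <- list()
  track_list <- list()
  input_list <- list()
  for (cond in c("control", "kd")) {
    for (rep_i in seq_len(config$n_replicates_chip)) {
      sid <- paste(cond, rep_i, sep = "_")
      samp_peaks <- with_seed(derive_seed(config$seed,
                                          paste("peaks", sid)), {
        lapply(names(arch), function(m) {
          pk <- arch[[m]]
          if (m == "H3K36me3" && cond == "kd")
            pk <- pk[pk$kd_retained | !(pk$gene_id %in% loss_genes),
                     , drop = FALSE]
          # replicate jitter: whole-peak shifts on the 200 bp placement
          # grid (width preserved), mostly zero, emulating consistent
          # binding with occasional boundary wobble
          j <- config$peak_jitter *
            sample(c(-1L, 0L, 1L), nrow(pk), replace = TRUE,
                   prob = c(0.15, 0.7, 0.15))
          s <- pmax(0L, pk$start + j)
          e <- pmin(as.integer(cl[pk$chrom]), pk$end + j)
          keep <- e - s >= 100
          genomic_intervals(pk$chrom[keep], s[keep], e[keep])
        })
      })
      names(samp_peaks) <- names(arch)
      for (m in names(arch))
        peaksets[[length(peaksets) + 1]] <-
          list(mark = m, condition = cond, sample_id = sid,
               peaks = samp_peaks[[m]])
      if (tracks) {
        tl <- list()
        for (m in names(arch)) {
          tl[[m]] <- with_seed(derive_seed(config$seed,
                                           paste("track", sid, m)),
                               .poisson_track(samp_peaks[[m]], cl,
                                              config$track_bin,
                                              config$bg_rate,
                                              config$chip_rate))
        }
        track_list[[sid]] <- tl
        input_list[[sid]] <- with_seed(derive_seed(config$seed,
                                                   paste("input", sid)),
                                       .poisson_track(NULL, cl,
                                                      config$track_bin,
                                                      config$input_rate, 0))
      }
    }
  }
  list(peaksets = peaksets, tracks = track_list, inputs = input_list,
       chrom_lengths = cl)
}

.poisson_track <- function(peaks, chrom_lengths, bin, bg_rate, peak_rate,
                           pad = 200) {
  # pad emulates fragment-extension smear: ChIP coverage extends a fragment
  # length beyond the called peak boundaries
  vals <- lapply(names(chrom_lengths), function(ch) {
    n <- as.integer(ceiling(chrom_lengths[[ch]] / bin))
    mu <- rep(bg_rate, n)
    if (!is.null(peaks) && nrow(peaks)) {
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(pk))) {
        b0 <- max(1L, (pk$start[i] - pad) %/% bin + 1L)
        b1 <- min(n, as.integer(ceiling((pk$end[i] + pad) / bin)))
        if (b1 >= b0) mu[b0:b1] <- mu[b0:b1] + peak_rate
      }
    }
    as.numeric(rpois(n, mu))
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, bin, chrom_lengths)
}

#' Simulate transcript TPMs with planted PSI shifts
#'
#' Gene expression is lognormal with replicate jitter; within each gene the
#' inclusion isoform's share is the gene's PSI (uniform for unshifted
#' genes, `psi_ctrl` vs `psi_ctrl - delta_psi` for planted events, so that
#' dPSI = PSI_control - PSI_knockdown equals the planted value), with
#' replicate noise. Every column is normalized to sum to 1e6 TPM.
#'
#' @param config `sim_config`.
#' @param sim [simulate_annotation()] output.
#' @param truth [simulate_truth()] output.
#' @param events `splicing_events` from [extract_events()] on the
#'   annotation (identifies each gene's inclusion transcript).
#' @return list: `tpm` (transcripts x samples), `condition` (per column),
#'   `realized_dpsi` (named per shifted gene, before replicate noise).
#' @export
simulate_expression <- function(config, sim, truth, events) {
  with_seed(derive_seed(config$seed, "expression"), {
    gt <- truth$genes
    n <- nrow(gt)
    ev <- events$events
    inc_tx <- vapply(gt$gene_id, function(g) {
      i <- which(ev$gene_id == g)
      if (!length(i)) return(NA_character_)
      strsplit(ev$inclusion[i[1]], ",")[[1]][1]
    }, "")
    base_expr <- ifelse(gt$expressed,
                        rlnorm(n, config$expr_meanlog, config$expr_sdlog),
                        runif(n, 0.02, 0.3))
    psi_ctrl <- runif(n, 0.35, 0.65)
    psi_kd <- psi_ctrl
    m <- match(truth$events$gene_id, gt$gene_id)
    psi_ctrl[m] <- truth$events$psi_ctrl
    psi_kd[m] <- truth$events$psi_ctrl - truth$events$delta_psi
    samples <- c(outer(seq_len(config$n_replicates_rna),
                       c("control", "kd"),
                       function(r, cc) paste(cc, r, sep = "_")))
    condition <- rep(c("control", "kd"), each = config$n_replicates_rna)
    tx_ids <- unique(sim$annotation$transcript_id)
    tpm <- matrix(0, length(tx_ids), length(samples),
                  dimnames = list(tx_ids, samples))
    for (ci in seq_along(samples)) {
      cond <- condition[ci]
      psi_g <- if (cond == "control") psi_ctrl else psi_kd
      psi_s <- pmin(pmax(psi_g + rnorm(n, 0, config$psi_replicate_sd),
                         0.02), 0.98)
      expr_s <- base_expr * exp(rnorm(n, 0, config$expr_rep_sd))
      for (gi in seq_len(n)) {
        g <- gt$gene_id[gi]
        t1 <- paste(g, "T1", sep = "."); t2 <- paste(g, "T2", sep = ".")
        inc <- inc_tx[gi]
        if (is.na(inc)) inc <- t1
        exc <- if (inc == t1) t2 else t1
        tpm[inc, ci] <- expr_s[gi] * psi_s[gi]
        tpm[exc, ci] <- expr_s[gi] * (1 - psi_s[gi])
      }
    }
    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
    realized <- stats::setNames(psi_ctrl[m] - psi_kd[m],
                                truth$events$gene_id)
    list(tpm = tpm, condition = condition, realized_dpsi = realized)
  })
}

#' Simulate AP-MS peptide intensities for two antibodies
#'
#' Per protein, 2-10 peptides measured in IP and IgG channels over
#' replicates. Background proteins share a mean between channels; planted
#' true interactors have their IP mean shifted by `interactor_log2_shift`
#' log2 units. Intensities are lognormal around the channel mean
#' (`peptide_noise_sd` on the log2 scale, independent across observations);
#' a fraction of IgG entries is missing at random.
#'
#' @param config `sim_config`.
#' @param truth optional [simulate_truth()] output (for the interactor
#'   ids); when NULL the first `n_true_interactors` proteins are planted.
#' @return list: `table` (long peptide data.frame over both antibodies
#'   "ab17"/"ab18"), `true_interactors`.
#' @export
simulate_peptides <- function(config, truth = NULL) {
  with_seed(derive_seed(config$seed, "peptides"), {
    prots <- sprintf("P%04d", seq_len(config$n_proteins))
    true_set <- if (!is.null(truth)) truth$interactors
                else prots[seq_len(config$n_true_interactors)]
    n_pep <- sample(config$peptides_range[1]:config$peptides_range[2],
                    config$n_proteins, replace = TRUE)
    base <- rnorm(config$n_proteins, 20, 2)
    shift <- ifelse(prots %in% true_set, config$interactor_log2_shift, 0)
    pep_prot <- rep(seq_len(config$n_proteins), n_pep)
    pep_id <- sprintf("%s_pep%d", prots[pep_prot],
                      sequence(n_pep))
    grid <- expand.grid(obs = seq_along(pep_prot),
                        replicate = seq_len(config$ms_replicates),
                        channel = c("IP", "IgG"),
                        antibody = c("ab17", "ab18"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pi <- pep_prot[grid$obs]
    mu <- base[pi] + ifelse(grid$channel == "IP", shift[pi], 0)
    val <- 2^(mu + rnorm(nrow(grid), 0, config$peptide_noise_sd))
    val[grid$channel == "IgG" &
          runif(nrow(grid)) < config$igg_missing_frac] <- NA_real_
    tab <- data.frame(protein_id = prots[pi], peptide_id = pep_id[grid$obs],
                      antibody = grid$antibody, channel = grid$channel,
                      replicate = grid$replicate, intensity = val,
                      stringsAsFactors = FALSE)
    list(table = tab, true_interactors = true_set)
  })
}

#' Simulate exon-flank sequences with a planted RBP motif
#'
#' Sequences are iid draws from the background nucleotide distribution; a
#' subset (per-sequence planting probability) receives the planted motif's
#' consensus at a random offset. A small decoy motif set accompanies the
#' planted one.
#'
#' @param config `sim_config`.
#' @param seq_ids sequence names to generate.
#' @param plant_prob per-sequence planting probability (recycled; default
#'   `config$motif_plant_rate`).
#' @param background nucleotide frequencies (A, C, G, T).
#' @return list: `sequences` (named character), `pwms` (list of `pwm`;
#'   first is the planted motif), `family_map`, `planted` (data.frame
#'   `sequence_id`, `offset`; offset NA when unplanted).
#' @export
simulate_flank_sequences <- function(config, seq_ids,
                                     plant_prob = NULL,
                                     background = c(0.3, 0.2, 0.2, 0.3)) {
  if (is.null(plant_prob)) plant_prob <- config$motif_plant_rate
  plant_prob <- rep_len(plant_prob, length(seq_ids))
  with_seed(derive_seed(config$seed, "motifs"), {
    L <- 2 * config$flank_len
    bases <- c("A", "C", "G", "T")
    sharp <- function(cons) {
      W <- nchar(cons)
      m <- matrix((1 - 0.94) / 3, 4, W, dimnames = list(bases, NULL))
      idx <- match(strsplit(cons, "")[[1]], bases)
      m[cbind(idx, seq_len(W))] <- 0.94
      m
    }
    pl <- pwm(sharp("ACACACA"), "M_planted", family = "CA_rich",
              background = background)
    decoys <- list(pwm(sharp("GGTAAGT"), "M_decoy1", family = "decoyA",
                       background = background),
                   pwm(sharp("TTTCGCG"), "M_decoy2", family = "decoyB",
                       background = background))
    cons <- "ACACACA"
    seqs <- character(length(seq_ids))
    offs <- rep(NA_integer_, length(seq_ids))
    for (i in seq_along(seq_ids)) {
      s <- sample(bases, L, replace = TRUE, prob = background)
      if (runif(1) < plant_prob[i]) {
        o <- sample(L - nchar(cons) + 1, 1)
        s[o:(o + nchar(cons) - 1)] <- strsplit(cons, "")[[1]]
        offs[i] <- o
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- seq_ids
    pwms <- c(list(pl), decoys)
    fam <- stats::setNames(vapply(pwms, `[[`, "", "family"),
                           vapply(pwms, `[[`, "", "motif_id"))
    list(sequences = seqs, pwms = pwms, family_map = fam,
         planted = data.frame(sequence_id = seq_ids, offset = offs,
                              stringsAsFactors = FALSE))
  })
}

#' Write the synthetic bundle to disk
#'
#' Emits the GTF annotation, per-sample peak BEDs, optionally bedGraph
#' tracks, the TPM matrix, the peptide table, the flank FASTA and PWM TSV,
#' machine-readable ground-truth TSVs and the config as YAML.
#'
#' @param config `sim_config`.
#' @param dir output directory (created).
#' @param tracks also write bedGraph tracks (large; default FALSE).
#' @return the directory, invisibly.
#' @export
write_synthetic_bundle <- function(config, dir, tracks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotation(config)
  truth <- simulate_truth(config, sim)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  ev <- extract_events(sim$annotation)
  expr <- simulate_expression(config, sim, truth, ev)
  write_tpm(expr$tpm, file.path(dir, "tpm.tsv"))
  pk <- simulate_peaks_and_tracks(config, sim, truth, tracks = tracks)
  for (p in pk$peaksets)
    write_bed(p$peaks, file.path(dir, sprintf("peaks_%s_%s.bed", p$mark,
                                              p$sample_id)))
  if (tracks) {
    for (sid in names(pk$tracks)) {
      for (m in names(pk$tracks[[sid]]))
        write_bedgraph(pk$tracks[[sid]][[m]],
                       file.path(dir, sprintf("track_%s_%s.bedgraph",
                                              m, sid)))
      write_bedgraph(pk$inputs[[sid]],
                     file.path(dir, sprintf("input_%s.bedgraph", sid)))
    }
  }
  pep <- simulate_peptides(config, truth)
  data.table::fwrite(pep$table, file.path(dir, "peptides.tsv"), sep = "\t")
  sig_ids <- ev$events$event_id[ev$events$gene_id %in%
                                  truth$events$gene_id]
  fl <- simulate_flank_sequences(config, sig_ids)
  writeLines(paste0(">", names(fl$sequences), "\n", fl$sequences),
             file.path(dir, "flanks.fasta"))
  write_pwms(fl$pwms, file.path(dir, "motifs.tsv"))
  data.table::fwrite(truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t")
  writeLines(sort(truth$interactors), file.path(dir, "truth_interactors.txt"))
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
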