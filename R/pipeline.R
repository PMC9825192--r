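#' Run the full synthetic-data analysis pipeline
#'
#' Generates every input from the configuration, then executes the stages
#' in order: peak harmonization (narrow-mark merging, replicate-common
#' peaks), chromatin-state segmentation on the pooled control samples with
#' per-state peak-count contrasts, gene-body H3K36me3 loss detection,
#' negative-binomial differential binding over H3K36me3 consensus peaks,
#' PSI differential splicing with the empirical null, event-peak
#' intersection, RBP motif scanning of event flank sequences, AP-MS
#' interactor scoring for two antibodies, and the gene-set overlap
#' statistics tying H3K36me3 loss to splicing change. Fully deterministic
#' given the config seed.
#'
#' @param config `sim_config`.
#' @param K chromatin states (default 10).
#' @param hmm_max_iter Baum-Welch iteration budget (default 100).
#' @param out_dir optional directory for the JSON summary and TSV tables.
#' @return list of class `chromsplice_report` with elements `truth`,
#'   `contrast`, `state_labels`, `k36`, `diffbind`, `splicing`, `motifs`,
#'   `ms`, `integration` and `summary` (flat named list of headline
#'   numbers).
#' @export
run_pipeline <- function(config = sim_config(), K = 10, hmm_max_iter = 100,
                         out_dir = NULL) {
  sim <- simulate_annotation(config)
  truth <- simulate_truth(config, sim)
  ann <- sim$annotation
  gt <- gene_table(ann)
  ev <- extract_events(ann)
  expr <- simulate_expression(config, sim, truth, ev)
  pk <- simulate_peaks_and_tracks(config, sim, truth, tracks = TRUE)

  narrow <- c("H3K27ac", "H3K4me1", "H3K4me2", "H3K4me3")
  # per-(mark, condition) replicate-common harmonized peaks
  harmonized <- list()
  for (m in unique(vapply(pk$peaksets, `[[`, "", "mark"))) {
    for (cond in c("control", "kd")) {
      reps <- Filter(function(p) p$mark == m && p$condition == cond,
                     pk$peaksets)
      sets <- lapply(reps, function(p)
        if (m %in% narrow) merge_close(p$peaks) else p$peaks)
      harmonized[[paste(m, cond, sep = ".")]] <-
        if (length(sets) >= 2) common_peaks_all(sets) else sets[[1]]
    }
  }

  # chromatin states on pooled control tracks (histone marks only; the
  # remodeler ChIP is contrasted across states but not a segmentation input)
  ctrl_sids <- grep("^control", names(pk$tracks), value = TRUE)
  marks <- setdiff(names(pk$tracks[[1]]), "CHD8")
  pooled <- lapply(marks, function(m) {
    vals <- pk$tracks[[ctrl_sids[1]]][[m]]$values
    for (sid in ctrl_sids[-1])
      vals <- Map(`+`, vals, pk$tracks[[sid]][[m]]$values)
    signal_track(vals, config$track_bin, pk$chrom_lengths)
  })
  names(pooled) <- marks
  bm <- binarized_matrix(lapply(pooled, binarize), bin_size = 200)
  model <- fit_hmm(bm, K = K, seed = derive_seed(config$seed, "hmm"),
                   max_iter = hmm_max_iter)
  model$state_labels <- label_states_by_emission(model)
  seg <- segment_genome(model, bm)
  seg$state_labels <- model$state_labels
  contrast <- state_mark_contrast(seg, pk$peaksets)

  # gene-body H3K36me3 loss (body = span past the promoter zone)
  bodies <- gene_bodies(gt)
  k36_ctrl <- harmonized[["H3K36me3.control"]]
  k36_kd <- harmonized[["H3K36me3.kd"]]
  n_body_ctrl <- count_in_segments(k36_ctrl, bodies)
  n_body_kd <- count_in_segments(k36_kd, bodies)
  lost_peaks <- k36_ctrl[!overlaps_any(k36_ctrl, k36_kd), , drop = FALSE]
  body_hit <- function(peaks) gt$gene_id[overlaps_any(bodies, peaks)]
  lost_genes <- setdiff(body_hit(k36_ctrl), body_hit(k36_kd))
  pct_loss <- if (n_body_ctrl > 0)
    100 * (n_body_ctrl - n_body_kd) / n_body_ctrl else NA_real_

  # differential binding over H3K36me3 consensus peaks
  k36_sets <- Filter(function(p) p$mark == "H3K36me3", pk$peaksets)
  consensus <- consensus_peaks(lapply(k36_sets, `[[`, "peaks"),
                               min_samples = 2)
  k36_tracks <- lapply(k36_sets, function(p)
    pk$tracks[[p$sample_id]][["H3K36me3"]])
  names(k36_tracks) <- vapply(k36_sets, `[[`, "", "sample_id")
  cnt <- count_fragments(k36_tracks, consensus)
  db <- nb_difftest(cnt, vapply(k36_sets, `[[`, "", "condition"))

  # differential splicing
  psi_mat <- psi(ev, expr$tpm)
  ds <- diff_psi_empirical(ev, psi_mat, expr$tpm, expr$condition)
  sig <- ds[ds$significant, , drop = FALSE]
  census <- event_type_summary(sig)
  ev_peak <- intersect_events_peaks(ev, lost_peaks)

  # motif scanning of flank sequences of significant events
  motifs <- NULL
  if (nrow(sig) > 0) {
    sig_genes <- unique(sig$gene_id)
    in_lost <- sig$gene_id %in% lost_genes
    rate <- ifelse(in_lost, min(1, config$motif_plant_rate + 0.2),
                   config$motif_plant_rate)
    fl <- simulate_flank_sequences(config, sig$event_id, plant_prob = rate)
    thr <- lapply(fl$pwms, score_threshold)
    matches <- do.call(rbind, Map(function(p, t)
      scan_pwm(fl$sequences, p, t$threshold), fl$pwms, thr))
    bound_genes <- truth$genes$gene_id[truth$genes$chd8_bound]
    groups <- list(all_as = sig$event_id,
                   as_bound = sig$event_id[sig$gene_id %in% bound_genes],
                   as_k36_lost = sig$event_id[in_lost])
    fractions <- lapply(groups, function(ids)
      if (length(ids)) family_match_fraction(matches, ids, fl$family_map)
      else NULL)
    motifs <- list(matches = matches, fractions = fractions,
                   thresholds = thr, planted = fl$planted)
  }

  # AP-MS interactome
  pep <- simulate_peptides(config, truth)
  norm <- normalize_intensities(pep$table)
  tab_a <- protein_fc_test(norm, "ab17")
  tab_b <- protein_fc_test(norm, "ab18")
  stringent <- stringent_interactors(tab_a, tab_b)

  # integration
  universe <- expressed_universe(expr$tpm, ann, expr$condition)
  as_genes <- unique(sig$gene_id)
  fo <- fisher_overlap(intersect(lost_genes, universe),
                       intersect(as_genes, universe), universe)
  gmt <- with_seed(derive_seed(config$seed, "gmt"), {
    terms <- lapply(1:8, function(i) sample(universe, min(50, length(universe))))
    names(terms) <- sprintf("random_term_%d", 1:8)
    hit <- unique(c(sample(as_genes, round(0.6 * length(as_genes))),
                    sample(universe, 20)))
    c(terms, list(splicing_regulation = hit))
  })
  enr <- ora(as_genes, gmt, universe)
  contrast_feat <- if (length(as_genes) && length(setdiff(universe, as_genes)))
    gene_feature_contrast(as_genes, setdiff(universe, as_genes), gt)
  else NULL

  # planted-event recovery bookkeeping
  truth_ids <- ev$events$event_id[ev$events$gene_id %in%
                                    truth$events$gene_id]
  tmatch <- match(ds$gene_id, truth$events$gene_id)
  planted <- !is.na(tmatch)
  correct_sign <- planted & ds$significant &
    sign(ds$dpsi) == sign(truth$events$delta_psi[tmatch])
  recovery <- sum(correct_sign) / nrow(truth$events)

  elong <- which(model$state_labels == "transcriptional elongation")
  k36_rows <- contrast[contrast$mark == "H3K36me3", ]
  top_state <- k36_rows$state[which.max(k36_rows$diff)]

  summary <- list(
    n_genes = nrow(gt),
    n_events_extracted = nrow(ev$events),
    n_events_significant = nrow(sig),
    planted_event_recovery = recovery,
    k36_body_peak_ctrl = n_body_ctrl,
    k36_body_peak_kd = n_body_kd,
    k36_body_peak_loss_pct = pct_loss,
    n_k36_lost_genes = length(lost_genes),
    top_k36_diff_state = top_state,
    top_k36_diff_is_elongation = top_state %in% elong,
    top_k36_diff_p = k36_rows$p_value[k36_rows$state == top_state],
    overlap_odds_ratio = fo$odds_ratio,
    overlap_p = fo$p,
    n_stringent_interactors = length(stringent),
    interactor_recall =
      length(intersect(stringent, pep$true_interactors)) /
        length(pep$true_interactors),
    diffbind_depleted = sum(db$direction == "depleted_in_KD", na.rm = TRUE),
    diffbind_enriched = sum(db$direction == "enriched_in_KD", na.rm = TRUE))

  report <- structure(list(
    config = config, truth = truth, model = model,
    state_labels = model$state_labels, contrast = contrast,
    k36 = list(lost_peaks = lost_peaks, lost_genes = lost_genes,
               pct_loss = pct_loss),
    diffbind = db, splicing = list(results = ds, significant = sig,
                                   census = census, ev_peak = ev_peak),
    motifs = motifs,
    ms = list(ab17 = tab_a, ab18 = tab_b, stringent = stringent,
              true_interactors = pep$true_interactors),
    integration = list(universe = universe, fisher = fo, ora = enr,
                       features = contrast_feat),
    summary = summary), class = "chromsplice_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    data.table::fwrite(contrast, file.path(out_dir, "state_contrast.tsv"),
                       sep = "\t")
    data.table::fwrite(ds, file.path(out_dir, "diff_splicing.tsv"),
                       sep = "\t")
    data.table::fwrite(db, file.path(out_dir, "diff_binding.tsv"),
                       sep = "\t")
    data.table::fwrite(tab_a, file.path(out_dir, "interactors_ab17.tsv"),
                       sep = "\t")
    data.table::fwrite(tab_b, file.path(out_dir, "interactors_ab18.tsv"),
                       sep = "\t")
  }
  report
}
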