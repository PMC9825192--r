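two_tx_gene <- function(ex1, ex2, strand = "+", gene = "g1", chrom = "chr1") {
  mk <- function(tx, ex) data.frame(
    gene_id = gene, transcript_id = paste(gene, tx, sep = "."),
    chrom = chrom, strand = strand, start = ex[, 1], end = ex[, 2],
    stringsAsFactors = FALSE)
  gene_annotation(rbind(mk("T1", ex1), mk("T2", ex2)))
}

test_that("SE: a skipped cassette with shared flanks, inclusion = carrier", {
  e3 <- cbind(c(0, 500, 1000), c(100, 600, 1100))
  ann <- two_tx_gene(e3, e3[c(1, 3), ])
  ev <- extract_events(ann)$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "SE")
  expect_equal(ev$inclusion, "g1.T1")
  expect_equal(ev$exclusion, "g1.T2")
})

test_that("AF: distinct first exons sharing the downstream acceptor", {
  t1 <- cbind(c(1000, 2000, 3000), c(1200, 2200, 3200))
  t2 <- cbind(c(0, 2000, 3000), c(200, 2200, 3200))
  ev <- extract_events(two_tx_gene(t1, t2))$events
  expect_equal(ev$type, "AF")
  # inclusion = more distal (5'-most) first exon
  expect_equal(ev$inclusion, "g1.T2")
})

test_that("RI: retained intron, inclusion = retention isoform", {
  t1 <- cbind(c(0, 500), c(100, 600))
  t2 <- cbind(0, 600)
  ev <- extract_events(two_tx_gene(t1, t2))$events
  expect_equal(ev$type, "RI")
  expect_equal(ev$inclusion, "g1.T2")
})

test_that("A5/A3 and AF/AL swap when a gene is mirrored to the minus
           strand", {
  t1 <- cbind(c(0, 1000, 2000), c(200, 1200, 2200))
  t2a5 <- t1; t2a5[1, 2] <- 300             # donor of exon 1 extended
  ev_p <- extract_events(two_tx_gene(t1, t2a5, "+"))$events
  expect_equal(ev_p$type, "A5")
  ev_m <- extract_events(two_tx_gene(t1, t2a5, "-"))$events
  expect_equal(ev_m$type, "A3")              # same genomic change, - strand

  t2af <- rbind(c(400, 600), t1[2:3, ])      # alternative leftmost exon
  ev_af <- extract_events(two_tx_gene(t1, t2af, "+"))$events
  expect_equal(ev_af$type, "AF")
  ev_al <- extract_events(two_tx_gene(t1, t2af, "-"))$events
  expect_equal(ev_al$type, "AL")
})

test_that("MX: mutually exclusive cassettes sharing both flanks", {
  t1 <- cbind(c(0, 1000, 3000), c(200, 1200, 3200))
  t2 <- cbind(c(0, 2000, 3000), c(200, 2200, 3200))
  ev <- extract_events(two_tx_gene(t1, t2))$events
  expect_equal(ev$type, "MX")
  expect_equal(ev$inclusion, "g1.T1")        # 5'-proximal cassette on +
})

test_that("the generator's planted event census equals the extractor's", {
  cfg <- sim_config(seed = 21, n_genes = 70, chrom_length = 2e6,
                    n_chd8_bound = 20, n_as_events_shifted = 20)
  sim <- simulate_annotation(cfg)
  ev <- extract_events(sim$annotation)
  got <- table(ev$events$type)
  planted <- table(sim$gene_types$event_type)
  expect_equal(as.vector(got[names(planted)]), as.vector(planted))
  expect_equal(nrow(ev$events), nrow(sim$gene_types))
  # one event per gene, inclusion/exclusion disjoint and non-empty
  expect_true(all(nzchar(ev$events$inclusion)))
  expect_true(all(nzchar(ev$events$exclusion)))
})

test_that("PSI is the inclusion fraction, scale-invariant and NA when
           unexpressed", {
  e3 <- cbind(c(0, 500, 1000), c(100, 600, 1100))
  ann <- two_tx_gene(e3, e3[c(1, 3), ])
  ev <- extract_events(ann)
  tpm <- rbind(`g1.T1` = c(8, 0), `g1.T2` = c(2, 0))
  colnames(tpm) <- c("s1", "s2")
  p <- psi(ev, tpm)
  expect_equal(unname(p[1, "s1"]), 0.8)
  expect_true(is.na(p[1, "s2"]))
  expect_equal(psi(ev, tpm * 7)[1, "s1"], p[1, "s1"])
  bad <- tpm[1, , drop = FALSE]
  expect_error(psi(ev, bad), "absent")
})

test_that("empirical differential test recovers planted shifts with the
           paper's thresholds and controls the sign convention", {
  cfg <- sim_config(seed = 22, n_genes = 80, chrom_length = 2.5e6,
                    n_chd8_bound = 20, n_as_events_shifted = 25,
                    planted_delta_psi = 0.35)
  sim <- simulate_annotation(cfg)
  truth <- simulate_truth(cfg, sim)
  ev <- extract_events(sim$annotation)
  expr <- simulate_expression(cfg, sim, truth, ev)
  pm <- psi(ev, expr$tpm)
  ds <- diff_psi_empirical(ev, pm, expr$tpm, expr$condition)
  m <- match(ds$gene_id, truth$events$gene_id)
  planted <- !is.na(m)
  hit <- planted & ds$significant &
    sign(ds$dpsi) == sign(truth$events$delta_psi[m])
  expect_gte(sum(hit) / nrow(truth$events), 0.8)
  # dPSI = PSI_ctrl - PSI_KD: a knockdown-reduced event has positive dPSI
  pos <- which(planted & truth$events$delta_psi[m] > 0)
  expect_true(all(ds$dpsi[pos] > 0))
  # |dPSI| <= 0.2 never significant regardless of p
  expect_true(all(!ds$significant[abs(ds$dpsi) <= 0.2]))
  # antisymmetry under condition swap
  ds2 <- diff_psi_empirical(ev, pm, expr$tpm,
                            ifelse(expr$condition == "control", "kd",
                                   "control"))
  expect_equal(ds2$dpsi, -ds$dpsi)
})

test_that("the empirical null holds its size when nothing is planted", {
  cfg <- sim_config(seed = 23, n_genes = 120, chrom_length = 3.5e6,
                    n_chd8_bound = 20, n_as_events_shifted = 0)
  sim <- simulate_annotation(cfg)
  truth <- simulate_truth(cfg, sim)
  ev <- extract_events(sim$annotation)
  expr <- simulate_expression(cfg, sim, truth, ev)
  pm <- psi(ev, expr$tpm)
  ds <- diff_psi_empirical(ev, pm, expr$tpm, expr$condition)
  frac <- mean(ds$p < 0.05, na.rm = TRUE)
  expect_lt(frac, 0.12)                    # ~5% with binomial slack
  expect_true(all(ds$p > 0 & ds$p <= 1, na.rm = TRUE))
  expect_equal(sum(ds$significant), 0)
})

test_that("event census: printed-count arithmetic and percentage
           normalization", {
  set.seed(26)
  res <- data.frame(type = sample(c("AF", "SE", "RI"), 500, TRUE),
                    dpsi = rnorm(500, 0, 0.3))
  cs <- event_type_summary(res)
  expect_equal(sum(cs$by_type$percent), 100, tolerance = 1e-9)
  expect_equal(sum(cs$by_sign$percent), 100, tolerance = 1e-9)
  one <- event_type_summary(data.frame(type = rep("RI", 5), dpsi = 1:5 / 10))
  expect_equal(one$by_type$percent, 100)
  expect_equal(one$by_sign$count, c(5L, 0L))
})

test_that("event-peak intersection flags any defining-exon overlap", {
  e3 <- cbind(c(0, 500, 1000), c(100, 600, 1100))
  ann <- two_tx_gene(e3, e3[c(1, 3), ])
  ev <- extract_events(ann)
  inside <- genomic_intervals("chr1", 520, 580)     # over the cassette
  expect_true(intersect_events_peaks(ev, inside)$overlaps)
  away <- genomic_intervals("chr1", 5000, 6000)
  expect_false(intersect_events_peaks(ev, away)$overlaps)
  set.seed(24)
  cfg <- sim_config(seed = 25, n_genes = 30, chrom_length = 1e6,
                    n_chd8_bound = 5, n_as_events_shifted = 5)
  sim <- simulate_annotation(cfg)
  ev2 <- extract_events(sim$annotation)
  pks <- random_intervals(50, max_pos = 9e5)
  got <- intersect_events_peaks(ev2, pks)
  want <- vapply(got$event_id, function(id) {
    ex <- ev2$exons[ev2$exons$event_id == id, ]
    any(bf_overlaps_any(ex, pks))
  }, TRUE)
  expect_equal(got$overlaps, unname(want))
})

test_that("band-intensity PSI is in/(in+out) with guarded edge cases", {
  expect_equal(psi_from_band_intensities(300, 100), 0.75)
  expect_equal(psi_from_band_intensities(5, 0), 1.0)
  expect_equal(psi_from_band_intensities(0, 5), 0.0)
  expect_error(psi_from_band_intensities(0, 0), "undefined")
  expect_error(psi_from_band_intensities(-1, 5), ">= 0")
})
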