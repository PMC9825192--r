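pep_table <- function(int, protein = "P1", peptide = "p1", ab = "ab17",
                      channel = "IP", rep_id = 1) {
  data.frame(protein_id = protein, peptide_id = peptide, antibody = ab,
             channel = channel, replicate = rep_id, intensity = int,
             stringsAsFactors = FALSE)
}

test_that("sample_mean normalization centres each sample at 1 and absorbs
           global scaling", {
  tab <- rbind(pep_table(10, "P1", "p1"), pep_table(20, "P2", "p2"),
               pep_table(30, "P3", "p3"))
  n <- normalize_intensities(tab)
  expect_equal(n$norm, c(0.5, 1.0, 1.5))
  n10 <- normalize_intensities(transform(tab, intensity = intensity * 10))
  expect_equal(n10$norm, n$norm)
  # random table: per-sample mean is 1
  set.seed(41)
  big <- do.call(rbind, lapply(1:3, function(r)
    rbind(pep_table(runif(5, 1, 100), sprintf("P%d", 1:5),
                    sprintf("p%d", 1:5), channel = "IP", rep_id = r),
          pep_table(runif(5, 1, 100), sprintf("P%d", 1:5),
                    sprintf("p%d", 1:5), channel = "IgG", rep_id = r))))
  nb <- normalize_intensities(big)
  key <- paste(nb$antibody, nb$channel, nb$replicate)
  expect_true(all(abs(tapply(nb$norm, key, mean) - 1) < 1e-9))
  # protein_mean mode centres within protein
  np <- normalize_intensities(big, mode = "protein_mean")
  kp <- paste(np$antibody, np$channel, np$replicate, np$protein_id)
  expect_true(all(abs(tapply(np$norm, kp, mean) - 1) < 1e-9))
})

test_that("missing intensities are imputed as half the sample minimum", {
  tab <- rbind(pep_table(c(10, NA), c("P1", "P2"), c("p1", "p2")))
  n <- normalize_intensities(tab)
  expect_equal(n$intensity[2], 5)
  expect_true(n$imputed[2])
  allna <- pep_table(NA_real_)
  expect_error(normalize_intensities(allna), "no observed")
})

test_that("peptide FC is mean log2 IP minus mean log2 IgG", {
  # balanced design: the target peptide is 2x in IP, a mirror peptide 2x in
  # IgG, so per-sample means agree and normalization is neutral
  tab <- do.call(rbind, lapply(1:3, function(r)
    rbind(pep_table(c(200, 100), c("P1", "P2"), c("p1", "p2"),
                    channel = "IP", rep_id = r),
          pep_table(c(100, 200), c("P1", "P2"), c("p1", "p2"),
                    channel = "IgG", rep_id = r))))
  n <- normalize_intensities(tab)
  fc <- peptide_fc(n, "ab17")
  expect_equal(fc$fc[fc$protein_id == "P1"], 1.0)  # IP = 2 x IgG
  expect_equal(fc$fc[fc$protein_id == "P2"], -1.0)
  tab0 <- transform(tab, intensity = 100)
  expect_equal(peptide_fc(normalize_intensities(tab0), "ab17")$fc, c(0, 0))
})

test_that("channel swap negates FC and preserves the Welch p", {
  set.seed(42)
  tab <- do.call(rbind, lapply(1:3, function(r)
    rbind(pep_table(2^rnorm(4, 11, 0.3), "P1", sprintf("p%d", 1:4),
                    channel = "IP", rep_id = r),
          pep_table(2^rnorm(4, 10, 0.3), "P1", sprintf("p%d", 1:4),
                    channel = "IgG", rep_id = r))))
  n <- normalize_intensities(tab)
  t1 <- protein_fc_test(n, "ab17")
  swapped <- transform(n, channel = ifelse(channel == "IP", "IgG", "IP"))
  t2 <- protein_fc_test(swapped, "ab17")
  expect_equal(t2$fc, -t1$fc, tolerance = 1e-12)
  expect_equal(t2$p, t1$p, tolerance = 1e-12)
})

test_that("planted interactors are all recovered and the null flags ~5%
           before the FC filter", {
  cfg <- sim_config(seed = 43, n_proteins = 250, n_true_interactors = 15,
                    interactor_log2_shift = 2, peptide_noise_sd = 0.3,
                    peptides_range = c(5, 5), ms_replicates = 3,
                    igg_missing_frac = 0)
  pep <- simulate_peptides(cfg)
  n <- normalize_intensities(pep$table)
  tab <- protein_fc_test(n, "ab17")
  hit <- tab$significant[tab$protein_id %in% pep$true_interactors]
  expect_true(all(hit))
  # null: no shift planted
  cfg0 <- sim_config(seed = 44, n_proteins = 400, n_true_interactors = 0,
                     interactor_log2_shift = 0, peptide_noise_sd = 0.3,
                     peptides_range = c(5, 5), igg_missing_frac = 0)
  pep0 <- simulate_peptides(cfg0)
  tab0 <- protein_fc_test(normalize_intensities(pep0$table), "ab17")
  frac <- mean(tab0$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02); expect_lt(frac, 0.09)
})

test_that("single-replicate rule: one-sample t of peptide differences", {
  tab <- rbind(pep_table(c(100, 200, 400), "P1", sprintf("p%d", 1:3),
                         channel = "IP"),
               pep_table(c(100, 200, 400), "P1", sprintf("p%d", 1:3),
                         channel = "IgG"))
  n <- normalize_intensities(tab)
  out <- single_replicate_enrichment(n, "ab17", 1)
  expect_equal(out$fc, 0)
  expect_equal(out$p, 1)
  # constant positive difference with tiny jitter -> small p, FC ~ d; a
  # large unshifted background anchors the per-sample normalization
  set.seed(45)
  bgp <- sprintf("bg%03d", 1:200)
  tab2 <- rbind(pep_table(2^(10 + 1.5 + rnorm(4, 0, 0.01)), "P1",
                          sprintf("p%d", 1:4), channel = "IP"),
                pep_table(2^(10 + rnorm(4, 0, 0.01)), "P1",
                          sprintf("p%d", 1:4), channel = "IgG"),
                pep_table(2^(10 + rnorm(200, 0, 0.01)), bgp, bgp,
                          channel = "IP"),
                pep_table(2^(10 + rnorm(200, 0, 0.01)), bgp, bgp,
                          channel = "IgG"))
  out2 <- single_replicate_enrichment(normalize_intensities(tab2),
                                      "ab17", 1)
  fc1 <- out2$fc[out2$protein_id == "P1"]
  expect_equal(fc1, 1.5, tolerance = 0.1)
  expect_lt(out2$p[out2$protein_id == "P1"], 0.01)
  # single-peptide protein: p missing
  tab3 <- rbind(pep_table(300, channel = "IP"),
                pep_table(100, channel = "IgG"))
  out3 <- single_replicate_enrichment(normalize_intensities(tab3),
                                      "ab17", 1)
  expect_true(is.na(out3$p))
})

test_that("stringent interactors intersect both antibodies and drop the
           bait", {
  ta <- data.frame(protein_id = c("A", "B", "C", "BAIT"),
                   n_peptides = 2, fc = 1, p = 0.01,
                   significant = c(TRUE, TRUE, FALSE, TRUE))
  tb <- data.frame(protein_id = c("A", "B", "C", "BAIT"),
                   n_peptides = 2, fc = 1, p = 0.01,
                   significant = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(stringent_interactors(ta, tb), c("A", "BAIT"))
  expect_equal(stringent_interactors(ta, tb, bait = "BAIT"), "A")
})
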