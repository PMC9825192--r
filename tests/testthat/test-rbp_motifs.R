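sharp_pwm <- function(cons, p = 0.97, bg = rep(0.25, 4), id = "m1") {
  bases <- c("A", "C", "G", "T")
  W <- nchar(cons)
  m <- matrix((1 - p) / 3, 4, W, dimnames = list(bases, NULL))
  m[cbind(match(strsplit(cons, "")[[1]], bases), seq_len(W))] <- p
  pwm(m, id, background = bg)
}

test_that("similarity threshold: near-consensus PWM admits only the
           consensus at 95%, and rel = 1 gives S_max exactly", {
  p <- sharp_pwm("ACGTAC", p = 0.99)
  th <- score_threshold(p, rel_similarity = 0.95, fpr = 1e-12)
  # with fpr essentially off, the similarity cutoff governs
  expect_equal(th$threshold, max(th$t_sim, th$t_fpr))
  hits <- scan_pwm(c(s1 = "ACGTAC", s2 = "ACGTAA", s3 = "TTTTTT"),
                   p, th$t_sim)
  expect_equal(hits$sequence_id, "s1")     # one mismatch falls below 95%
  th1 <- score_threshold(p, rel_similarity = 1, fpr = 0.5)
  expect_equal(th1$t_sim, th1$s_max)
})

test_that("the DP tail matches a Monte-Carlo scan and the empirical FPR is
           controlled", {
  set.seed(31)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  p <- sharp_pwm("ACACACA", p = 0.94, bg = bg)
  th <- score_threshold(p, rel_similarity = 0, fpr = 0.001)
  n <- 1e5
  seqv <- paste(sample(c("A", "C", "G", "T"), n + 6, TRUE, prob = bg),
                collapse = "")
  hits <- scan_pwm(c(bgseq = seqv), p, th$t_fpr)
  rate <- nrow(hits) / n
  margin <- 3 * sqrt(0.001 * 0.999 / n)
  expect_lte(rate, 0.001 + margin)
  # the DP tail is tight: halving the threshold lets many more through
  hits2 <- scan_pwm(c(bgseq = seqv), p, th$t_fpr - 3)
  expect_gt(nrow(hits2), nrow(hits))
})

test_that("thresholds are monotone in rel_similarity and fpr", {
  p <- sharp_pwm("GATTACA")
  t_lo <- score_threshold(p, rel_similarity = 0.8, fpr = 0.01)$threshold
  t_hi <- score_threshold(p, rel_similarity = 0.95, fpr = 0.01)$threshold
  expect_gte(t_hi, t_lo)
  f_lo <- score_threshold(p, rel_similarity = 0, fpr = 0.01)$t_fpr
  f_hi <- score_threshold(p, rel_similarity = 0, fpr = 1e-4)$t_fpr
  expect_gte(f_hi, f_lo)
  expect_error(score_threshold(p, fpr = 0), "fpr")
})

test_that("reverse-complement scanning mirrors offsets", {
  p <- sharp_pwm("ACGGT", p = 0.98)
  s <- "TTTTACGGTTTTT"
  hit <- scan_pwm(c(x = s), p, score_threshold(p, 0.9, 0.9)$t_sim)
  expect_equal(hit$offset, 5L)
  rc_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rc_mat <- p$ppm[4:1, ncol(p$ppm):1]
  rownames(rc_mat) <- c("A", "C", "G", "T")
  p_rc <- pwm(rc_mat, "m1rc")
  hit_rc <- scan_pwm(c(x = rc_seq), p_rc,
                     score_threshold(p_rc, 0.9, 0.9)$t_sim)
  expect_equal(hit_rc$offset, nchar(s) - (5L + 5L) + 2L)
})

test_that("flank extraction is strand-aware and truncation is flagged", {
  ev <- list(events = NULL,
             exons = data.frame(event_id = c("e1", "e2"), chrom = "chr1",
                                start = c(1000L, 40L), end = c(1100L, 140L),
                                strand = c("+", "+"), role = "alternative"))
  class(ev) <- "splicing_events"
  genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))  # 2000 nt
  fl <- extract_flanks(ev, genome, flank = 100)
  expect_equal(unname(fl$sequences["e1|1|upstream"]),
               substr(genome[["chr1"]], 901, 1000))
  expect_equal(unname(fl$sequences["e1|1|downstream"]),
               substr(genome[["chr1"]], 1101, 1200))
  expect_true(fl$meta$truncated[fl$meta$name == "e2|2|upstream"])

  # minus strand: roles swap and sequences reverse-complement
  ev$exons$strand <- "-"
  flm <- extract_flanks(ev, genome, flank = 100)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(flm$sequences["e1|1|upstream"]),
               rc(substr(genome[["chr1"]], 1101, 1200)))
  expect_equal(unname(flm$sequences["e1|1|downstream"]),
               rc(substr(genome[["chr1"]], 901, 1000)))
})

test_that("planted motifs are recovered at their offsets and family
           fractions track the planting rate", {
  cfg <- sim_config(seed = 33, motif_plant_rate = 0.4)
  ids <- sprintf("s%03d", 1:300)
  fl <- simulate_flank_sequences(cfg, ids)
  planted <- fl$planted[!is.na(fl$planted$offset), ]
  th <- score_threshold(fl$pwms[[1]], 0.95, 0.001)
  hits <- scan_pwm(fl$sequences, fl$pwms[[1]], th$threshold)
  found <- merge(planted, hits,
                 by.x = c("sequence_id", "offset"),
                 by.y = c("sequence_id", "offset"))
  expect_equal(nrow(found), nrow(planted))   # every planted copy recovered
  fr <- family_match_fraction(hits, ids, fl$family_map)
  ca <- fr$fraction[fr$family == "CA_rich"]
  expect_equal(ca, 0.4, tolerance = 0.12)
  expect_true(ca >= nrow(planted) / 300)     # at least the planted ones
  # a family with no matching motifs scores 0
  none <- family_match_fraction(hits[0, ], ids, fl$family_map)
  expect_true(all(none$fraction == 0))
  expect_error(family_match_fraction(hits, character(0), fl$family_map),
               "empty")
  # motif planted in every sequence -> fraction 1
  fl2 <- simulate_flank_sequences(cfg, ids[1:50], plant_prob = 1)
  h2 <- scan_pwm(fl2$sequences, fl2$pwms[[1]],
                 score_threshold(fl2$pwms[[1]])$threshold)
  fr2 <- family_match_fraction(h2, ids[1:50], fl2$family_map)
  expect_equal(fr2$fraction[fr2$family == "CA_rich"], 1.0)
})

test_that("PWM TSV round trip and validation", {
  p1 <- sharp_pwm("ACGTA", id = "mA")
  p2 <- sharp_pwm("GGGCC", id = "mB")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwms(list(p1, p2), f)
  back <- read_pwms(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$ppm, p1$ppm, tolerance = 1e-9)
  expect_error(pwm(matrix(0.5, 4, 4), "bad"), "sum to 1")
  expect_error(pwm(matrix(0.25, 3, 4), "bad"), "4 rows")
})
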