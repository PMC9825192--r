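test_that("binarize calls bins by the exact Poisson upper tail", {
  # independent oracle: smallest c with sum_{x>=c} pmf(x; lambda) <= 1e-4
  lam <- 1
  pmf <- dpois(0:100, lam)
  tails <- rev(cumsum(rev(pmf)))
  c_min <- min(which(tails <= 1e-4)) - 1   # 0-based count value
  v <- rep(0, 4000)
  v[1] <- c_min; v[2] <- c_min - 1
  # lambda is the genome-wide mean; engineer it to ~1 per 200 bp bin
  v[3:4000] <- rep(lam, 3998)
  tr <- signal_track(list(chr1 = v), bin_size = 200)
  lam_real <- mean(v)
  tails_real <- rev(cumsum(rev(dpois(0:100, lam_real))))
  c_real <- min(which(tails_real <= 1e-4)) - 1
  b <- binarize(tr, bin_size = 200)$chr1
  expect_equal(b[1], as.integer(c_min >= c_real))
  expect_equal(b[2], as.integer((c_min - 1) >= c_real))
  expect_true(c_min >= c_real)  # the planted bin is called
  # all-zero track -> all zeros, no error
  z <- signal_track(list(chr1 = rep(0, 100)), bin_size = 200)
  expect_equal(binarize(z)$chr1, integer(100))
})

test_that("binarize aggregates finer bins and keeps quantile patterns under
           joint scaling", {
  set.seed(2)
  v <- rpois(2000, 3)
  tr10 <- signal_track(list(chr1 = as.numeric(v)), bin_size = 10)
  b1 <- binarize(tr10, bin_size = 200)
  agg <- colSums(matrix(v, nrow = 20))
  expect_equal(length(b1$chr1), 100L)
  # doubling all counts doubles lambda; the called set can only be similar
  tr2 <- signal_track(list(chr1 = as.numeric(2 * v)), bin_size = 10)
  b2 <- binarize(tr2, bin_size = 200)
  expect_gte(mean(b1$chr1 == b2$chr1), 0.95)
})

test_that("K = 1 reduces to the closed-form Bernoulli MLE", {
  set.seed(3)
  X <- matrix(rbinom(600, 1, rep(c(0.2, 0.7, 0.5), each = 200)), 200, 3)
  colnames(X) <- c("a", "b", "c")
  bm <- list(mat = X, bins = data.frame(chrom = "chr1",
                                        start = 200 * (0:199)),
             bin_size = 200, seq_starts = 1L)
  class(bm) <- "binarized_matrix"
  m <- fit_hmm(bm, K = 1)
  expect_equal(as.numeric(m$emission), unname(colMeans(X)),
               tolerance = 1e-12)
})

test_that("Baum-Welch log-likelihood is monotone and the fit is
           deterministic under a fixed seed", {
  set.seed(4)
  E <- rbind(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.5))
  A <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  sm <- sample_hmm(2000, E, A, c(0.5, 0.5))
  bm <- structure(list(mat = sm$X,
                       bins = data.frame(chrom = "chr1",
                                         start = 200 * (0:1999)),
                       bin_size = 200, seq_starts = 1L),
                  class = "binarized_matrix")
  m1 <- fit_hmm(bm, K = 2, seed = 10)
  expect_true(all(diff(m1$loglik_trace) >= -1e-6 * abs(m1$loglik_trace[-1])))
  m2 <- fit_hmm(bm, K = 2, seed = 10)
  expect_identical(m1$emission, m2$emission)
  expect_identical(m1$transition, m2$transition)
  # model invariants
  expect_equal(rowSums(m1$transition), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(m1$initial), 1, tolerance = 1e-9)
  expect_true(all(m1$emission >= 0 & m1$emission <= 1))
})

test_that("a 3-state model is recovered from its own simulation", {
  set.seed(5)
  E <- rbind(c(0.95, 0.05, 0.05, 0.05),
             c(0.05, 0.9, 0.8, 0.05),
             c(0.05, 0.05, 0.1, 0.85))
  A <- matrix(0.05, 3, 3); diag(A) <- 0.9
  sm <- sample_hmm(12000, E, A, rep(1 / 3, 3))
  bm <- structure(list(mat = sm$X,
                       bins = data.frame(chrom = "chr1",
                                         start = 200 * (0:11999)),
                       bin_size = 200, seq_starts = 1L),
                  class = "binarized_matrix")
  m <- fit_hmm(bm, K = 3, seed = 1)
  perm <- match_states(m$emission, E)
  expect_lt(max(abs(m$emission[perm, ] - E)), 0.05)
})

test_that("Viterbi equals exhaustive enumeration on tiny instances", {
  set.seed(6)
  for (rep_i in 1:8) {
    Tn <- sample(3:6, 1)
    E <- matrix(runif(2 * 2, 0.1, 0.9), 2, 2)
    A <- matrix(runif(4, 0.2, 0.8), 2, 2); A <- A / rowSums(A)
    pi0 <- c(0.6, 0.4)
    X <- matrix(rbinom(Tn * 2, 1, 0.5), Tn, 2)
    colnames(X) <- colnames(E) <- c("m1", "m2")
    bm <- structure(list(mat = X,
                         bins = data.frame(chrom = "c1",
                                           start = 200 * (seq_len(Tn) - 1)),
                         bin_size = 200, seq_starts = 1L),
                    class = "binarized_matrix")
    model <- structure(list(emission = E, transition = A, initial = pi0,
                            marks = c("m1", "m2"), K = 2L,
                            state_labels = NULL),
                       class = "chromatin_state_model")
    got <- segment_genome(model, bm, method = "viterbi")$states
    expect_equal(got, bf_viterbi(X, E, A, pi0))
  }
})

test_that("posterior segmentation recovers near-deterministic emissions and
           tiles the genome", {
  set.seed(7)
  E <- rbind(c(0.999, 0.001), c(0.001, 0.999))
  A <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  sm <- sample_hmm(500, E, A, c(0.5, 0.5))
  bm <- structure(list(mat = sm$X,
                       bins = data.frame(chrom = rep(c("c1", "c2"),
                                                     each = 250),
                                         start = 200 * c(0:249, 0:249)),
                       bin_size = 200, seq_starts = c(1L, 251L)),
                  class = "binarized_matrix")
  model <- structure(list(emission = E, transition = A, initial = c(.5, .5),
                          marks = colnames(sm$X), K = 2L,
                          state_labels = NULL),
                     class = "chromatin_state_model")
  seg <- segment_genome(model, bm)
  expect_equal(seg$states, sm$z)
  expect_equal(rowSums(seg$posterior), rep(1, 500), tolerance = 1e-9)
  # runs tile each chromosome without gaps or overlaps
  for (ch in c("c1", "c2")) {
    r <- seg$runs[seg$runs$chrom == ch, ]
    expect_equal(r$start[1], 0L)
    expect_equal(r$start[-1], r$end[-nrow(r)])
    expect_equal(r$end[nrow(r)], 250L * 200L)
  }
})

test_that("state_mark_contrast: identical conditions give zero differences
           and p = 1; percentages sum to 100", {
  runs <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                     end = c(1000, 2000, 3000), state = c(1L, 2L, 1L))
  seg <- structure(list(runs = runs, state_labels = NULL),
                   class = "segmentation")
  pk <- genomic_intervals("chr1", c(100, 1500), c(200, 1600))
  ps <- list()
  for (cond in c("control", "kd")) for (r in 1:2)
    ps[[length(ps) + 1]] <- list(mark = "H3K36me3", condition = cond,
                                 sample_id = paste(cond, r), peaks = pk)
  ctr <- state_mark_contrast(seg, ps)
  expect_equal(ctr$diff, c(0, 0))
  expect_equal(ctr$p_value, c(1, 1))
  expect_equal(sum(ctr$pct_control), 100, tolerance = 1e-6)
  expect_equal(sum(ctr$pct_kd), 100, tolerance = 1e-6)
  expect_true(all(ctr$low_n))
})

test_that("state model YAML round trip", {
  E <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  m <- structure(list(emission = E,
                      transition = rbind(c(0.7, 0.3), c(0.4, 0.6)),
                      initial = c(0.5, 0.5), marks = c("a", "b"), K = 2L,
                      state_labels = c("x", "y")),
                 class = "chromatin_state_model")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_state_model(m, f)
  b <- read_state_model(f)
  expect_equal(unname(b$emission), unname(E))
  expect_equal(b$state_labels, c("x", "y"))
  expect_equal(unname(b$transition), unname(m$transition))
})
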