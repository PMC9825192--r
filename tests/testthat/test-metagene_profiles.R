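make_track <- function(v, bin = 10) signal_track(list(chr1 = v), bin)

test_that("SES factors are 1 for identical tracks and recover a known
           background ratio", {
  set.seed(1)
  v <- rpois(5000, 2)
  chip <- make_track(as.numeric(v))
  expect_equal(ses_factors(chip, chip)$sf_input, 1, tolerance = 1e-9)

  # chip = 3 x input everywhere: after scaling, log2 ratio ~ 0
  input <- make_track(as.numeric(v) + 0.0)
  chip3 <- make_track(as.numeric(3 * v))
  nf <- ses_factors(chip3, input)
  ratio <- log2((3 * v[v > 0] * nf$sf_chip) / (v[v > 0] * nf$sf_input))
  expect_equal(mean(ratio), 0, tolerance = 1e-9)

  # spiked chip: background equals input, 100 enriched bins
  set.seed(2)
  bg <- rpois(5000, 5)
  chip_v <- as.numeric(bg)
  chip_v[1:100] <- chip_v[1:100] + 60
  nf2 <- ses_factors(make_track(chip_v), make_track(as.numeric(bg)))
  expect_lt(abs(nf2$sf_input - 1), 0.05)   # true background ratio is 1
  expect_warning(ses_factors(make_track(chip_v),
                             make_track(rep(0, 5000))), "zero-signal")
})

test_that("filter_genes applies length, distance and opposite-strand rules", {
  gt <- data.frame(
    gene_id = c("short", "lonely", "pairA", "pairB", "host", "anti"),
    gene_type = "protein_coding", chrom = "chr1",
    strand = c("+", "+", "+", "+", "+", "-"),
    start = c(1000, 20000, 50000, 56000, 80000, 81000),
    end = c(2999, 25000, 53000, 59000, 90000, 84000),
    tss = c(1000, 20000, 50000, 56000, 80000, 83999),
    tes = c(2998, 24999, 52999, 58999, 89999, 81000),
    n_transcripts = 1, max_exons = 1, stringsAsFactors = FALSE)
  got <- filter_genes(gt)
  expect_false("short" %in% got)    # length 1999 < 2000
  expect_false("pairA" %in% got)    # 3 kb apart: both excluded
  expect_false("pairB" %in% got)
  expect_false("host" %in% got)     # opposite-strand overlap
  expect_false("anti" %in% got)
  expect_true("lonely" %in% got)

  # brute-force filter on random gene layouts
  set.seed(3)
  for (rep_i in 1:5) {
    s <- sort(sample.int(3e5, 20)) * 2L
    len <- sample(seq(1000, 8000, 500), 20, replace = TRUE)
    g2 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                     gene_type = "protein_coding", chrom = "chr1",
                     strand = sample(c("+", "-"), 20, TRUE),
                     start = s, end = s + len, tss = s, tes = s + len,
                     n_transcripts = 1, max_exons = 1)
    want <- vapply(1:20, function(i) {
      if (g2$end[i] - g2$start[i] < 2000) return(FALSE)
      for (j in setdiff(1:20, i)) {
        d <- max(g2$start[i], g2$start[j]) - min(g2$end[i], g2$end[j])
        if (d < 4000) return(FALSE)
      }
      TRUE
    }, TRUE)
    expect_equal(sort(filter_genes(g2)), sort(g2$gene_id[want]))
  }
})

test_that("metagene matrix is 900 bins, oriented 5' to 3', and identity on a
           5 kbp body", {
  n <- 2000                     # 20 kb of 10 bp bins
  chip <- make_track(rep(4, n))
  input <- make_track(rep(4, n))
  nf <- list(sf_chip = 1, sf_input = 1)
  gt <- data.frame(gene_id = "g1", gene_type = "protein_coding",
                   chrom = "chr1", strand = "+", start = 5000L, end = 10000L,
                   tss = 5000L, tes = 9999L, n_transcripts = 1, max_exons = 1)
  m <- metagene_matrix(chip, input, nf, gt, "g1")
  expect_equal(ncol(m), 900L)
  expect_equal(nrow(m), 0L)     # uniform chip = input: all-zero, dropped

  # spike at the 5' end of a minus-strand gene lands at the TSS column
  v <- rep(4, n); v[996:1000] <- 400       # bases 9950-10000
  chip2 <- make_track(v)
  gt$strand <- "-"; gt$tss <- 9999L; gt$tes <- 5000L
  m2 <- metagene_matrix(chip2, input, nf, gt, "g1")
  body <- m2[1, 201:700]
  expect_gt(max(body[1:10]), 2)           # spike at 5' body start
  expect_lt(max(body[490:500]), 0.1)      # not at the 3' end
  # body of exactly 5 kbp: resampling is identity (500 bins of 10 bp)
  expect_equal(length(body), 500L)
  idx <- which(v >= 400)
  raw <- rev(log2((v * 1 + 1) / (4 * 1 + 1)))[1001:1500]
  expect_equal(unname(body), raw)

  # reversing the strand reverses the row
  gt2 <- gt; gt2$strand <- "+"; gt2$tss <- 5000L; gt2$tes <- 9999L
  m3 <- metagene_matrix(chip2, input, nf, gt2, "g1")
  expect_equal(unname(m3[1, ]), rev(unname(m2[1, ])))
})

test_that("k-means profile clusters are relabeled by enrichment level and
           deterministic", {
  set.seed(8)
  truth <- rep(1:3, each = 40)
  mat <- matrix(rnorm(120 * 50, mean = c(3, 1, -1)[truth], sd = 0.2),
                120, 50)
  rownames(mat) <- sprintf("g%03d", 1:120)
  cl <- kmeans_profiles(mat, k = 3, seed = 99)
  # perfect recovery: adjusted-Rand equivalent via contingency purity
  tab <- table(cl$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 120)
  # cluster 1 = highest mean enrichment
  expect_equal(unname(cl$cluster[1]), 1L)
  expect_true(all(diff(cl$means) < 0))
  cl2 <- kmeans_profiles(mat, k = 3, seed = 99)
  expect_identical(cl$cluster, cl2$cluster)
  expect_equal(unname(kmeans_profiles(mat, k = 1, seed = 1)$cluster),
               rep(1L, 120))
  expect_error(kmeans_profiles(mat[1:2, ], k = 3), "k exceeds")
})

test_that("paired Cohen's d: zero for A = B, delta/sigma under a planted
           shift, Bonferroni arithmetic, antisymmetry", {
  set.seed(9)
  A <- matrix(rnorm(500 * 20), 500, 20, dimnames = list(sprintf("g%d", 1:500)))
  d0 <- paired_cohens_d(A, A)
  expect_true(all(d0$d == 0))
  expect_true(all(d0$ci_lower <= 0 & d0$ci_upper >= 0))

  delta <- 0.5; sigma <- 1
  B <- A - delta + matrix(rnorm(500 * 20, 0, sigma), 500, 20)
  dd <- paired_cohens_d(A, B)
  expect_equal(mean(dd$d), delta / sigma, tolerance = 0.1)
  expect_true(attr(dd, "affected"))
  expect_true(all(dd$ci_lower <= dd$d & dd$d <= dd$ci_upper))
  # per-bin alpha for a 900-bin profile at 99% simultaneous coverage
  M <- matrix(rnorm(2700), 3, 900, dimnames = list(c("a", "b", "c")))
  d900 <- paired_cohens_d(M, M * 0.5)
  expect_equal(attr(d900, "alpha_per_bin"), 0.01 / 900)

  # antisymmetry under swapping A and B
  dswap <- paired_cohens_d(B, A)
  expect_equal(dswap$d, -dd$d)
  # CI width shrinks roughly as 1/sqrt(n)
  dhalf <- paired_cohens_d(A[1:125, ], B[1:125, ])
  w_full <- mean(dd$ci_upper - dd$ci_lower)
  w_half <- mean(dhalf$ci_upper - dhalf$ci_lower)
  expect_equal(w_half / w_full, 2, tolerance = 0.2)
  expect_error(paired_cohens_d(A[1:2, ], B[1:2, ]), "at least 3")
})
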