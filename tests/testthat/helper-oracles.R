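# Independent brute-force oracles for the interval algebra and decoding
# operations. These deliberately use naive O(n^2) pairwise mechanics so they
# share no code path with the package implementations.

random_intervals <- function(n, max_pos = 10000, max_len = 300,
                             chroms = c("chr1", "chr2")) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w, strand = ".",
             stringsAsFactors = FALSE)
}

# union-find over an explicit pair list
.uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

bf_merge_close <- function(x, gap) {
  n <- nrow(x)
  if (n == 0) return(x[, c("chrom", "start", "end")])
  # all-pairs distance matrix (O(n^2) memory, deliberately naive)
  same <- outer(x$chrom, x$chrom, "==")
  dist <- outer(x$start, x$start, pmax) - outer(x$end, x$end, pmin)
  q <- same & dist < gap & upper.tri(dist)
  prs <- which(q, arr.ind = TRUE)
  comp <- .uf_components(n, prs)
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    i <- which(comp == cc)
    data.frame(chrom = x$chrom[i[1]], start = min(x$start[i]),
               end = max(x$end[i]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

bf_common_peaks <- function(a, b, frac) {
  na <- nrow(a); nb <- nrow(b)
  same <- outer(a$chrom, b$chrom, "==")
  ov <- outer(a$end, b$end, pmin) - outer(a$start, b$start, pmax)
  shortest <- outer(a$end - a$start, b$end - b$start, pmin)
  q <- same & ov > 0 & ov >= frac * shortest
  if (!any(q))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  pr <- which(q, arr.ind = TRUE)
  pr[, 2] <- pr[, 2] + na
  comp <- .uf_components(na + nb, pr)
  nodes <- sort(unique(c(pr)))
  ch <- c(a$chrom, b$chrom); st <- c(a$start, b$start); en <- c(a$end, b$end)
  out <- do.call(rbind, lapply(unique(comp[nodes]), function(cc) {
    i <- nodes[comp[nodes] == cc]
    data.frame(chrom = ch[i[1]], start = min(st[i]), end = max(en[i]),
               stringsAsFactors = FALSE)
  }))
  out <- unique(out[order(out$chrom, out$start, out$end), ])
  rownames(out) <- NULL
  out
}

bf_overlaps_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & x$start[i] < y$end)
  }, TRUE)
}

bf_count_in_segments <- function(peaks, segments) {
  if (nrow(peaks) == 0) return(0L)
  sum(bf_overlaps_any(peaks, segments))
}

bf_consensus <- function(peaksets, min_samples) {
  allp <- do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")]))
  merged <- bf_merge_close(allp, gap = 1)
  supp <- rep(0L, nrow(merged))
  for (p in peaksets)
    supp <- supp + as.integer(bf_overlaps_any(merged, p))
  out <- merged[supp >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

bf_annotate <- function(peaks, gt, tss_window) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    hits <- character(0)
    for (g in seq_len(nrow(gt))) {
      rs <- min(gt$start[g], gt$tss[g] - tss_window)
      re <- max(gt$end[g], gt$tss[g] + tss_window + 1)
      if (gt$chrom[g] == peaks$chrom[i] &&
          rs < peaks$end[i] && peaks$start[i] < re)
        hits <- c(hits, gt$gene_id[g])
    }
    out[[i]] <- if (length(hits)) sort(hits) else NA_character_
  }
  out
}

# exhaustive MAP path for a Bernoulli-emission HMM (tiny instances only)
bf_viterbi <- function(X, E, A, pi0) {
  Tn <- nrow(X); K <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  emit <- function(k, t) prod(E[k, ]^X[t, ] * (1 - E[k, ])^(1 - X[t, ]))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(pi0[p[1]]) + log(emit(p[1], 1))
    if (Tn > 1) for (t in 2:Tn)
      lp <- lp + log(A[p[t - 1], p[t]]) + log(emit(p[t], t))
    if (lp > best) { best <- lp; arg <- p }
  }
  as.integer(arg)
}

# sample a path + binary observations from a Bernoulli HMM
sample_hmm <- function(Tn, E, A, pi0) {
  K <- nrow(E); M <- ncol(E)
  z <- integer(Tn)
  z[1] <- sample(K, 1, prob = pi0)
  if (Tn > 1) for (t in 2:Tn) z[t] <- sample(K, 1, prob = A[z[t - 1], ])
  X <- matrix(rbinom(Tn * M, 1, E[z, ]), Tn, M)
  colnames(X) <- paste0("m", seq_len(M))
  list(z = z, X = X)
}

# match estimated states to true states by emission distance
match_states <- function(E_hat, E_true) {
  K <- nrow(E_true)
  perm <- NULL; best <- Inf
  for (p in asplit(.permutations(K), 1)) {
    d <- sum((E_hat[p, ] - E_true)^2)
    if (d < best) { best <- d; perm <- p }
  }
  perm
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# small annotation fixture used by several suites
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gA", "gB", "gB"),
    transcript_id = c("gA.T1", "gA.T1", "gA.T1", "gA.T2", "gA.T2",
                      "gB.T1", "gB.T1"),
    chrom = "chr1", strand = c(rep("+", 5), "-", "-"),
    start = c(1000, 2000, 3000, 1000, 3000, 20000, 22000),
    end = c(1200, 2200, 3200, 1200, 3200, 20500, 22500),
    stringsAsFactors = FALSE))
}
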