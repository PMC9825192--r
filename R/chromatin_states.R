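#' Binarize a signal track by Poisson upper tail
#'
#' ChromHMM-style preprocessing: counts are aggregated into `bin_size` bins
#' and a bin is called present (1) when its count is improbably high under a
#' genome-wide Poisson background, i.e. when `P(X >= c) <= p_threshold` with
#' rate lambda equal to the genome-wide mean count per bin.
#'
#' @param track `signal_track` whose bin size divides `bin_size`.
#' @param bin_size output bin width, default 200 bp.
#' @param p_threshold Poisson upper-tail probability cutoff, default 1e-4.
#' @return named list of per-chromosome 0/1 integer vectors.
#' @export
binarize <- function(track, bin_size = 200, p_threshold = 1e-4) {
  if (bin_size %% track$bin_size != 0)
    stop("track bin size must divide ", bin_size)
  f <- bin_size %/% track$bin_size
  agg <- lapply(track$values, function(v) {
    n <- ceiling(length(v) / f)
    length(v) <- n * f            # pad with NA then zero
    v[is.na(v)] <- 0
    colSums(matrix(v, nrow = f))
  })
  lambda <- mean(unlist(agg))
  if (lambda == 0) return(lapply(agg, function(v) integer(length(v))))
  # smallest c with P(X >= c) <= p_threshold
  cmin <- stats::qpois(p_threshold, lambda, lower.tail = FALSE) + 1
  while (ppois(cmin - 2, lambda, lower.tail = FALSE) <= p_threshold &&
         cmin > 1) cmin <- cmin - 1
  lapply(agg, function(v) as.integer(v >= cmin))
}

#' Assemble binarized mark columns into a bins-by-marks matrix
#'
#' @param columns named list (one per mark) of [binarize()] outputs sharing
#'   the same chromosome structure.
#' @param bin_size bin width of the columns.
#' @return object of class `binarized_matrix`: list with `mat` (bins x marks
#'   0/1 matrix), `bins` (data.frame chrom/start), `bin_size`, `seq_starts`
#'   (1-based first bin of each chromosome).
#' @export
binarized_matrix <- function(columns, bin_size = 200) {
  marks <- names(columns)
  if (is.null(marks)) stop("columns must be a named list (one per mark)")
  chroms <- names(columns[[1]])
  lens <- vapply(columns[[1]], length, 0L)
  for (m in marks) {
    if (!identical(names(columns[[m]]), chroms) ||
        !identical(vapply(columns[[m]], length, 0L), lens))
      stop("mark ", m, ": chromosome structure mismatch")
  }
  mat <- do.call(cbind, lapply(columns, function(col) unlist(col, use.names = FALSE)))
  colnames(mat) <- marks
  bins <- data.frame(
    chrom = rep(chroms, lens),
    start = unlist(lapply(lens, function(n) (seq_len(n) - 1L) * bin_size)))
  structure(list(mat = mat, bins = bins, bin_size = bin_size,
                 seq_starts = c(1L, cumsum(lens)[-length(lens)] + 1L)),
            class = "binarized_matrix")
}

# bins x K matrix of per-bin log-likelihoods under product-Bernoulli emissions
.emission_loglik <- function(X, E) {
  E <- pmin(pmax(E, 1e-10), 1 - 1e-10)
  X %*% t(log(E)) + (1 - X) %*% t(log(1 - E))
}

#' Fit a Bernoulli-emission hidden Markov model by Baum-Welch
#'
#' The chromatin-state model: K hidden states, each emitting the M binary
#' mark calls independently with state-specific Bernoulli probabilities.
#' Chromosomes are independent sequences (the initial distribution applies
#' at every chromosome start). Emissions are initialized from a seeded
#' k-means on the bin patterns; transitions start near-uniform with jitter.
#'
#' @param bm `binarized_matrix`.
#' @param K number of states, default 10.
#' @param seed RNG seed for initialization (the fit is deterministic given
#'   the seed).
#' @param max_iter,tol EM stops when the relative log-likelihood gain falls
#'   below `tol` or after `max_iter` iterations.
#' @return object of class `chromatin_state_model`: `emission` (K x M),
#'   `transition` (K x K row-stochastic), `initial`, `marks`, `loglik_trace`,
#'   `state_labels` (NULL until set).
#' @export
fit_hmm <- function(bm, K = 10, seed = 1, max_iter = 200, tol = 1e-4) {
  if (K < 1) stop("K must be >= 1")
  X <- bm$mat
  Tn <- nrow(X); M <- ncol(X)
  if (K == 1) {
    # closed form: independent Bernoulli MLE, no hidden structure
    E <- matrix(colMeans(X), nrow = 1, dimnames = list(NULL, colnames(X)))
    ll <- sum(.emission_loglik(X, E))
    return(structure(list(emission = E,
                          transition = matrix(1, 1, 1),
                          initial = 1, marks = colnames(X),
                          loglik_trace = ll, K = 1L,
                          state_labels = NULL),
                     class = "chromatin_state_model"))
  }
  init_pars <- with_seed(seed, {
    E <- tryCatch({
      km <- suppressWarnings(kmeans(X, centers = K, nstart = 3,
                                    iter.max = 50))
      km$centers
    }, error = function(e) matrix(runif(K * M, 0.1, 0.9), K, M))
    E <- pmin(pmax(E + matrix(rnorm(K * M, 0, 0.01), K, M), 0.02), 0.98)
    A <- matrix(1, K, K) + matrix(runif(K * K, 0, 0.1), K, K)
    A <- A / rowSums(A)
    list(E = E, A = A, pi0 = rep(1 / K, K))
  })
  E <- init_pars$E; A <- init_pars$A; pi0 <- init_pars$pi0
  seq0 <- as.integer(bm$seq_starts - 1L)
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- .emission_loglik(X, E)
    es <- .hmm_estep(logB, A, pi0, seq0)
    trace <- c(trace, es$loglik)
    g <- es$gamma
    denom <- colSums(g)
    E <- pmin(pmax(t(g) %*% X / pmax(denom, 1e-12), 1e-6), 1 - 1e-6)
    A <- es$xi + 1e-12
    A <- A / rowSums(A)
    pi0 <- es$init_counts + 1e-12
    pi0 <- pi0 / sum(pi0)
    if (is.finite(prev) && abs(es$loglik - prev) <
        tol * abs(prev)) break
    prev <- es$loglik
  }
  if (length(unique(round(rowSums(X) + X %*% 2^(seq_len(M) - 1)))) < K)
    warning("fewer distinct bin patterns than states; model degenerate")
  colnames(E) <- colnames(X)
  structure(list(emission = E, transition = A, initial = as.numeric(pi0),
                 marks = colnames(X), loglik_trace = trace, K = as.integer(K),
                 state_labels = NULL),
            class = "chromatin_state_model")
}

#' Segment the genome with a fitted chromatin-state model
#'
#' @param model `chromatin_state_model`.
#' @param bm `binarized_matrix` with the same mark order.
#' @param method "posterior" (per-bin argmax of the forward-backward
#'   posterior; default) or "viterbi" (joint MAP path).
#' @return object of class `segmentation`: `states` (integer per bin),
#'   `bins`, `runs` (data.frame chrom/start/end/state of maximal
#'   constant-state runs, tiling the binned genome), `posterior` (bins x K,
#'   posterior method only).
#' @export
segment_genome <- function(model, bm, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  if (!identical(model$marks, colnames(bm$mat)))
    stop("mark order mismatch between model and binarized matrix")
  logB <- .emission_loglik(bm$mat, model$emission)
  seq0 <- as.integer(bm$seq_starts - 1L)
  post <- NULL
  if (model$K == 1L) {
    states <- rep(1L, nrow(bm$mat))
  } else if (method == "posterior") {
    es <- .hmm_estep(logB, model$transition, model$initial, seq0)
    post <- es$gamma
    states <- max.col(post, ties.method = "first")
  } else {
    states <- .hmm_viterbi(logB, model$transition, model$initial, seq0)
  }
  bins <- bm$bins
  bs <- bm$bin_size
  runs <- do.call(rbind, lapply(split(seq_along(states), bins$chrom), function(i) {
    r <- rle(states[i])
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    data.frame(chrom = bins$chrom[i[1]],
               start = bins$start[i[1]] + s * bs,
               end = bins$start[i[1]] + e * bs,
               state = r$values)
  }))
  rownames(runs) <- NULL
  structure(list(states = as.integer(states), bins = bins, runs = runs,
                 bin_size = bs, K = model$K, posterior = post,
                 state_labels = model$state_labels),
            class = "segmentation")
}

#' Heuristic state labels from emission signatures
#'
#' Mirrors manual ChromHMM annotation with a fixed decision list on the
#' emission matrix: promoter-mark states are "transcriptional initiation",
#' H3K36me3-dominated states "transcriptional elongation", H3K27me3 states
#' "repressed", H3K4me1/H3K27ac states "enhancer", anything else
#' "quiescent". Labels can repeat across states and can always be overridden
#' with a hand-written map.
#'
#' @param model `chromatin_state_model`.
#' @param threshold emission probability above which a mark counts as
#'   present; 0.25 by default so weak but genuine signal states (e.g.
#'   partially covered gene-body edges) label by their dominant mark.
#' @return character vector of length K.
#' @export
label_states_by_emission <- function(model, threshold = 0.25) {
  E <- model$emission
  g <- function(m) if (m %in% colnames(E)) E[, m] else rep(0, nrow(E))
  lab <- rep("quiescent", nrow(E))
  lab[g("H3K4me1") >= threshold | g("H3K27ac") >= threshold] <- "enhancer"
  lab[g("H3K27me3") >= threshold] <- "repressed"
  lab[g("H3K36me3") >= threshold] <- "transcriptional elongation"
  lab[g("H3K4me3") >= threshold] <- "transcriptional initiation"
  lab
}

#' Per-state, per-mark peak-count contrast between conditions
#'
#' For every (state, mark): peaks of each sample falling in that state's
#' segments are counted; each condition's counts are expressed as a
#' percentage of the mark's total over states; the reported difference is
#' control percent minus knockdown percent; a two-sided equal-variance
#' two-sample t-test compares the replicate counts. With n = 2 replicates
#' per condition the t-test is reported as computed, with a `low_n` caveat
#' flag.
#'
#' @param segmentation `segmentation`.
#' @param peaksets list; each element a list with fields `mark`, `condition`,
#'   `sample_id` and `peaks` (interval data.frame).
#' @param control condition label treated as control (default "control").
#' @return data.frame, one row per (state, mark): counts summed per
#'   condition, `pct_control`, `pct_kd`, `diff` (= pct_control - pct_kd),
#'   `p_value`, `label`, `low_n`.
#' @export
state_mark_contrast <- function(segmentation, peaksets, control = "control") {
  conds <- unique(vapply(peaksets, `[[`, "", "condition"))
  if (length(conds) != 2) stop("exactly two conditions required")
  if (!control %in% conds) stop("control condition '", control, "' absent")
  kd <- setdiff(conds, control)
  marks <- unique(vapply(peaksets, `[[`, "", "mark"))
  states <- sort(unique(segmentation$runs$state))
  seg_by_state <- lapply(states, function(s)
    segmentation$runs[segmentation$runs$state == s, , drop = FALSE])
  labels <- segmentation$state_labels
  rows <- list()
  for (m in marks) {
    ps <- Filter(function(p) p$mark == m, peaksets)
    cnt <- sapply(ps, function(p)
      vapply(seg_by_state, function(seg) count_in_segments(p$peaks, seg), 0L))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = length(states))
    pcond <- vapply(ps, `[[`, "", "condition")
    tot <- vapply(conds, function(cc)
      sum(cnt[, pcond == cc, drop = FALSE]), 0)
    names(tot) <- conds
    for (si in seq_along(states)) {
      cc <- cnt[si, pcond == control]
      ck <- cnt[si, pcond == kd]
      pctc <- if (tot[[control]] > 0) 100 * sum(cc) / tot[[control]] else 0
      pctk <- if (tot[[kd]] > 0) 100 * sum(ck) / tot[[kd]] else 0
      p <- NA_real_
      if (length(cc) >= 2 && length(ck) >= 2) {
        if (var(cc) == 0 && var(ck) == 0) {
          p <- if (mean(cc) == mean(ck)) 1 else 0
        } else {
          p <- t.test(cc, ck, var.equal = TRUE)$p.value
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        state = states[si],
        label = if (is.null(labels)) NA_character_ else labels[states[si]],
        mark = m,
        count_control = sum(cc), count_kd = sum(ck),
        pct_control = pctc, pct_kd = pctk, diff = pctc - pctk,
        p_value = p,
        low_n = length(cc) < 3 || length(ck) < 3,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Save / load a chromatin-state model as YAML
#' @param model `chromatin_state_model`.
#' @param path YAML file.
#' @export
write_state_model <- function(model, path) {
  yaml::write_yaml(list(
    K = model$K, marks = model$marks,
    emission = apply(model$emission, 1, as.list),
    transition = apply(model$transition, 1, as.list),
    initial = as.list(model$initial),
    state_labels = model$state_labels), path)
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  y <- yaml::read_yaml(path)
  E <- do.call(rbind, lapply(y$emission, unlist))
  colnames(E) <- y$marks
  structure(list(emission = E,
                 transition = do.call(rbind, lapply(y$transition, unlist)),
                 initial = unlist(y$initial), marks = y$marks,
                 loglik_trace = NULL, K = as.integer(y$K),
                 state_labels = if (is.null(y$state_labels)) NULL
                                else unlist(y$state_labels)),
            class = "chromatin_state_model")
}
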