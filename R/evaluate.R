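#' Per-word target correlations
#'
#' Pearson correlation of each predicted row with the corresponding gold
#' row. A zero-variance row (e.g. an untrained all-zero prediction) cannot
#' be correlated and receives the sentinel value 0, flagged in the
#' `"degenerate"` attribute.
#'
#' @param Shat Predicted matrix (m x q), e.g. `C %*% F`.
#' @param S Gold matrix of the same shape.
#' @return Numeric vector of correlations in `[-1, 1]`, named by row names
#'   of `S` when present, with logical attribute `"degenerate"`.
#' @export
target_correlations <- function(Shat, S) {
  Shat <- as.matrix(Shat)
  S <- as.matrix(S)
  if (!all(dim(Shat) == dim(S))) stop("Shat and S must have the same shape")
  A <- Shat - rowMeans(Shat)
  B <- S - rowMeans(S)
  na2 <- rowSums(A^2)
  nb2 <- rowSums(B^2)
  degenerate <- na2 == 0 | nb2 == 0
  denom <- sqrt(na2 * nb2)
  r <- ifelse(degenerate, 0, rowSums(A * B) / ifelse(degenerate, 1, denom))
  r <- pmin(1, pmax(-1, r))
  names(r) <- rownames(S)
  attr(r, "degenerate") <- degenerate
  r
}

# Row-standardised matrix for correlation-by-matrix-product; zero-variance
# rows become all-zero (correlation sentinel 0).
row_standardise <- function(M) {
  M <- as.matrix(M)
  A <- M - rowMeans(M)
  n2 <- sqrt(rowSums(A^2))
  zero <- n2 == 0
  A / ifelse(zero, 1, n2)
}

#' Rank of each word's gold vector among all gold vectors
#'
#' For each word, correlates its predicted row with every gold row and
#' ranks the word's own gold row among them: rank 1 means the target is the
#' nearest gold vector. Ties within `tol` are resolved in the target's
#' favour, so homophone sets sharing identical predictions are not
#' auto-failed. A degenerate (zero-variance) prediction is assigned rank m:
#' it carries no direction and cannot legitimately select a target.
#'
#' @param Shat Predicted matrix (m x q).
#' @param S Gold matrix (m x q).
#' @param tol Tie tolerance on correlations, default `1e-12`.
#' @return Integer vector of ranks in `1..m`.
#' @export
semantic_ranks <- function(Shat, S, tol = 1e-12) {
  Z1 <- row_standardise(Shat)
  Z2 <- row_standardise(S)
  m <- nrow(Z1)
  R <- tcrossprod(Z1, Z2)  # R[i, j] = cor(shat_i, s_j) (0 for degenerate)
  target <- diag(R)
  Shat <- as.matrix(Shat)
  pred_deg <- rowSums((Shat - rowMeans(Shat))^2) == 0
  # self-correlation R[i, i] never exceeds target + tol, so no self-term
  ranks <- 1L + rowSums(R > target + tol)
  ranks[pred_deg & m > 1] <- m
  as.integer(ranks)
}

#' Accuracy at k under correlation similarity
#'
#' A word is correct at k iff the correlation of its predicted vector with
#' its own gold vector is at least the k-th largest of its correlations
#' with all m gold vectors (ties within `1e-12` count in the target's
#' favour). `accuracy_at_k(..., k = 1)` is the correlation accuracy used
#' throughout: the predicted vector must be closest to its target.
#'
#' @param Shat Predicted matrix (m x q).
#' @param S Gold matrix (m x q).
#' @param k Integer between 1 and m.
#' @return A list with `accuracy` (type-level mean), `correct` (per-word
#'   logical flags) and `rank` (per-word target ranks).
#' @export
accuracy_at_k <- function(Shat, S, k = 1) {
  m <- nrow(as.matrix(S))
  if (k < 1 || k > m) stop("k must be between 1 and m")
  ranks <- semantic_ranks(Shat, S)
  correct <- ranks <= k
  list(accuracy = mean(correct), correct = correct, rank = ranks)
}

#' Frequency-weighted (token) accuracy
#'
#' Correctness averaged over tokens rather than types: each word's flag is
#' weighted by its token frequency, so a frequency-0 word contributes
#' nothing.
#'
#' @param correct Logical or 0/1 per-word correctness flags.
#' @param frequencies Non-negative per-word token frequencies; must sum to
#'   a positive value.
#' @return `sum(f * correct) / sum(f)`, in `[0, 1]`.
#' @export
frequency_weighted_accuracy <- function(correct, frequencies) {
  if (length(correct) != length(frequencies)) {
    stop("correct and frequencies must have equal length")
  }
  if (any(frequencies < 0)) stop("negative frequency")
  if (sum(frequencies) <= 0) stop("total frequency is zero")
  sum(frequencies * as.numeric(correct)) / sum(frequencies)
}

#' 1 - r: a latency proxy from target correlations
#'
#' The closer a predicted semantic vector is to its target, the more
#' word-like the form and the faster a lexical decision is expected to be;
#' `1 - r` is therefore expected to correlate positively with reaction
#' time.
#'
#' @param r Numeric vector of target correlations (e.g. from
#'   [target_correlations()]).
#' @return `1 - r`, in `[0, 2]`.
#' @export
one_minus_r <- function(r) {
  out <- 1 - as.numeric(r)
  names(out) <- names(r)
  out
}

#' Priming measures over prime-target pairs
#'
#' For each pair, computes `1 - cor(shat_prime, s_target)`: the predicted
#' semantic vector of the prime correlated with the gold vector of the
#' target, as a simulated reaction time for primed lexical decision. For an
#' identity pair under a perfect mapping the measure is 0; for unrelated
#' orthogonal vectors it is 1. Condition-level means and dispersions are
#' returned, along with pairwise condition contrasts whose significance is
#' summarised by a label-permutation test.
#'
#' @param pairs Data frame with character columns `prime`, `target` and
#'   `condition` (e.g. ST, S, T, UR).
#' @param Shat Predicted semantic matrix with word ids as row names.
#' @param S Gold semantic matrix with word ids as row names.
#' @param n_perm Number of label permutations for the contrast summary.
#' @param seed Seed for the permutation draw.
#' @return A list with `items` (the pairs plus the per-pair `measure`),
#'   `condition_stats` (n, mean, sd per condition) and `contrasts`
#'   (pairwise mean differences with two-sided permutation p-values).
#' @export
priming_measures <- function(pairs, Shat, S, n_perm = 1999, seed = 1L) {
  needed <- c("prime", "target", "condition")
  if (!all(needed %in% names(pairs))) {
    stop("pairs must have columns prime, target, condition")
  }
  Shat <- as.matrix(Shat)
  S <- as.matrix(S)
  ids <- rownames(S)
  if (is.null(ids) || is.null(rownames(Shat))) {
    stop("Shat and S need word ids as row names")
  }
  unknown <- setdiff(unique(c(pairs$prime, pairs$target)), ids)
  if (length(unknown) > 0) {
    stop("unknown word id(s) in pairs: ", paste(unknown, collapse = ", "))
  }
  Z1 <- row_standardise(Shat)
  Z2 <- row_standardise(S)
  pi_ <- match(pairs$prime, rownames(Shat))
  ti <- match(pairs$target, ids)
  r <- rowSums(Z1[pi_, , drop = FALSE] * Z2[ti, , drop = FALSE])
  items <- data.frame(prime = pairs$prime, target = pairs$target,
                      condition = pairs$condition, measure = 1 - r,
                      stringsAsFactors = FALSE)
  conds <- unique(items$condition)
  stats <- do.call(rbind, lapply(conds, function(cc) {
    v <- items$measure[items$condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  contrasts <- NULL
  if (length(conds) >= 2) {
    cmb <- utils::combn(conds, 2)
    set.seed(seed)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      va <- items$measure[items$condition == a]
      vb <- items$measure[items$condition == b]
      obs <- mean(va) - mean(vb)
      pool <- c(va, vb)
      na <- length(va)
      perm <- replicate(n_perm, {
        s <- sample.int(length(pool), na)
        mean(pool[s]) - mean(pool[-s])
      })
      p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
      data.frame(condition_a = a, condition_b = b, mean_diff = obs,
                 p_perm = p, stringsAsFactors = FALSE)
    }))
  }
  list(items = items, condition_stats = stats, contrasts = contrasts)
}

#' Per-word measure table for a fitted mapping
#'
#' Convenience wrapper computing, for each lexicon word, the target
#' correlation, correctness at the requested k values, the token frequency
#' and the `1 - r` latency proxy, as a table ready for [write_measures()].
#'
#' @param lex An `ldl_lexicon` aligned with `C` and `S`.
#' @param C Cue matrix (m x r).
#' @param S Gold semantic matrix (m x q).
#' @param F_mat Comprehension mapping (r x q).
#' @param k Integer vector of k values for accuracy flags, default `c(1, 10)`
#'   (capped at m).
#' @return Data frame with columns `word_id`, `frequency`,
#'   `target_correlation`, `one_minus_r`, `rank` and one `correct_at_<k>`
#'   column per k.
#' @export
ldl_measures <- function(lex, C, S, F_mat, k = c(1, 10)) {
  Shat <- as.matrix(C %*% F_mat)
  r <- target_correlations(Shat, S)
  ranks <- semantic_ranks(Shat, S)
  out <- data.frame(word_id = lex$word_id, frequency = lex$frequency,
                    target_correlation = as.numeric(r),
                    one_minus_r = 1 - as.numeric(r),
                    rank = ranks, stringsAsFactors = FALSE)
  for (kk in unique(pmin(k, nrow(lex)))) {
    out[[paste0("correct_at_", kk)]] <- as.integer(ranks <= kk)
  }
  out
}
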