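#' Batchwise incremental learning over an ordered token stream
#'
#' Trains the comprehension mapping with the Widrow-Hoff rule over a token
#' stream in its given order, evaluating after every `batch` learning
#' events (and after the final partial batch): at each evaluation all
#' words' target correlations are recorded, together with each word's token
#' count within the batch just processed. For comparison, the order-free
#' frequency-informed mapping is fitted on the stream's aggregate counts.
#'
#' @param stream Character vector of word ids (learning order) or integer
#'   row indices.
#' @param lex Lexicon resolving the stream ids; row order must match `C`
#'   and `S`.
#' @param C Cue matrix (m x r).
#' @param S Semantic matrix (m x q).
#' @param eta Positive learning rate.
#' @param batch Evaluation interval in events, >= 1 (a batch larger than
#'   the stream gives a single evaluation at stream end).
#' @param ridge Ridge passed to the frequency-informed fit.
#' @return An object of class `ldl_trajectory`: a list with `correlations`
#'   (n_batches x m matrix), `counts` (n_batches x m within-batch token
#'   counts), `F_whl`, `F_fil`, `aggregate_frequencies`, `batch`, `eta` and
#'   `word_id`.
#' @export
run_trajectory <- function(stream, lex, C, S, eta, batch = 5000, ridge = 0) {
  if (batch < 1) stop("batch must be >= 1")
  m <- nrow(C)
  if (is.character(stream)) {
    idx <- match(stream, lex$word_id)
    if (anyNA(idx)) {
      stop("stream contains unknown id(s): ",
           paste(utils::head(unique(stream[is.na(idx)]), 5), collapse = ", "))
    }
  } else {
    idx <- as.integer(stream)
    if (any(idx < 1 | idx > m)) stop("stream index out of range")
  }
  T_len <- length(idx)
  if (T_len < 1) stop("empty stream")
  Sd <- as.matrix(S)
  rows <- row_support(C)
  r <- ncol(C)
  q <- ncol(Sd)
  F_mat <- matrix(0, r, q)
  bounds <- unique(c(seq_len(T_len %/% batch) * batch, T_len))
  n_b <- length(bounds)
  corr <- matrix(NA_real_, n_b, m, dimnames = list(NULL, lex$word_id))
  counts <- matrix(0L, n_b, m, dimnames = list(NULL, lex$word_id))
  b <- 1L
  cnt <- integer(m)
  for (t in seq_len(T_len)) {
    i <- idx[t]
    ii <- rows$idx[[i]]
    v <- rows$val[[i]]
    pred <- drop(v %*% F_mat[ii, , drop = FALSE])
    err <- Sd[i, ] - pred
    if (any(!is.finite(err))) {
      stop("non-finite update in batch ", b, " (event ", t,
           "); eta may be too large")
    }
    F_mat[ii, ] <- F_mat[ii, , drop = FALSE] + eta * outer(v, err)
    cnt[i] <- cnt[i] + 1L
    if (t == bounds[b]) {
      corr[b, ] <- as.numeric(target_correlations(as.matrix(C %*% F_mat), Sd))
      counts[b, ] <- cnt
      cnt <- integer(m)
      b <- b + 1L
    }
  }
  f_agg <- tabulate(idx, nbins = m)
  structure(list(
    correlations = corr,
    counts = counts,
    F_whl = F_mat,
    F_fil = solve_frequency_informed(C, S, f_agg, ridge = ridge),
    aggregate_frequencies = f_agg,
    batch = as.integer(batch),
    eta = eta,
    n_events = T_len,
    word_id = lex$word_id
  ), class = "ldl_trajectory")
}

#' @export
print.ldl_trajectory <- function(x, ...) {
  cat("Widrow-Hoff learning trajectory\n")
  cat("  events:", x$n_events, " batch size:", x$batch,
      " evaluations:", nrow(x$correlations), "\n")
  cat("  words:", length(x$word_id), " eta:", x$eta, "\n")
  invisible(x)
}

#' Occurrence-time moments of each word's frequency distribution
#'
#' Treats the batch index as a random variable with mass proportional to
#' the word's per-batch token count and returns its weighted mean, mode
#' (smallest maximising batch on ties), skewness and excess kurtosis. A
#' high mean/mode and negative skew indicate a word whose tokens cluster
#' late in the stream. Words occurring in a single batch (zero variance)
#' receive the sentinel 0 for skewness and kurtosis, flagged in
#' `degenerate`. Because raw kurtosis is outlier-dominated, a
#' sign-preserving damped version `sign(k) * log(1 + |k|)` is also
#' returned (`kurtosis_tr`); this transform is this package's own choice.
#' Per-batch counts normalised by each batch's maximum count are exposed in
#' the `"normalized_counts"` attribute for plotting.
#'
#' @param traj An `ldl_trajectory` from [run_trajectory()].
#' @return Data frame with columns `word_id`, `total`, `mean`, `mode`,
#'   `skewness`, `kurtosis`, `kurtosis_tr` and `degenerate`; words with
#'   zero total count get an `NA` moment row, flagged degenerate.
#' @export
occurrence_moments <- function(traj) {
  counts <- traj$counts
  n_b <- nrow(counts)
  m <- ncol(counts)
  b_idx <- seq_len(n_b)
  out <- data.frame(word_id = traj$word_id,
                    total = colSums(counts),
                    mean = NA_real_, mode = NA_integer_,
                    skewness = NA_real_, kurtosis = NA_real_,
                    kurtosis_tr = NA_real_, degenerate = TRUE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    w <- counts[, j]
    tot <- sum(w)
    if (tot == 0) next
    mu <- sum(w * b_idx) / tot
    v <- sum(w * (b_idx - mu)^2) / tot
    out$mean[j] <- mu
    out$mode[j] <- b_idx[which.max(w)]
    if (v == 0) {
      out$skewness[j] <- 0
      out$kurtosis[j] <- 0
      out$kurtosis_tr[j] <- 0
      out$degenerate[j] <- TRUE
    } else {
      sk <- sum(w * (b_idx - mu)^3) / tot / v^1.5
      ku <- sum(w * (b_idx - mu)^4) / tot / v^2 - 3
      out$skewness[j] <- sk
      out$kurtosis[j] <- ku
      out$kurtosis_tr[j] <- sign(ku) * log1p(abs(ku))
      out$degenerate[j] <- FALSE
    }
  }
  norm_counts <- counts
  for (b in seq_len(n_b)) {
    mx <- max(counts[b, ])
    if (mx > 0) norm_counts[b, ] <- counts[b, ] / mx
  }
  attr(out, "normalized_counts") <- norm_counts
  attr(out, "kurtosis_transform") <-
    "sign(k) * log(1 + |k|); package's own outlier damping"
  out
}

#' Per-word difference between incremental and frequency-informed learning
#'
#' Compares the final Widrow-Hoff mapping with the frequency-informed
#' mapping fitted on the stream's aggregate counts: per word,
#' `delta = r_WHL - r_FIL` (positive when order-sensitive learning wins,
#' e.g. for words whose tokens arrive late), plus the Pearson correlation
#' between the two per-word target-correlation vectors as a summary of how
#' similar the two solutions are. The returned table joins the deltas with
#' the occurrence-time moments for downstream regression.
#'
#' @param traj An `ldl_trajectory` from [run_trajectory()].
#' @param C Cue matrix used for training.
#' @param S Semantic matrix used for training.
#' @return A list with `table` (word_id, r_whl, r_fil, delta, moments) and
#'   `summary_correlation`.
#' @export
whl_fil_delta <- function(traj, C, S) {
  r_whl <- traj$correlations[nrow(traj$correlations), ]
  r_fil <- as.numeric(target_correlations(as.matrix(C %*% traj$F_fil), S))
  delta <- as.numeric(r_whl) - r_fil
  mom <- occurrence_moments(traj)
  tbl <- data.frame(word_id = traj$word_id,
                    r_whl = as.numeric(r_whl), r_fil = r_fil, delta = delta,
                    stringsAsFactors = FALSE)
  tbl <- cbind(tbl, mom[, c("total", "mean", "mode", "skewness",
                            "kurtosis", "kurtosis_tr", "degenerate")])
  list(table = tbl,
       summary_correlation = stats::cor(as.numeric(r_whl), r_fil))
}
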