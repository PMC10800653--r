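#' Endstate learning: least-squares linear mapping
#'
#' Solves for the matrix `F` minimising the summed squared row-wise error of
#' `X F - Y`, i.e. multivariate multiple regression via the normal equations
#' \deqn{F = (X^T X)^{-1} X^T Y.} The Gram matrix is factorised by Cholesky
#' decomposition when positive definite; otherwise (rank deficiency, e.g.
#' homophones inducing duplicate rows) the unique minimum-norm least-squares
#' solution is computed from the singular value decomposition of `X`. With
#' `ridge = 0` and a consistent full-rank system, `X F = Y` exactly.
#'
#' @param X Input matrix (m x r), dense or sparse; e.g. a cue matrix `C`
#'   for comprehension or a semantic matrix `S` for production.
#' @param Y Output matrix (m x q) with the same number of rows.
#' @param ridge Small non-negative ridge penalty added to the Gram diagonal.
#' @return Dense mapping matrix (r x q) with attributes `method = "EL"` and
#'   `solver` (`"cholesky"` or `"minimum-norm"`). Row names are taken from
#'   `colnames(X)`.
#' @export
solve_linear_mapping <- function(X, Y, ridge = 0) {
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of rows (",
         nrow(X), " vs ", nrow(Y), ")")
  }
  if (nrow(X) < 1) stop("empty system")
  if (ridge < 0) stop("ridge must be non-negative")
  if (all(X == 0)) stop("X is all zero")
  G <- as.matrix(Matrix::crossprod(X))
  if (ridge > 0) diag(G) <- diag(G) + ridge
  B <- as.matrix(Matrix::crossprod(X, Y))
  solver <- "cholesky"
  # a numerically singular Gram (duplicate cue rows, more cues than words)
  # has no stable Cholesky solution; only the SVD minimum-norm solution is
  # well defined and invariant under row rescaling, so detect it up front
  ill <- tryCatch(rcond(G) < 1e-10, error = function(e) TRUE)
  F_mat <- if (ill) NULL else tryCatch({
    R <- chol(G)
    backsolve(R, backsolve(R, B, transpose = TRUE))
  }, error = function(e) NULL)
  if (is.null(F_mat) || any(!is.finite(F_mat))) {
    solver <- "minimum-norm"
    F_mat <- minimum_norm_solve(as.matrix(X), Y, ridge)
  }
  dimnames(F_mat) <- list(colnames(X), colnames(Y))
  attr(F_mat, "method") <- "EL"
  attr(F_mat, "solver") <- solver
  F_mat
}

# Minimum-norm least squares via SVD; for ridge > 0 the shrunken inverse
# d / (d^2 + ridge) is used instead of thresholded 1/d.
minimum_norm_solve <- function(X, Y, ridge = 0) {
  sv <- svd(X)
  d <- sv$d
  if (ridge > 0) {
    dinv <- d / (d^2 + ridge)
  } else {
    tol <- max(dim(X)) * .Machine$double.eps * max(d)
    dinv <- ifelse(d > tol, 1 / d, 0)
  }
  sv$v %*% (dinv * crossprod(sv$u, Y))
}

#' Frequency-informed learning: weighted least-squares mapping
#'
#' Computes the mapping that endstate learning would produce on matrices
#' `C_f`, `S_f` in which the row of every word is replicated according to
#' its token frequency, without materialising the replication: row i of both
#' `C` and `S` is scaled by `sqrt(f_i / max(f))` (so that the squared scale
#' is proportional to the weight) and the scaled system is solved by
#' [solve_linear_mapping()]. Normalising by the maximum frequency leaves the
#' solution unchanged but is numerically more stable. Words with frequency 0
#' contribute nothing to the fit but remain evaluable.
#'
#' @param C Cue (or, for production, semantic) matrix, m x r.
#' @param S Target matrix, m x q.
#' @param frequencies Per-word non-negative weights of length m; at least
#'   one must be positive. Integer token frequencies reproduce the
#'   row-replication construction exactly.
#' @param ridge Small non-negative ridge penalty.
#' @return Dense mapping matrix (r x q) with attribute `method = "FIL"`.
#' @export
solve_frequency_informed <- function(C, S, frequencies, ridge = 0) {
  if (length(frequencies) != nrow(C)) {
    stop("frequencies must have length nrow(C)")
  }
  if (any(frequencies < 0)) stop("negative weight")
  if (all(frequencies == 0)) stop("all weights are zero")
  w <- sqrt(frequencies / max(frequencies))
  Ct <- Matrix::Diagonal(x = w) %*% C
  St <- as.matrix(w * as.matrix(S))
  F_mat <- solve_linear_mapping(Ct, St, ridge)
  dimnames(F_mat) <- list(colnames(C), colnames(S))
  attr(F_mat, "method") <- "FIL"
  F_mat
}

#' Translate token frequencies into a sequence of learning events
#'
#' For incremental learning, each word contributes a number of learning
#' events derived from its frequency: `raw` uses the frequency itself (a
#' word with frequency 100 is presented 100 times); `scaled` divides by
#' `divisor` and applies a ceiling, so attested words keep at least one
#' event; `log_backoff` uses `round(log(f + 1))`, floored at one event for
#' attested words (the rounding convention is this package's, since a count
#' must be an integer).
#'
#' @param frequencies Non-negative integer token counts.
#' @param transform One of `"raw"`, `"log_backoff"`, `"scaled"`.
#' @param divisor Divisor for the `scaled` transform, >= 1.
#' @param order `"shuffled"` (default; uses `seed`) or `"as_given"` (all of
#'   word 1's events, then word 2's, ...).
#' @param seed Integer seed for shuffling.
#' @return Integer vector of word indices (class `ldl_events`), with
#'   attributes `counts` (events per word), `transform` and `seed`.
#' @export
frequencies_to_events <- function(frequencies,
                                  transform = c("raw", "log_backoff", "scaled"),
                                  divisor = 100,
                                  order = c("shuffled", "as_given"),
                                  seed = 1L) {
  transform <- match.arg(transform)
  order <- match.arg(order)
  if (any(frequencies < 0)) stop("negative frequency")
  if (transform == "scaled" && divisor < 1) stop("divisor must be >= 1")
  counts <- switch(transform,
    raw = as.integer(frequencies),
    scaled = as.integer(ceiling(frequencies / divisor)),
    log_backoff = {
      n <- as.integer(round(log(frequencies + 1)))
      n[frequencies >= 1 & n < 1] <- 1L
      n
    })
  events <- rep.int(seq_along(frequencies), counts)
  if (length(events) < 1) {
    stop("no learning events: all transformed frequencies are zero")
  }
  if (order == "shuffled") {
    set.seed(seed)
    events <- events[sample.int(length(events))]
  }
  structure(as.integer(events), counts = counts, transform = transform,
            order = order, seed = if (order == "shuffled") seed else NA_integer_,
            class = "ldl_events")
}

#' Incremental Widrow-Hoff learning of a linear mapping
#'
#' Applies the delta rule once per learning event, in order:
#' \deqn{F \leftarrow F + c_t^T (s_t - c_t F)\,\eta,}
#' where \eqn{c_t} and \eqn{s_t} are the cue and semantic row vectors of the
#' word encountered at event t and \eqn{\eta} is the learning rate. Training
#' starts from the zero matrix unless `F0` is given, and is deterministic
#' given the event sequence and `F0`.
#'
#' @param C Cue matrix, m x r (sparse or dense).
#' @param S Semantic matrix, m x q.
#' @param events Integer vector of row indices (e.g. from
#'   [frequencies_to_events()]) in learning order.
#' @param eta Positive learning rate.
#' @param F0 Optional initial mapping (r x q); default zero.
#' @param snapshot_every If a positive integer N, a copy of `F` is retained
#'   after every N events and returned in the `"snapshots"` attribute.
#' @return Dense mapping matrix (r x q), attributes `method = "WHL"`, `eta`,
#'   `n_events`, and optionally `snapshots` (list) and `snapshot_events`.
#' @export
train_incremental <- function(C, S, events, eta, F0 = NULL,
                              snapshot_every = NULL) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) {
    stop("eta must be a positive real")
  }
  m <- nrow(C)
  r <- ncol(C)
  q <- ncol(S)
  events <- as.integer(events)
  if (length(events) < 1) stop("empty event sequence")
  if (any(events < 1 | events > m)) stop("event index out of range 1..m")
  if (is.null(F0)) {
    F_mat <- matrix(0, r, q)
  } else {
    if (!all(dim(F0) == c(r, q))) stop("F0 has wrong shape")
    F_mat <- as.matrix(F0)
  }
  Sd <- as.matrix(S)
  rows <- row_support(C)
  snaps <- list()
  snap_at <- integer(0)
  do_snap <- !is.null(snapshot_every) && snapshot_every >= 1
  for (t in seq_along(events)) {
    i <- events[t]
    idx <- rows$idx[[i]]
    v <- rows$val[[i]]
    if (length(idx) == 0) {
      stop("event ", t, " refers to word index ", i,
           " whose cue row is all zero")
    }
    pred <- drop(v %*% F_mat[idx, , drop = FALSE])
    err <- Sd[i, ] - pred
    if (any(!is.finite(err))) {
      stop("non-finite update at event ", t, " (word index ", i,
           "); eta may be too large")
    }
    F_mat[idx, ] <- F_mat[idx, , drop = FALSE] + eta * outer(v, err)
    if (do_snap && t %% snapshot_every == 0) {
      snaps[[length(snaps) + 1]] <- F_mat
      snap_at <- c(snap_at, t)
    }
  }
  dimnames(F_mat) <- list(colnames(C), colnames(S))
  attr(F_mat, "method") <- "WHL"
  attr(F_mat, "eta") <- eta
  attr(F_mat, "n_events") <- length(events)
  if (do_snap) {
    attr(F_mat, "snapshots") <- snaps
    attr(F_mat, "snapshot_events") <- snap_at
  }
  F_mat
}

# Per-row nonzero support of a (possibly sparse) matrix, computed once so
# the event loop touches only active cues.
row_support <- function(C) {
  if (methods::is(C, "sparseMatrix")) {
    R <- methods::as(methods::as(C, "generalMatrix"), "RsparseMatrix")
    p <- R@p
    idx <- lapply(seq_len(nrow(C)), function(i) R@j[seq2(p[i] + 1, p[i + 1])] + 1L)
    val <- lapply(seq_len(nrow(C)), function(i) R@x[seq2(p[i] + 1, p[i + 1])])
  } else {
    Cd <- as.matrix(C)
    idx <- lapply(seq_len(nrow(Cd)), function(i) which(Cd[i, ] != 0))
    val <- lapply(seq_len(nrow(Cd)), function(i) Cd[i, idx[[i]]])
  }
  list(idx = idx, val = val)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)
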