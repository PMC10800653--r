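test_that("endstate solution satisfies the defining least-squares identities", {
  set.seed(1)
  Y <- matrix(rnorm(6), 3, 2)
  expect_equal(solve_linear_mapping(diag(3), Y), Y, ignore_attr = TRUE)
  expect_equal(solve_linear_mapping(matrix(rbinom(12, 1, 0.5) + diag(3)[, 1],
                                           3, 4),
                                    matrix(0, 3, 2)),
               matrix(0, 4, 2), ignore_attr = TRUE)
})

test_that("endstate learning recovers a planted mapping on full-rank systems", {
  set.seed(2)
  X <- matrix(rnorm(24), 6, 4)
  F_star <- matrix(rnorm(8), 4, 2)
  F_hat <- solve_linear_mapping(X, X %*% F_star)
  expect_lt(max(abs(F_hat - F_star)), 1e-8)
  # pseudo-inverse oracle agrees
  expect_equal(unclass(F_hat)[, ], MASS::ginv(X) %*% (X %*% F_star),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("endstate solver validates its inputs", {
  expect_error(solve_linear_mapping(diag(3), matrix(0, 4, 2)), "same number")
  expect_error(solve_linear_mapping(matrix(0, 3, 2), matrix(0, 3, 2)),
               "all zero")
  expect_error(solve_linear_mapping(diag(3), matrix(0, 3, 2), ridge = -1),
               "non-negative")
})

test_that("rank-deficient systems fall back to the minimum-norm solution", {
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3)
  X <- rbind(X, X[1, ])          # duplicate row: homophone situation
  X <- cbind(X, X[, 1])          # linearly dependent cue column
  Y <- matrix(rnorm(10), 5, 2)
  F_hat <- solve_linear_mapping(X, Y)
  expect_equal(attr(F_hat, "solver"), "minimum-norm")
  expect_equal(unclass(F_hat)[, ], MASS::ginv(X) %*% Y, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("frequency-informed learning equals endstate on replicated rows", {
  for (seed in 1:25) {
    inst <- rand_instance(seed,
                          with_duplicates = seed %% 3 == 0,
                          with_zero_f = seed %% 4 == 0)
    F_fil <- solve_frequency_informed(inst$C, inst$S, inst$f)
    F_rep <- replication_solution(inst$C, inst$S, inst$f)
    expect_lt(max(abs(F_fil - F_rep)), 1e-8)
  }
})

test_that("uniform weights collapse to endstate and scaling is irrelevant", {
  inst <- rand_instance(99)
  F_el <- solve_linear_mapping(inst$C, inst$S)
  F_u <- solve_frequency_informed(inst$C, inst$S, rep(3L, inst$m))
  expect_lt(max(abs(F_u - F_el)), 1e-10)
  F_1 <- solve_frequency_informed(inst$C, inst$S, inst$f)
  F_10 <- solve_frequency_informed(inst$C, inst$S, 10 * inst$f)
  expect_lt(max(abs(F_1 - F_10)), 1e-10)
})

test_that("frequency-informed learning validates its weights", {
  inst <- rand_instance(7)
  expect_error(solve_frequency_informed(inst$C, inst$S, rep(0, inst$m)),
               "all weights")
  f_bad <- inst$f
  f_bad[1] <- -1
  expect_error(solve_frequency_informed(inst$C, inst$S, f_bad), "negative")
  expect_error(solve_frequency_informed(inst$C, inst$S, inst$f[-1]), "length")
})

test_that("frequencies translate into learning events per transform", {
  ev <- frequencies_to_events(100L, "raw", order = "as_given")
  expect_length(ev, 100L)
  expect_true(all(ev == 1L))

  ev2 <- frequencies_to_events(c(250L, 1L), "scaled", divisor = 100,
                               order = "as_given")
  expect_equal(attr(ev2, "counts"), c(3L, 1L))

  # round(log(f + 1)), floored at one event for attested words
  ev3 <- frequencies_to_events(c(0L, 1L, 100L, 10000L), "log_backoff",
                               order = "as_given")
  expect_equal(attr(ev3, "counts"), c(0L, 1L, 5L, 9L))

  expect_error(frequencies_to_events(0L, "raw"), "no learning events")
  expect_error(frequencies_to_events(10L, "scaled", divisor = 0), "divisor")
  expect_error(frequencies_to_events(-1L, "raw"), "negative")
})

test_that("event shuffling is deterministic under a fixed seed", {
  f <- c(5L, 3L, 2L)
  e1 <- frequencies_to_events(f, "raw", seed = 42L)
  e2 <- frequencies_to_events(f, "raw", seed = 42L)
  e3 <- frequencies_to_events(f, "raw", seed = 43L)
  expect_identical(as.integer(e1), as.integer(e2))
  expect_false(identical(as.integer(e1), as.integer(e3)))
  expect_equal(sort(tabulate(e1, 3)), sort(f))
})

test_that("a single Widrow-Hoff event from zero equals eta * c^T s exactly", {
  C <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3, byrow = TRUE)
  S <- matrix(c(2, -1, 0.5, 3), 2, 2, byrow = TRUE)
  F_1 <- train_incremental(C, S, 1L, eta = 0.5)
  expect_equal(unclass(F_1)[, ], 0.5 * outer(C[1, ], S[1, ]), tolerance = 0,
               ignore_attr = TRUE)
})

test_that("a zero-error event leaves the mapping unchanged", {
  C <- diag(2)
  F0 <- matrix(c(1, 2, 3, 4), 2, 2)
  S <- C %*% F0
  F_after <- train_incremental(C, S, c(1L, 2L, 1L), eta = 0.1, F0 = F0)
  expect_equal(unclass(F_after)[, ], F0, tolerance = 0, ignore_attr = TRUE)
})

test_that("two events on orthogonal unit cues match the unrolled recurrence", {
  C <- rbind(c(1, 0, 0), c(0, 1, 0))
  S <- rbind(c(2, -1), c(4, 0.5))
  eta <- 0.5
  # unroll by hand: F after event 1 then event 2
  F_manual <- matrix(0, 3, 2)
  F_manual <- F_manual + eta * outer(C[1, ], S[1, ] - drop(C[1, ] %*% F_manual))
  F_manual <- F_manual + eta * outer(C[2, ], S[2, ] - drop(C[2, ] %*% F_manual))
  F_pkg <- train_incremental(C, S, c(1L, 2L), eta = eta)
  expect_equal(unclass(F_pkg)[, ], F_manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  # repeated events on the same orthogonal cue follow the geometric series
  F_rep <- train_incremental(C, S, c(1L, 1L, 1L), eta = eta)
  expect_equal(F_rep[1, ], (1 - (1 - eta)^3) * S[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("incremental training validates events and detects divergence", {
  C <- diag(2)
  S <- matrix(1, 2, 2)
  expect_error(train_incremental(C, S, 3L, eta = 0.1), "out of range")
  expect_error(train_incremental(C, S, integer(0), eta = 0.1), "empty")
  expect_error(train_incremental(C, S, 1L, eta = 0), "positive")
  big <- matrix(1, 2, 2)
  expect_error(train_incremental(big, S * 1e300, rep(c(1L, 2L), 400),
                                 eta = 10),
               "event")
})

test_that("snapshots are retained at the requested interval", {
  inst <- planted_setup(10, m = 10)
  ev <- frequencies_to_events(rep(1L, 10), "raw", seed = 1)
  F_fin <- train_incremental(inst$C, inst$S, ev, eta = 0.01,
                             snapshot_every = 4)
  expect_length(attr(F_fin, "snapshots"), 2L)
  expect_equal(attr(F_fin, "snapshot_events"), c(4L, 8L))
})

test_that("Widrow-Hoff approaches the endstate over repeated uniform epochs", {
  # long distinctive forms give a well-conditioned cue Gram matrix, so the
  # delta rule's slowest mode still converges within the epoch budget
  inst <- planted_setup(21, m = 30, noise_sd = 0, n = 3, alphabet = letters,
                        length_range = c(16, 24))
  F_el <- solve_linear_mapping(inst$C, inst$S)
  ev <- unlist(lapply(1:300, function(e) {
    frequencies_to_events(rep(1L, 30), "raw", seed = 500L + e)
  }))
  F_wh <- train_incremental(inst$C, inst$S, ev, eta = 5e-3)
  rel <- norm(F_wh - F_el, "F") / norm(F_el, "F")
  expect_lt(rel, 1e-3)
  # half the epochs leave a strictly larger residual: distance decreases
  F_half <- train_incremental(inst$C, inst$S, ev[seq_len(length(ev) / 2)],
                              eta = 5e-3)
  expect_lt(rel, norm(F_half - F_el, "F") / norm(F_el, "F"))
})

test_that("training is bit-reproducible under identical seeds and inputs", {
  inst <- planted_setup(33, m = 20, noise_sd = 1)
  ev1 <- frequencies_to_events(inst$lexicon$frequency, "scaled",
                               divisor = 10, seed = 5L)
  ev2 <- frequencies_to_events(inst$lexicon$frequency, "scaled",
                               divisor = 10, seed = 5L)
  expect_identical(as.integer(ev1), as.integer(ev2))
  F_a <- train_incremental(inst$C, inst$S, ev1, eta = 0.01)
  F_b <- train_incremental(inst$C, inst$S, ev2, eta = 0.01)
  expect_identical(unclass(F_a)[, ], unclass(F_b)[, ])
})
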