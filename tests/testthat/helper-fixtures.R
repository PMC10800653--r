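# Shared fixtures, built in code at test time.

toy_lexicon <- function() {
  lexicon(word_id = c("aap", "noot", "mies", "piet", "zus"),
          form = c("aap", "noot", "mies", "piet", "zus"),
          frequency = c(7L, 3L, 1L, 5L, 2L))
}

# Random weighted-regression instance within the small-instance envelope
# (m <= 50, r <= 40, q <= 10, integer frequencies <= 20). Binary cue rows
# are guaranteed non-empty; duplicate rows and zero frequencies can be
# injected to exercise rank deficiency and zero-weight words.
rand_instance <- function(seed, with_duplicates = FALSE, with_zero_f = FALSE) {
  set.seed(seed)
  m <- sample(5:50, 1)
  r <- sample(4:40, 1)
  q <- sample(2:10, 1)
  C <- matrix(rbinom(m * r, 1, 0.3), m, r)
  empty <- rowSums(C) == 0
  C[cbind(which(empty), sample.int(r, sum(empty), replace = TRUE))] <- 1
  if (with_duplicates && m >= 2) C[m, ] <- C[1, ]
  S <- matrix(rnorm(m * q), m, q)
  f <- sample.int(20, m, replace = TRUE)
  if (with_zero_f) f[sample.int(m, max(1, m %/% 5))] <- 0L
  if (all(f == 0)) f[1] <- 1L
  list(C = C, S = S, f = f, m = m, r = r, q = q)
}

# Brute-force oracle: endstate solution on row-replicated matrices.
replication_solution <- function(C, S, f) {
  idx <- rep(seq_len(nrow(C)), f)
  solve_linear_mapping(C[idx, , drop = FALSE], S[idx, , drop = FALSE])
}

# Small planted-linear setup through the generator.
planted_setup <- function(seed, m = 50, noise_sd = 0, n = 2,
                          alphabet = letters[1:6], length_range = c(3, 7),
                          q = 10, f_max = 100, ...) {
  cfg <- generator_config(seed = seed, m = m, alphabet = alphabet,
                          length_range = length_range, q = q, f_max = f_max,
                          semantic_model = "planted_linear",
                          noise_sd = noise_sd, ...)
  lex <- generate_lexicon(cfg)
  C <- build_cue_matrix(lex, n = n)
  S <- generate_semantics(lex, C, cfg)
  list(config = cfg, lexicon = lex, C = C, S = S,
       F_star = attr(S, "F_star"))
}
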