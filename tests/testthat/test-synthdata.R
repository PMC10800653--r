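test_that("generated frequencies follow the deterministic Zipf law", {
  cfg <- generator_config(seed = 1, m = 100, f_max = 1000, zipf_exponent = 1)
  lex <- generate_lexicon(cfg)
  expect_equal(nrow(lex), 100L)
  expect_true(all(diff(lex$frequency) <= 0))
  expect_equal(lex$frequency[1], 1000L)
  expect_equal(lex$frequency[1] / lex$frequency[100], 100)
  expect_false(any(duplicated(lex$word_id)))
})

test_that("log-log regression of frequency on rank recovers the exponent", {
  for (a in c(0.8, 1.2)) {
    cfg <- generator_config(seed = 2, m = 500, f_max = 100000,
                            zipf_exponent = a)
    lex <- generate_lexicon(cfg)
    fit <- lm(log(lex$frequency) ~ log(seq_len(500)))
    expect_lt(abs(unname(coef(fit)[2]) + a), 0.1)
  }
})

test_that("homophone injection yields exactly the requested identical pairs", {
  cfg <- generator_config(seed = 3, m = 40, homophone_pairs = 2)
  lex <- generate_lexicon(cfg)
  tab <- table(lex$form)
  expect_equal(sum(tab == 2), 2L)
  expect_equal(sum(tab > 2), 0L)
  expect_false(any(duplicated(lex$word_id)))
})

test_that("generation is a pure function of config and seed", {
  cfg <- generator_config(seed = 7, m = 30)
  expect_identical(generate_lexicon(cfg), generate_lexicon(cfg))
  lex <- generate_lexicon(cfg)
  C <- build_cue_matrix(lex, 2)
  expect_identical(generate_semantics(lex, C, cfg),
                   generate_semantics(lex, C, cfg))
  expect_identical(generate_token_stream(lex, 200, cfg),
                   generate_token_stream(lex, 200, cfg))
  cfg2 <- generator_config(seed = 8, m = 30)
  expect_false(identical(generate_lexicon(cfg2), lex))
})

test_that("an exhausted form space is reported", {
  cfg <- generator_config(seed = 4, m = 10, alphabet = c("a", "b"),
                          length_range = c(1, 1))
  expect_error(generate_lexicon(cfg), "unique forms")
})

test_that("noise-free planted semantics are perfectly recoverable", {
  inst <- planted_setup(5, m = 30, noise_sd = 0)
  F_el <- solve_linear_mapping(inst$C, inst$S)
  Shat <- as.matrix(inst$C %*% F_el)
  expect_lt(max(abs(Shat - inst$S)), 1e-8)
  expect_equal(accuracy_at_k(Shat, inst$S, 1)$accuracy, 1)
})

test_that("gaussian semantic row norms concentrate near sqrt(q)", {
  cfg <- generator_config(seed = 6, m = 100, q = 300,
                          semantic_model = "gaussian")
  lex <- generate_lexicon(cfg)
  S <- generate_semantics(lex, NULL, cfg)
  norms <- sqrt(rowSums(S^2))
  # chi_q concentration: sd of the norm is ~ 1/sqrt(2), mean ~ sqrt(q)
  expect_true(all(abs(norms - sqrt(300)) < 4))
})

test_that("stationary streams match multinomial expectation", {
  cfg <- generator_config(seed = 9, m = 50, f_max = 100)
  lex <- generate_lexicon(cfg)
  stream <- generate_token_stream(lex, 10000, cfg)
  counts <- table(factor(stream, levels = lex$word_id))
  p <- lex$frequency / sum(lex$frequency)
  expected <- 10000 * p
  bound <- 4 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(as.numeric(counts) - expected) <= bound + 1))
})

test_that("late-burst tokens land in the final fraction of the stream", {
  cfg0 <- generator_config(seed = 10, m = 20, f_max = 100)
  lex <- generate_lexicon(cfg0)
  bw <- lex$word_id[3]
  cfg <- generator_config(seed = 10, m = 20, f_max = 100,
                          schedule = "late_burst", burst_fraction = 0.1,
                          burst_words = bw)
  stream <- generate_token_stream(lex, 5000, cfg)
  pos <- which(stream == bw)
  expect_gte(mean(pos > 0.9 * 5000), 0.95)
  cfg_e <- generator_config(seed = 10, m = 20, f_max = 100,
                            schedule = "early_burst", burst_fraction = 0.1,
                            burst_words = bw)
  pos_e <- which(generate_token_stream(lex, 5000, cfg_e) == bw)
  expect_gte(mean(pos_e <= 0.1 * 5000), 0.95)
  cfg_bad <- generator_config(seed = 10, m = 20, schedule = "late_burst")
  expect_error(generate_token_stream(lex, 100, cfg_bad), "burst_words")
})

test_that("priming designs respect the four sharing patterns", {
  cfg <- generator_config(seed = 11, m = 120, tonal = TRUE)
  lex <- generate_lexicon(cfg)
  pairs <- generate_priming_design(lex, 10, seed = 11)
  expect_equal(nrow(pairs), 40L)
  seg_of <- function(id) {
    p <- parse_tonal_transcription(lex$form[match(id, lex$word_id)])
    paste(p$segments, collapse = "-")
  }
  tone_of <- function(id) {
    p <- parse_tonal_transcription(lex$form[match(id, lex$word_id)])
    paste(p$tone, collapse = "")
  }
  st <- pairs[pairs$condition == "ST", ]
  expect_true(all(st$prime == st$target))
  s_ <- pairs[pairs$condition == "S", ]
  expect_true(all(mapply(function(p, t) seg_of(p) == seg_of(t) &&
                           tone_of(p) != tone_of(t), s_$prime, s_$target)))
  t_ <- pairs[pairs$condition == "T", ]
  expect_true(all(mapply(function(p, t) tone_of(p) == tone_of(t) &&
                           seg_of(p) != seg_of(t), t_$prime, t_$target)))
  ur <- pairs[pairs$condition == "UR", ]
  expect_true(all(mapply(function(p, t) tone_of(p) != tone_of(t) &&
                           seg_of(p) != seg_of(t), ur$prime, ur$target)))
})

test_that("an impoverished tonal lexicon fails with the condition named", {
  # all words share one tone pattern: no S pairs (same segments, new tone)
  lex <- lexicon(paste0("w", 1:4),
                 c("ba1bo1", "du1ka1", "ke1li1", "ma1mi1"),
                 rep(1L, 4))
  expect_error(generate_priming_design(lex, 2, seed = 1), "condition S")
})
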