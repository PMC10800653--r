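#' Configuration for the synthetic lexicon generator
#'
#' Bundles the parameters of the synthetic data generator emulating the
#' statistical structure of real lexical resources: Zipfian token
#' frequencies, high-dimensional real-valued semantic vectors (optionally
#' produced by a planted linear map from form cues plus Gaussian noise),
#' homophones, and token streams whose per-word frequency drifts over time.
#' All generators are pure functions of (config, seed).
#'
#' @param seed Integer master seed; sub-generators derive small offsets.
#' @param m Number of words.
#' @param alphabet Character vector of form symbols (plain scheme).
#' @param length_range Integer vector `c(min, max)` of form lengths.
#' @param zipf_exponent Zipf exponent a: the rank-i word has frequency
#'   proportional to `i^-a` (deterministic, rounded, floored at 1).
#' @param f_max Frequency of the rank-1 word.
#' @param q Semantic dimension.
#' @param semantic_model `"planted_linear"` (semantics are a linear image
#'   of the cue vectors plus noise; the ground-truth map is returned for
#'   recovery tests) or `"gaussian"` (i.i.d. standard normal rows).
#' @param noise_sd Noise standard deviation for `planted_linear`.
#' @param homophone_pairs Number of id pairs given identical forms.
#' @param schedule Token stream schedule: `"stationary"` (i.i.d. draws
#'   proportional to frequency) or `"early_burst"`/`"late_burst"`, where
#'   the designated `burst_words` have all their tokens concentrated in the
#'   first/last `burst_fraction` of the stream.
#' @param burst_fraction Fraction of the stream holding burst tokens.
#' @param burst_words Character vector of word ids subject to the burst
#'   schedule (required for burst schedules).
#' @param tonal If `TRUE`, forms are tonal transcriptions (syllable strings
#'   with tone digits) suitable for the `tonal_union` cue scheme and for
#'   [generate_priming_design()].
#' @param syllable_pool Pool of syllable segment strings for tonal forms.
#' @param tones Tone digits in use, default `1:4`.
#' @param syllables_per_word Syllables per tonal form, default 2.
#' @param n_tone_patterns Size of the tone-pattern pool; keeping it small
#'   guarantees tone-sharing (T-condition) pairs exist.
#' @return A list of class `ldl_config`.
#' @export
generator_config <- function(seed = 1L,
                             m = 500L,
                             alphabet = letters[1:6],
                             length_range = c(3L, 7L),
                             zipf_exponent = 1,
                             f_max = 10000L,
                             q = 50L,
                             semantic_model = c("planted_linear", "gaussian"),
                             noise_sd = 4,
                             homophone_pairs = 0L,
                             schedule = c("stationary", "early_burst",
                                          "late_burst"),
                             burst_fraction = 0.1,
                             burst_words = NULL,
                             tonal = FALSE,
                             syllable_pool = c("ba", "bo", "chun", "du", "ka",
                                               "ke", "li", "liao", "lu", "ma",
                                               "mi", "nu", "po", "su", "ta",
                                               "ti", "tong", "wa", "wen",
                                               "yu"),
                             tones = 1:4,
                             syllables_per_word = 2L,
                             n_tone_patterns = 6L) {
  semantic_model <- match.arg(semantic_model)
  schedule <- match.arg(schedule)
  stopifnot(m >= 1, length(alphabet) >= 2, length_range[1] >= 1,
            length_range[2] >= length_range[1], zipf_exponent >= 0,
            f_max >= 1, q >= 1, noise_sd >= 0, homophone_pairs >= 0,
            burst_fraction > 0, burst_fraction < 1,
            syllables_per_word >= 1, n_tone_patterns >= 1)
  if (2 * homophone_pairs > m) stop("too many homophone pairs for m")
  structure(list(seed = as.integer(seed), m = as.integer(m),
                 alphabet = alphabet, length_range = as.integer(length_range),
                 zipf_exponent = zipf_exponent, f_max = as.integer(f_max),
                 q = as.integer(q), semantic_model = semantic_model,
                 noise_sd = noise_sd,
                 homophone_pairs = as.integer(homophone_pairs),
                 schedule = schedule, burst_fraction = burst_fraction,
                 burst_words = burst_words, tonal = isTRUE(tonal),
                 syllable_pool = syllable_pool, tones = tones,
                 syllables_per_word = as.integer(syllables_per_word),
                 n_tone_patterns = as.integer(n_tone_patterns)),
            class = "ldl_config")
}

#' Generate a synthetic lexicon with Zipfian frequencies
#'
#' Forms are unique random symbol strings (or tonal transcriptions when
#' `config$tonal`); the rank-i word receives the deterministic frequency
#' `max(1, round(f_max * i^-a))`, so frequencies are exactly reproducible.
#' If `homophone_pairs > 0`, that many entries at the bottom of the
#' frequency ranking have their forms overwritten with the forms of the
#' top-ranked entries, yielding distinct word ids with identical forms.
#'
#' @param config An `ldl_config` from [generator_config()].
#' @return An `ldl_lexicon` ordered by decreasing frequency, word ids
#'   `w0001, w0002, ...`.
#' @export
generate_lexicon <- function(config) {
  set.seed(config$seed)
  m <- config$m
  forms <- character(0)
  tries <- 0L
  while (length(forms) < m) {
    tries <- tries + 1L
    if (tries > 200L) {
      stop("cannot generate ", m, " unique forms from the configured space")
    }
    need <- m - length(forms)
    new <- if (config$tonal) random_tonal_forms(need * 2L, config)
           else random_plain_forms(need * 2L, config)
    forms <- unique(c(forms, new))
  }
  forms <- forms[seq_len(m)]
  ranks <- seq_len(m)
  freq <- pmax(1L, as.integer(round(config$f_max * ranks^(-config$zipf_exponent))))
  h <- config$homophone_pairs
  if (h > 0) {
    forms[(m - h + 1):m] <- forms[seq_len(h)]
  }
  lexicon(word_id = sprintf("w%04d", ranks), form = forms, frequency = freq)
}

random_plain_forms <- function(n, config) {
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(config$alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

random_tonal_forms <- function(n, config) {
  k <- config$syllables_per_word
  # tone-pattern pool kept small so tone sharing across words is common
  all_pat <- expand.grid(rep(list(config$tones), k))
  pat_pool <- all_pat[seq_len(min(nrow(all_pat), config$n_tone_patterns)), ,
                      drop = FALSE]
  vapply(seq_len(n), function(i) {
    syl <- sample(config$syllable_pool, k, replace = TRUE)
    pat <- pat_pool[sample.int(nrow(pat_pool), 1), ]
    paste(paste0(syl, unlist(pat)), collapse = "")
  }, character(1))
}

#' Generate a semantic matrix for a lexicon
#'
#' Under `planted_linear`, a ground-truth mapping `F*` with i.i.d. standard
#' normal entries is drawn and `S = C F* + e`, `e ~ N(0, noise_sd^2)`; `F*`
#' is attached as the `"F_star"` attribute for parameter-recovery tests.
#' Under `gaussian`, rows are i.i.d. standard normal (embedding-like,
#' unrelated to form).
#'
#' @param lex The lexicon (supplies row order and ids).
#' @param C Cue matrix; required for `planted_linear`.
#' @param config An `ldl_config`.
#' @return Numeric m x q matrix with word ids as row names; for
#'   `planted_linear`, attribute `"F_star"` holds the generating map.
#' @export
generate_semantics <- function(lex, C = NULL, config) {
  set.seed(config$seed + 1L)
  m <- nrow(lex)
  q <- config$q
  if (config$semantic_model == "gaussian") {
    S <- matrix(stats::rnorm(m * q), m, q)
  } else {
    if (is.null(C)) stop("planted_linear requires the cue matrix C")
    Fstar <- matrix(stats::rnorm(ncol(C) * q), ncol(C), q)
    S <- as.matrix(C %*% Fstar)
    if (config$noise_sd > 0) {
      S <- S + matrix(stats::rnorm(m * q, sd = config$noise_sd), m, q)
    }
    attr(S, "F_star") <- Fstar
  }
  rownames(S) <- lex$word_id
  S
}

#' Generate an ordered token stream
#'
#' Token identities are multinomial draws proportional to lexicon
#' frequency. Each token then receives a timestamp: uniform over the whole
#' stream for ordinary words, uniform over the first (`early_burst`) or
#' last (`late_burst`) `burst_fraction` of the stream for the designated
#' `burst_words`; the stream is the timestamp-sorted token sequence. Under
#' the stationary schedule per-word frequencies therefore drift only by
#' sampling noise, while burst words' occurrences are concentrated by
#' construction.
#'
#' @param lex The lexicon.
#' @param T_events Stream length (number of tokens); at least m draws are
#'   recommended.
#' @param config An `ldl_config` (supplies schedule, burst parameters and
#'   seed).
#' @return Character vector of word ids of length `T_events`.
#' @export
generate_token_stream <- function(lex, T_events, config) {
  if (T_events < 1) stop("T_events must be >= 1")
  set.seed(config$seed + 2L)
  m <- nrow(lex)
  prob <- lex$frequency / sum(lex$frequency)
  tok <- sample.int(m, T_events, replace = TRUE, prob = prob)
  if (config$schedule == "stationary") {
    return(lex$word_id[tok])
  }
  if (is.null(config$burst_words)) {
    stop("burst schedules require config$burst_words")
  }
  bw <- match(config$burst_words, lex$word_id)
  if (anyNA(bw)) stop("burst_words contains unknown id(s)")
  hit <- tok %in% bw
  window <- max(1L, floor(config$burst_fraction * T_events))
  win_pos <- if (config$schedule == "early_burst") seq_len(window)
             else seq.int(T_events - window + 1L, T_events)
  n_burst <- sum(hit)
  if (n_burst > window) {
    stop("burst window of ", window, " positions cannot hold ", n_burst,
         " burst tokens; increase burst_fraction or T_events")
  }
  out <- integer(T_events)
  burst_at <- sort(sample(win_pos, n_burst))
  out[burst_at] <- tok[hit]
  out[-burst_at] <- tok[!hit]
  lex$word_id[out]
}

#' Generate a prime-target priming design over a tonal lexicon
#'
#' Emits `n_per_condition` prime-target pairs per condition following the
#' standard auditory-priming design for a tone language: `ST` prime and
#' target are the same word; `S` prime shares the full segment string but
#' differs in tone pattern; `T` prime shares the tone pattern but has a
#' different segment string; `UR` prime shares neither. Pairs are sampled
#' uniformly among the qualifying combinations.
#'
#' @param lex A lexicon whose forms are tonal transcriptions.
#' @param n_per_condition Pairs per condition.
#' @param seed Sampling seed.
#' @return Data frame with columns `prime`, `target`, `condition`.
#' @export
generate_priming_design <- function(lex, n_per_condition = 20, seed = 1L) {
  set.seed(seed)
  parsed <- lapply(lex$form, function(f) {
    tryCatch(parse_tonal_transcription(f),
             error = function(e) stop("lexicon form '", f,
                                      "' is not a tonal transcription",
                                      call. = FALSE))
  })
  segs <- vapply(parsed, function(p) paste(p$segments, collapse = "-"),
                 character(1))
  tones <- vapply(parsed, function(p) paste(p$tone, collapse = ""),
                  character(1))
  m <- nrow(lex)
  pick_pairs <- function(qualify, label) {
    # qualify(t): candidate prime indices for target t
    out <- matrix(NA_integer_, 0, 2)
    targets <- sample.int(m)
    for (t in targets) {
      cand <- qualify(t)
      if (length(cand) == 0) next
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      out <- rbind(out, c(p, t))
      if (nrow(out) == n_per_condition) break
    }
    if (nrow(out) < n_per_condition) {
      stop("insufficient words to satisfy condition ", label)
    }
    data.frame(prime = lex$word_id[out[, 1]], target = lex$word_id[out[, 2]],
               condition = label, stringsAsFactors = FALSE)
  }
  st <- pick_pairs(function(t) t, "ST")
  s_ <- pick_pairs(function(t) {
    which(segs == segs[t] & tones != tones[t])
  }, "S")
  t_ <- pick_pairs(function(t) {
    which(tones == tones[t] & segs != segs[t])
  }, "T")
  ur <- pick_pairs(function(t) {
    which(tones != tones[t] & segs != segs[t])
  }, "UR")
  rbind(st, s_, t_, ur)
}
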