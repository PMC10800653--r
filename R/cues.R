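#' Extract overlapping n-gram cues from a word form
#'
#' Pads the form with one boundary marker on each side and emits all
#' overlapping n-grams left to right. Because cues code presence/absence,
#' repeated grams are collapsed, keeping first occurrence order: the form
#' `"aap"` with bigrams yields `#a, aa, ap, p#`.
#'
#' @param form Non-empty symbol string.
#' @param n Gram order, integer >= 1.
#' @param boundary Single boundary marker character, default `"#"`; it must
#'   not occur inside `form`.
#' @return Character vector of unique cues in first-occurrence order. A form
#'   shorter than `n - 2` after padding yields `character(0)`.
#' @export
extract_ngrams <- function(form, n = 2, boundary = "#") {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("n must be an integer >= 1")
  }
  if (!is.character(form) || length(form) != 1 || !nzchar(form)) {
    stop("form must be a non-empty string")
  }
  if (nchar(boundary) != 1) stop("boundary must be a single character")
  if (grepl(boundary, form, fixed = TRUE)) {
    stop("boundary marker '", boundary, "' occurs inside form '", form, "'")
  }
  padded <- paste0(boundary, form, boundary)
  L <- nchar(padded)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1)
  unique(substring(padded, starts, starts + n - 1))
}

#' Parse a tonal transcription into syllables
#'
#' A transcription is a concatenation of syllables, each consisting of
#' letters followed by one tone digit 1-5, e.g. `"wen4ti2"`.
#'
#' @param transcription The transcription string.
#' @return A data frame with columns `segments` (character) and `tone`
#'   (integer), one row per syllable in order.
#' @export
parse_tonal_transcription <- function(transcription) {
  if (!is.character(transcription) || length(transcription) != 1 ||
      !nzchar(transcription)) {
    stop("empty transcription")
  }
  m <- gregexpr("[A-Za-z]+[1-5]", transcription)[[1]]
  if (m[1] == -1) stop("malformed transcription '", transcription, "'")
  syl <- regmatches(transcription, gregexpr("[A-Za-z]+[1-5]", transcription))[[1]]
  if (paste(syl, collapse = "") != transcription) {
    stop("malformed transcription '", transcription,
         "': expected letters followed by a tone digit per syllable")
  }
  data.frame(
    segments = sub("[1-5]$", "", syl),
    tone = as.integer(sub("^[A-Za-z]+", "", syl)),
    stringsAsFactors = FALSE
  )
}

#' Mandarin-style union cues: segmental, tonal and tone-segment triphones
#'
#' Builds the union of three cue sets from a tonal transcription such as
#' `"wen4ti2"`: (a) segmental triphones over the concatenated segments with
#' boundary markers (`#we, wen, ent, nti, ti#`); (b) tritones over the tone
#' digit sequence (`#42, 42#`); and (c) tone-segment triphones in which each
#' vowel carries its syllable's tone digit as a suffix, the compound
#' vowel+digit counting as one symbol position (`#we4, we4n, e4nt, nti2,
#' ti2#`).
#'
#' @param transcription Tonal transcription parseable by
#'   [parse_tonal_transcription()].
#' @param vowels Character vector of vowel symbols that carry tone marks.
#' @param boundary Boundary marker, default `"#"`.
#' @return Character vector: the deduplicated union of the three cue sets in
#'   first-occurrence order (segmental, then tonal, then tone-segment).
#' @export
tonal_union_cues <- function(transcription, vowels, boundary = "#") {
  if (missing(vowels) || length(vowels) == 0) {
    stop("vowels must be a non-empty symbol set")
  }
  syl <- parse_tonal_transcription(transcription)
  segcat <- paste(syl$segments, collapse = "")
  segmental <- extract_ngrams(segcat, 3, boundary)
  tonal <- extract_ngrams(paste(syl$tone, collapse = ""), 3, boundary)
  # symbol sequence with tone-marked vowels; each vowel+digit is one position
  symbols <- boundary
  for (i in seq_len(nrow(syl))) {
    chars <- strsplit(syl$segments[i], "")[[1]]
    marked <- ifelse(chars %in% vowels, paste0(chars, syl$tone[i]), chars)
    symbols <- c(symbols, marked)
  }
  symbols <- c(symbols, boundary)
  ts <- character(0)
  if (length(symbols) >= 3) {
    ts <- vapply(seq_len(length(symbols) - 2), function(j) {
      paste(symbols[j:(j + 2)], collapse = "")
    }, character(1))
  }
  unique(c(segmental, tonal, ts))
}

cues_for_form <- function(form, n, scheme, vowels, boundary) {
  switch(scheme,
    plain = extract_ngrams(form, n, boundary),
    tonal_union = tonal_union_cues(form, vowels, boundary),
    stop("unknown cue scheme '", scheme, "'")
  )
}

#' Build a binary cue matrix over a lexicon
#'
#' The cue inventory is the union of each form's cues, in first-occurrence
#' order over the lexicon; row i of the matrix has a 1 exactly at word i's
#' cues. Identical forms (homophones) yield identical rows.
#'
#' @param lex An `ldl_lexicon`.
#' @param n Gram order for the `plain` scheme (ignored for `tonal_union`,
#'   which always uses triphones/tritones).
#' @param scheme `"plain"` overlapping n-grams, or `"tonal_union"`, the
#'   union of segmental, tonal and tone-segment cues for tonal
#'   transcriptions.
#' @param vowels Required for `tonal_union`: vowel symbols carrying tone
#'   marks.
#' @param boundary Boundary marker, default `"#"`.
#' @return A sparse binary matrix (`Matrix::dgCMatrix`) of size m x r with
#'   word ids as row names and the cue inventory as column names.
#' @export
build_cue_matrix <- function(lex, n = 2, scheme = c("plain", "tonal_union"),
                             vowels = NULL, boundary = "#") {
  scheme <- match.arg(scheme)
  if (scheme == "tonal_union" && (is.null(vowels) || length(vowels) == 0)) {
    stop("scheme 'tonal_union' requires a vowel set")
  }
  cue_lists <- vector("list", nrow(lex))
  for (i in seq_len(nrow(lex))) {
    cl <- tryCatch(
      cues_for_form(lex$form[i], n, scheme, vowels, boundary),
      error = function(e) {
        stop("cue extraction failed for word '", lex$word_id[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
    if (length(cl) == 0) {
      stop("no cues extracted for word '", lex$word_id[i], "'")
    }
    cue_lists[[i]] <- cl
  }
  inventory <- unique(unlist(cue_lists, use.names = FALSE))
  ii <- rep.int(seq_len(nrow(lex)), lengths(cue_lists))
  jj <- match(unlist(cue_lists, use.names = FALSE), inventory)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(nrow(lex), length(inventory)),
                            dimnames = list(lex$word_id, inventory))
  methods::as(C, "CsparseMatrix")
}

#' Cue rows for held-out forms against a frozen inventory
#'
#' Maps new forms onto an existing cue inventory; cues unseen at inventory
#' construction time are ignored, so a row may be all-zero (flagged by a
#' warning and the `"no_cue"` attribute).
#'
#' @param forms Character vector of forms.
#' @param inventory Character vector of cue strings (e.g.
#'   `colnames(build_cue_matrix(...))`).
#' @inheritParams build_cue_matrix
#' @return Sparse binary matrix `length(forms)` x `length(inventory)`.
#' @export
cue_rows <- function(forms, inventory, n = 2,
                     scheme = c("plain", "tonal_union"), vowels = NULL,
                     boundary = "#") {
  scheme <- match.arg(scheme)
  cue_lists <- lapply(forms, function(f) {
    intersect(cues_for_form(f, n, scheme, vowels, boundary), inventory)
  })
  empty <- lengths(cue_lists) == 0
  if (any(empty)) {
    warning(sum(empty), " form(s) share no cue with the inventory")
  }
  ii <- rep.int(seq_along(forms), lengths(cue_lists))
  jj <- match(unlist(cue_lists, use.names = FALSE), inventory)
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(forms), length(inventory)),
                            dimnames = list(forms, inventory))
  C <- methods::as(C, "CsparseMatrix")
  attr(C, "no_cue") <- which(empty)
  C
}
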