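#' Read a lexicon from a tab-separated file
#'
#' A lexicon is the universe of words over which all matrices are row-indexed:
#' one row per word, with a unique identifier, the form used for cue
#' extraction, and a non-negative token frequency. File row order is preserved
#' and defines the row index of every derived matrix.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param column_map Optional named character vector mapping the canonical
#'   column names (`word_id`, `form`, `frequency`, `condition`) to the names
#'   actually used in the file, e.g. `c(word_id = "Word", form = "DISC")`.
#' @return A data frame of class `ldl_lexicon` with columns `word_id`,
#'   `form`, `frequency` (integer) and, if present in the file, `condition`.
#' @details Words with a missing frequency are retained with frequency 0 and
#'   a warning; a frequency of 0 is legal (such words receive zero weight in
#'   frequency-informed learning but remain evaluable). Duplicated
#'   `word_id`s and negative frequencies are errors.
#' @seealso [write_lexicon()], [build_cue_matrix()]
#' @export
read_lexicon <- function(path, column_map = NULL) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(tbl))
      if (is.na(j)) {
        stop("column_map: column '", column_map[[canon]], "' not in file")
      }
      names(tbl)[j] <- canon
    }
  }
  required <- c("word_id", "form", "frequency")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("lexicon file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tbl) == 0) stop("empty lexicon")
  lex <- data.frame(word_id = tbl$word_id, form = tbl$form,
                    stringsAsFactors = FALSE)
  freq_raw <- tbl$frequency
  freq <- suppressWarnings(as.numeric(freq_raw))
  blank <- is.na(freq_raw) | !nzchar(trimws(freq_raw))
  if (any(blank)) {
    warning(sum(blank), " word(s) missing a frequency; set to 0: ",
            paste(utils::head(lex$word_id[blank], 5), collapse = ", "))
    freq[blank] <- 0
  }
  if (anyNA(freq)) {
    stop("unparseable frequency for word(s): ",
         paste(lex$word_id[is.na(freq)], collapse = ", "))
  }
  if (any(freq < 0)) {
    stop("negative frequency for word(s): ",
         paste(lex$word_id[freq < 0], collapse = ", "))
  }
  lex$frequency <- as.integer(round(freq))
  if ("condition" %in% names(tbl)) lex$condition <- tbl$condition
  validate_lexicon(lex)
}

#' Construct a lexicon from vectors
#'
#' @param word_id Character vector of unique word identifiers.
#' @param form Character vector of word forms (non-empty).
#' @param frequency Non-negative integer token counts (default all 1).
#' @param condition Optional character vector of condition labels.
#' @return An `ldl_lexicon` data frame.
#' @export
lexicon <- function(word_id, form, frequency = rep(1L, length(word_id)),
                    condition = NULL) {
  lex <- data.frame(word_id = as.character(word_id),
                    form = as.character(form),
                    frequency = as.integer(frequency),
                    stringsAsFactors = FALSE)
  if (!is.null(condition)) lex$condition <- as.character(condition)
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  if (nrow(lex) < 1) stop("empty lexicon")
  dup <- unique(lex$word_id[duplicated(lex$word_id)])
  if (length(dup) > 0) {
    stop("duplicate word_id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(lex$form))) {
    stop("empty form for word(s): ",
         paste(lex$word_id[!nzchar(lex$form)], collapse = ", "))
  }
  if (any(lex$frequency < 0)) stop("negative frequency")
  class(lex) <- c("ldl_lexicon", "data.frame")
  lex
}

#' Write a lexicon to a tab-separated file
#'
#' @param lex An `ldl_lexicon` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(as.data.frame(lex), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an embedding table aligned to a lexicon
#'
#' Reads a tab-separated table whose first column is `word_id` and whose
#' remaining columns are the numeric embedding dimensions, and returns the
#' semantic matrix `S` in lexicon row order.
#'
#' @param path Path to the embedding file.
#' @param lex The `ldl_lexicon` to align to.
#' @param mode What to do when a lexicon word has no embedding: `"strict"`
#'   (default) raises an error naming the words; `"drop"` returns the matrix
#'   for the covered words only (in lexicon order) and records the dropped
#'   ids in the `"dropped"` attribute. Use [align_lexicon()] to subset the
#'   lexicon accordingly.
#' @return A numeric matrix with one row per (covered) lexicon word; row
#'   names are word ids. Attribute `"dropped"` lists uncovered word ids.
#' @export
read_embeddings <- function(path, lex, mode = c("strict", "drop")) {
  mode <- match.arg(mode)
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tbl) < 2) stop("embedding table needs word_id plus >= 1 dimension")
  ids <- as.character(tbl[[1]])
  num <- tbl[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(v))
      if (anyNA(vv) && !anyNA(v)) {
        stop("non-numeric value in embedding column '", names(num)[j], "'")
      }
      v <- vv
    }
    num[[j]] <- v
  }
  M <- as.matrix(num)
  if (anyNA(M) || any(!is.finite(M))) stop("non-finite value in embeddings")
  rownames(M) <- ids
  missing <- setdiff(lex$word_id, ids)
  if (mode == "strict" && length(missing) > 0) {
    stop("no embedding for word(s): ", paste(missing, collapse = ", "))
  }
  keep <- lex$word_id[lex$word_id %in% ids]
  S <- M[keep, , drop = FALSE]
  attr(S, "dropped") <- missing
  S
}

#' Subset a lexicon to the rows of an aligned matrix
#'
#' @param lex An `ldl_lexicon`.
#' @param ids Character vector of word ids to keep (e.g. `rownames(S)` after
#'   [read_embeddings()] in drop mode); lexicon order is preserved.
#' @return The reduced `ldl_lexicon`.
#' @export
align_lexicon <- function(lex, ids) {
  validate_lexicon(lex[lex$word_id %in% ids, , drop = FALSE])
}

#' Write an embedding matrix to a tab-separated file
#'
#' @param S Numeric matrix with word ids as row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(S, path) {
  df <- data.frame(word_id = rownames(S), S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("word_id", paste0("V", seq_len(ncol(S))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an ordered token stream
#'
#' One word id per line; line order is learning order.
#'
#' @param path Path to the stream file.
#' @param lex Lexicon against which ids must resolve.
#' @return Character vector of word ids.
#' @export
read_token_stream <- function(path, lex) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (length(ids) < 1) stop("empty token stream")
  unknown <- setdiff(unique(ids), lex$word_id)
  if (length(unknown) > 0) {
    stop("token stream contains unknown id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ids
}

#' Write an ordered token stream
#' @param stream Character vector of word ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_token_stream <- function(stream, path) {
  writeLines(stream, path)
  invisible(path)
}

#' Write a per-word measure table
#'
#' @param table A data frame of per-word records (typically from
#'   [ldl_measures()]), one row per word, sharing a schema such as
#'   `word_id`, `frequency`, `target_correlation`, `correct_at_1`,
#'   `one_minus_r`.
#' @param path Output path; tab-separated with header. Numeric values
#'   round-trip through [read_measures()] to at least 12 significant digits.
#' @return Invisibly, `path`.
#' @export
write_measures <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-word measure table written by [write_measures()]
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_measures <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Serialize a sparse cue matrix
#'
#' Writes the binary cue matrix in MatrixMarket coordinate format together
#' with a sidecar table mapping column index to cue string and row index to
#' word id.
#'
#' @param C Sparse cue matrix from [build_cue_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.cues.tsv` and `<prefix>.words.tsv`.
#' @return Invisibly, `prefix`.
#' @export
write_cue_matrix <- function(C, prefix) {
  Matrix::writeMM(methods::as(C, "generalMatrix"), paste0(prefix, ".mtx"))
  utils::write.table(
    data.frame(index = seq_len(ncol(C)), cue = colnames(C)),
    paste0(prefix, ".cues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(index = seq_len(nrow(C)), word_id = rownames(C)),
    paste0(prefix, ".words.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a sparse cue matrix written by [write_cue_matrix()]
#' @param prefix Path prefix used at write time.
#' @return A sparse binary matrix with word and cue dimnames.
#' @export
read_cue_matrix <- function(prefix) {
  M <- Matrix::readMM(paste0(prefix, ".mtx"))
  M <- methods::as(1 * M, "CsparseMatrix")  # pattern/logical -> numeric
  cues <- utils::read.delim(paste0(prefix, ".cues.tsv"), sep = "\t",
                            quote = "", stringsAsFactors = FALSE)
  words <- utils::read.delim(paste0(prefix, ".words.tsv"), sep = "\t",
                             quote = "", stringsAsFactors = FALSE)
  dimnames(M) <- list(words$word_id, cues$cue)
  M
}

#' Write a dense mapping matrix
#'
#' @param F_mat Mapping matrix (e.g. from [solve_linear_mapping()]).
#' @param path Output path; tab-separated, first column holds row names.
#' @return Invisibly, `path`.
#' @export
write_mapping <- function(F_mat, path) {
  rn <- rownames(F_mat)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(F_mat)))
  df <- data.frame(row = rn, as.matrix(F_mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("row", paste0("V", seq_len(ncol(F_mat))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a dense mapping matrix written by [write_mapping()]
#' @param path Path to the file.
#' @return A numeric matrix with row names.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  colnames(M) <- NULL
  M
}
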