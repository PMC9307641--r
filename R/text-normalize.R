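#' Normalize free text for concept matching
#'
#' Lowercases, folds Unicode compatibility characters to ASCII where possible,
#' and collapses runs of whitespace to a single space. Runs that contain a
#' newline collapse to a single newline instead, so that line breaks remain
#' available as sentence boundaries for negation scoping. The returned offset
#' map gives, for every character of the normalized text, its 1-based position
#' in the original text, so matched spans can be projected back. The operation
#' is idempotent.
#'
#' @param text A single non-empty character string.
#' @return A list with `text` (normalized string) and `map` (integer vector,
#'   one original position per normalized character).
#' @export
#' @examples
#' normalize_text("Adeno-Carcinoma  of   colon")$text
normalize_text <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    abort("text must be a single non-empty string", class = "pathmil_validation_error")
  }
  folded <- iconv(text, from = "UTF-8", to = "ASCII//TRANSLIT")
  if (is.na(folded) || nchar(folded) != nchar(text)) folded <- text
  chars <- strsplit(tolower(folded), "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n)
  map <- integer(n)
  k <- 0L
  pending_ws <- FALSE
  pending_nl <- FALSE
  pending_at <- NA_integer_
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      pending_ws <- TRUE
      if (ch == "\n") pending_nl <- TRUE
      if (is.na(pending_at)) pending_at <- i
    } else {
      if (pending_ws && k > 0L) {
        k <- k + 1L
        out[k] <- if (pending_nl) "\n" else " "
        map[k] <- pending_at
      }
      pending_ws <- FALSE
      pending_nl <- FALSE
      pending_at <- NA_integer_
      k <- k + 1L
      out[k] <- ch
      map[k] <- i
    }
  }
  list(text = paste(out[seq_len(k)], collapse = ""), map = map[seq_len(k)])
}

# Tokenize normalized text. Tokens are maximal runs of characters that are
# neither whitespace nor separator punctuation; hyphens also split, so
# "high-grade" and "high grade" produce identical token streams. Spans are
# 1-based inclusive character positions into the normalized text.
tokenize_norm <- function(text) {
  if (!nzchar(text)) return(tibble(token = character(), start = integer(), end = integer()))
  m <- gregexpr("[^-\\s.,;:()!?\"']+", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(token = character(), start = integer(), end = integer()))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble(
    token = substring(text, starts, starts + lens - 1L),
    start = starts,
    end = starts + lens - 1L
  )
}

# Character positions of sentence boundaries in normalized text.
sentence_boundaries <- function(text) {
  m <- gregexpr("[.;\n]", text, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

has_boundary_between <- function(boundaries, from, to) {
  if (from > to) return(FALSE)
  any(boundaries > from & boundaries < to)
}
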