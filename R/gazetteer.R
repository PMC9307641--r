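#' Read a concept gazetteer
#'
#' The gazetteer is the flat concept table driving rule-based entity
#' recognition and linking: one row per ontology concept with a preferred
#' term, pipe-separated synonyms, an optional mapped annotation class, and a
#' `grade_sensitive` flag for concepts (like bare "dysplasia") whose class
#' depends on nearby grade adjectives. A small colon gazetteer is bundled with
#' the package.
#'
#' @param path Path to a TSV with columns `concept_id`, `preferred_term`,
#'   `synonyms` (pipe-separated, may be empty), `mapped_class` (empty = no
#'   class), `grade_sensitive` (0/1).
#' @return A tibble with list-column `synonyms` and logical `grade_sensitive`.
#' @export
read_gazetteer <- function(path = system.file("extdata", "colon_gazetteer.tsv",
                                              package = "pathmil")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("concept_id", "preferred_term", "synonyms", "mapped_class", "grade_sensitive")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Gazetteer is missing columns: ", paste(miss, collapse = ", ")),
          class = "pathmil_schema_error")
  }
  if (any(!nzchar(trimws(raw$preferred_term)))) {
    abort("Gazetteer preferred_term must be non-empty", class = "pathmil_schema_error")
  }
  mapped <- raw$mapped_class
  mapped[is.na(mapped) | !nzchar(trimws(mapped))] <- NA_character_
  assert_known_classes(mapped[!is.na(mapped)])
  tibble(
    concept_id = raw$concept_id,
    preferred_term = raw$preferred_term,
    synonyms = map(raw$synonyms, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) return(character())
      unique(trimws(strsplit(s, "|", fixed = TRUE)[[1]]))
    }),
    mapped_class = mapped,
    grade_sensitive = !is.na(raw$grade_sensitive) & raw$grade_sensitive == "1"
  )
}

# Expand a gazetteer into one row per (normalized term, concept): the lookup
# table the recognizer and linker share. `key` is the space-joined token form,
# so hyphen/space variants of a term collide onto one key by construction.
gazetteer_terms <- function(gazetteer) {
  rows <- pmap(list(gazetteer$concept_id, gazetteer$preferred_term, gazetteer$synonyms),
               function(cid, pref, syn) {
                 terms <- unique(c(pref, syn))
                 tibble(concept_id = cid, term = terms)
               })
  tab <- bind_rows(rows)
  tab$key <- map_chr(tab$term, function(tm) {
    toks <- tokenize_norm(normalize_text(tm)$text)
    paste(toks$token, collapse = " ")
  })
  tab$n_tokens <- map_int(strsplit(tab$key, " ", fixed = TRUE), length)
  distinct(tab, .data$concept_id, .data$key, .keep_all = TRUE)
}
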