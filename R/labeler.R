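#' Configuration for the report labeler
#'
#' Houses the knobs of the rule-based concept extraction pipeline. Negation
#' detection is on by default; disabling it (`negation_enabled = FALSE`)
#' reproduces the documented failure mode of rule-based report labelers on
#' phrases such as "NO high-grade dysplasia". `context_rules_enabled` governs
#' curated suppression rules, e.g. hyperplasia mentioned only to describe a
#' resection margin.
#'
#' @param similarity_threshold Minimal normalized Levenshtein ratio in (0, 1]
#'   for fuzzy linking; default 0.85.
#' @param negation_enabled Drop negated mentions; default `TRUE`.
#' @param negation_window Number of tokens before a mention scanned for a
#'   negation cue; default 5.
#' @param unspecified_grade_class Class assigned to bare grade-sensitive
#'   mentions ("dysplasia" with no grade adjective); default low-grade
#'   dysplasia, the most prevalent dysplasia grade in colon screening.
#' @param context_rules_enabled Apply curated context suppression rules;
#'   default `TRUE`.
#' @return A list of class `pathmil_labeler_config`.
#' @export
labeler_config <- function(similarity_threshold = 0.85,
                           negation_enabled = TRUE,
                           negation_window = 5L,
                           unspecified_grade_class = "low_grade_dysplasia",
                           context_rules_enabled = TRUE) {
  if (!is.numeric(similarity_threshold) || similarity_threshold <= 0 ||
      similarity_threshold > 1) {
    abort("similarity_threshold must be in (0, 1]", class = "pathmil_validation_error")
  }
  if (negation_window < 1) {
    abort("negation_window must be >= 1", class = "pathmil_validation_error")
  }
  assert_known_classes(unspecified_grade_class)
  structure(list(
    similarity_threshold = similarity_threshold,
    negation_enabled = isTRUE(negation_enabled),
    negation_window = as.integer(negation_window),
    unspecified_grade_class = unspecified_grade_class,
    fallback_class = "normal",
    context_rules_enabled = isTRUE(context_rules_enabled)
  ), class = "pathmil_labeler_config")
}

negation_cues <- function() {
  c("no", "not", "without", "absence of", "free of", "negative for")
}

#' Recognize concept mentions in normalized text
#'
#' Greedy longest-match, left-to-right dictionary scan over token n-grams of
#' the normalized gazetteer terms. Matches never overlap and never span a
#' sentence boundary; each mention carries every concept whose term matched
#' that surface. Token matching splits hyphens, so "high-grade dysplasia" and
#' "high grade dysplasia" hit the same term.
#'
#' @param text Normalized text (the `text` element of [normalize_text()]), or
#'   raw text which is normalized on the fly.
#' @param gazetteer Gazetteer tibble from [read_gazetteer()].
#' @return Tibble with one row per mention: `start`, `end` (1-based inclusive
#'   character span in the normalized text), `surface`, and list-column
#'   `candidate_ids`.
#' @export
recognize_mentions <- function(text, gazetteer) {
  if (is.list(text)) text <- text$text
  if (nrow(gazetteer) == 0) {
    abort("gazetteer must be non-empty", class = "pathmil_validation_error")
  }
  terms <- gazetteer_terms(gazetteer)
  dict <- split(terms$concept_id, terms$key)
  max_len <- max(terms$n_tokens)
  toks <- tokenize_norm(text)
  n <- nrow(toks)
  bounds <- sentence_boundaries(text)
  out <- list()
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      if (has_boundary_between(bounds, toks$end[i], toks$start[j])) next
      key <- paste(toks$token[i:j], collapse = " ")
      ids <- dict[[key]]
      if (!is.null(ids)) {
        out[[length(out) + 1L]] <- tibble(
          start = toks$start[i], end = toks$end[j],
          surface = substring(text, toks$start[i], toks$end[j]),
          candidate_ids = list(sort(unique(ids)))
        )
        hit_len <- len
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), surface = character(),
                  candidate_ids = list()))
  }
  bind_rows(out)
}

# Curated surface -> concept rewrite patterns tried between exact and
# similarity matching. A reconstruction of typical report shorthand; versioned
# with the package, not learned.
adhoc_patterns <- function() {
  list(
    list(pattern = "^adeno ?carcinomas?$", key = "adenocarcinoma"),
    list(pattern = "^adenoca$", key = "adenocarcinoma"),
    list(pattern = "^carcinomas$", key = "carcinoma"),
    list(pattern = "^(severe|marked) (glandular )?dysplasias?$", key = "severe dysplasia"),
    list(pattern = "^(mild|moderate|slight) (glandular )?dysplasias?$", key = "mild dysplasia"),
    list(pattern = "^dysplasias$", key = "dysplasia")
  )
}

#' Link a mention surface to a gazetteer concept
#'
#' Linking proceeds in three stages: exact normalized-string equality to a
#' term or synonym (`method = "exact"`, score 1), curated ad-hoc rewrite
#' patterns (`method = "adhoc_rule"`), and finally best normalized
#' edit-distance ratio over all terms (`method = "similarity"`), accepted only
#' at or above the configured threshold. Ties break by higher score, then by
#' lexicographically smallest concept id, so linking is deterministic.
#'
#' @param surface A mention surface string (normalized text slice) or one row
#'   of the tibble returned by [recognize_mentions()].
#' @param gazetteer Gazetteer tibble.
#' @param config [labeler_config()].
#' @return A one-row tibble (`concept_id`, `method`, `score`) or `NULL` when
#'   no link clears the threshold.
#' @export
link_mention <- function(surface, gazetteer, config = labeler_config()) {
  if (is.data.frame(surface)) surface <- surface$surface[[1]]
  key <- paste(tokenize_norm(normalize_text(surface)$text)$token, collapse = " ")
  terms <- gazetteer_terms(gazetteer)
  exact <- terms$concept_id[terms$key == key]
  if (length(exact) > 0) {
    return(tibble(concept_id = min(sort(exact)), method = "exact", score = 1.0))
  }
  for (rule in adhoc_patterns()) {
    if (grepl(rule$pattern, key, perl = TRUE)) {
      hit <- terms$concept_id[terms$key == rule$key]
      if (length(hit) > 0) {
        return(tibble(concept_id = min(sort(hit)), method = "adhoc_rule", score = 1.0))
      }
    }
  }
  d <- as.vector(adist(key, terms$key))
  ratio <- 1 - d / pmax(nchar(key), nchar(terms$key))
  best <- max(ratio)
  if (best >= config$similarity_threshold) {
    cand <- sort(terms$concept_id[ratio == best])
    return(tibble(concept_id = cand[1], method = "similarity", score = best))
  }
  NULL
}

#' Detect whether a mention is negated
#'
#' A mention is negated iff a negation cue ("no", "not", "without", "absence
#' of", "free of", "negative for") starts within `negation_window` tokens
#' before the mention with no intervening sentence boundary (".", ";" or a
#' newline).
#'
#' @param text Normalized text (string or [normalize_text()] result).
#' @param mention One row of [recognize_mentions()] output (or any list with
#'   `start`).
#' @param config [labeler_config()].
#' @return Logical scalar.
#' @export
detect_negation <- function(text, mention, config = labeler_config()) {
  if (is.list(text) && !is.data.frame(text)) text <- text$text
  start <- if (is.data.frame(mention)) mention$start[[1]] else mention$start
  toks <- tokenize_norm(text)
  bounds <- sentence_boundaries(text)
  before <- which(toks$end < start)
  if (length(before) == 0) return(FALSE)
  window_idx <- tail(before, config$negation_window)
  cues <- negation_cues()
  for (i in window_idx) {
    for (cue in cues) {
      cue_toks <- strsplit(cue, " ", fixed = TRUE)[[1]]
      j <- i + length(cue_toks) - 1L
      if (j > max(before)) next
      if (identical(toks$token[i:j], cue_toks) &&
          !has_boundary_between(bounds, toks$end[j], start)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

grade_adjectives <- function() {
  list(high = c("severe", "marked"), low = c("mild", "moderate", "slight"))
}

# Resolve the grade of a grade-sensitive mention from nearby adjectives:
# {severe, marked, high( grade)} -> high; {mild, moderate, slight, low} -> low;
# otherwise NA (caller applies the configured default).
resolve_grade <- function(text, mention_start, lookback = 4L) {
  toks <- tokenize_norm(text)
  before <- which(toks$end < mention_start)
  idx <- tail(before, lookback)
  if (length(idx) == 0) return(NA_character_)
  window <- toks$token[idx]
  adj <- grade_adjectives()
  if (any(window %in% adj$high) || "high" %in% window) return("high")
  if (any(window %in% adj$low) || "low" %in% window) return("low")
  NA_character_
}

# Context suppression: trigger phrase -> class whose mentions within `window`
# tokens after the trigger are non-diagnostic (e.g. hyperplasia describing a
# resection margin).
context_rules <- function() {
  list(list(trigger = "margin of resection", alt_trigger = "resection margin",
            class = "hyperplastic_polyp", window = 5L))
}

apply_context_rules <- function(text, linked) {
  if (nrow(linked) == 0) return(logical(0))
  toks <- tokenize_norm(text)
  suppressed <- rep(FALSE, nrow(linked))
  for (rule in context_rules()) {
    for (trig in c(rule$trigger, rule$alt_trigger)) {
      trig_toks <- strsplit(trig, " ", fixed = TRUE)[[1]]
      nt <- length(trig_toks)
      if (nrow(toks) < nt) next
      for (i in seq_len(nrow(toks) - nt + 1L)) {
        if (!identical(toks$token[i:(i + nt - 1L)], trig_toks)) next
        trig_end <- toks$end[i + nt - 1L]
        after <- which(toks$start > trig_end)
        lim <- if (length(after) >= rule$window) toks$end[after[rule$window]] else Inf
        hit <- linked$class %in% rule$class & linked$start > trig_end & linked$start <= lim
        suppressed <- suppressed | hit
      }
    }
  }
  suppressed
}

#' Label a single pathology report
#'
#' The full extraction pipeline for one report: normalize, recognize mentions,
#' link them to gazetteer concepts, discard negated mentions (when negation
#' detection is enabled), apply context suppression rules, resolve
#' grade-sensitive concepts to high-/low-grade dysplasia via adjective rules
#' (defaulting to the configured class), and OR the surviving concepts'
#' classes into a multilabel vector. If no class survives the report is
#' labeled `normal` (the fallback), so the result never is the all-zero
#' vector.
#'
#' @param report A character string or a list/one-row tibble with `text` (and
#'   optionally `report_id`).
#' @param gazetteer Gazetteer tibble from [read_gazetteer()].
#' @param config [labeler_config()].
#' @return List with `label` (named 0/1 vector) and `concepts` (tibble of
#'   linked concepts: `concept_id`, `surface`, `start`, `end`, `method`,
#'   `score`, `negated`, `suppressed`, `grade`, `class`).
#' @export
#' @examples
#' gaz <- read_gazetteer()
#' label_report("tubular adenoma with low-grade dysplasia", gaz)$label
label_report <- function(report, gazetteer, config = labeler_config()) {
  text <- if (is.character(report)) report else report$text[[1]]
  norm <- normalize_text(text)
  mentions <- recognize_mentions(norm$text, gazetteer)
  rows <- list()
  if (nrow(mentions) > 0) {
    for (i in seq_len(nrow(mentions))) {
      cand <- mentions$candidate_ids[[i]]
      link <- link_mention(mentions$surface[[i]], gazetteer, config)
      if (is.null(link)) next
      entry <- gazetteer[gazetteer$concept_id == link$concept_id, ]
      grade <- NA_character_
      cls <- entry$mapped_class[[1]]
      if (entry$grade_sensitive[[1]]) {
        grade <- resolve_grade(norm$text, mentions$start[[i]])
        cls <- switch(ifelse(is.na(grade), "default", grade),
                      high = "high_grade_dysplasia",
                      low = "low_grade_dysplasia",
                      default = config$unspecified_grade_class)
        if (is.na(grade)) {
          grade <- if (cls == "high_grade_dysplasia") "high" else "low"
        }
      }
      rows[[length(rows) + 1L]] <- tibble(
        concept_id = link$concept_id,
        surface = mentions$surface[[i]],
        start = mentions$start[[i]], end = mentions$end[[i]],
        method = link$method, score = link$score,
        negated = detect_negation(norm$text, mentions[i, ], config),
        suppressed = FALSE,
        grade = grade,
        class = if (is.na(cls)) NA_character_ else cls
      )
    }
  }
  concepts <- if (length(rows) > 0) bind_rows(rows) else
    tibble(concept_id = character(), surface = character(), start = integer(),
           end = integer(), method = character(), score = double(),
           negated = logical(), suppressed = logical(), grade = character(),
           class = character())
  if (config$context_rules_enabled && nrow(concepts) > 0) {
    concepts$suppressed <- apply_context_rules(norm$text, concepts)
  }
  keep <- concepts
  if (config$negation_enabled) keep <- keep[!keep$negated, ]
  keep <- keep[!keep$suppressed, ]
  classes <- unique(keep$class[!is.na(keep$class)])
  if (length(classes) == 0) classes <- config$fallback_class
  list(label = make_label(classes), concepts = concepts)
}

#' Label a corpus of reports
#'
#' Runs [label_report()] over a reports table and, when ground truth is
#' supplied, scores the extracted labels with multilabel micro-accuracy and
#' support-weighted macro F1.
#'
#' @param reports Tibble with columns `report_id` and `text` (extra columns
#'   are carried through untouched).
#' @param gazetteer Gazetteer tibble.
#' @param config [labeler_config()].
#' @param gt Optional ground-truth label tibble (`case_id` + five indicator
#'   columns) keyed by `report_id`.
#' @return List with `labels` (tibble `case_id` + indicators), `trace`
#'   (per-report linked concepts) and, when `gt` is given, `metrics`
#'   (micro-accuracy and weighted F1).
#' @export
label_corpus <- function(reports, gazetteer, config = labeler_config(), gt = NULL) {
  if (anyDuplicated(reports$report_id) > 0) {
    abort("report_id values must be unique", class = "pathmil_validation_error")
  }
  res <- map(seq_len(nrow(reports)), function(i) {
    label_report(reports$text[[i]], gazetteer, config)
  })
  lab_mat <- do.call(rbind, map(res, "label"))
  labels <- labels_to_tibble(reports$report_id, lab_mat)
  trace <- bind_rows(map2(reports$report_id, res, function(id, r) {
    if (nrow(r$concepts) == 0) return(NULL)
    bind_cols(tibble(report_id = id), r$concepts)
  }))
  out <- list(labels = labels, trace = trace)
  if (!is.null(gt)) {
    joined <- labels %>%
      rename(!!!setNames(class_names(), paste0("pred_", class_names()))) %>%
      left_join(gt %>% rename(!!!setNames(class_names(), paste0("gt_", class_names()))),
                by = "case_id")
    if (anyNA(joined)) {
      abort("Ground truth must cover every report_id", class = "pathmil_validation_error")
    }
    out$metrics <- tibble(
      micro_accuracy = micro_accuracy(joined),
      weighted_f1 = weighted_f1(joined)$weighted_f1
    )
  }
  out
}

#' Read reports from JSONL
#'
#' One JSON object per line with fields `report_id`, `text` and optionally
#' `case_ids`.
#'
#' @param path File path.
#' @return Tibble with `report_id`, `text`, `case_ids` (list-column).
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- map(lines, jsonlite::fromJSON)
  tibble(
    report_id = map_chr(rows, "report_id"),
    text = map_chr(rows, "text"),
    case_ids = map(rows, function(r) as.character(r$case_ids %||% character()))
  )
}

#' @rdname read_reports_jsonl
#' @param reports Reports tibble.
#' @export
write_reports_jsonl <- function(reports, path) {
  lines <- map_chr(seq_len(nrow(reports)), function(i) {
    jsonlite::toJSON(list(report_id = reports$report_id[[i]],
                          text = reports$text[[i]],
                          case_ids = if ("case_ids" %in% names(reports))
                            reports$case_ids[[i]] else character()),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
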