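#' The five colon annotation classes
#'
#' The diagnostic label space used throughout the package: cancer, high-grade
#' dysplasia, low-grade dysplasia, hyperplastic polyp and normal, in that
#' fixed canonical order. Every label vector, prediction matrix and attention
#' matrix indexes classes in this order.
#'
#' @return A tibble with columns `name` (class identifier) and `index`
#'   (0-based canonical position).
#' @export
#' @examples
#' annotation_classes()
annotation_classes <- function() {
  tibble(
    name = c("cancer", "high_grade_dysplasia", "low_grade_dysplasia",
             "hyperplastic_polyp", "normal"),
    index = 0:4
  )
}

#' @rdname annotation_classes
#' @export
class_names <- function() annotation_classes()$name

n_classes <- function() 5L

assert_known_classes <- function(classes) {
  bad <- setdiff(classes, class_names())
  if (length(bad) > 0) {
    abort(paste0("Unknown annotation class: ", paste(bad, collapse = ", "),
                 ". Valid classes: ", paste(class_names(), collapse = ", ")),
          class = "pathmil_schema_error")
  }
  invisible(TRUE)
}

#' Build a multilabel vector from a set of classes
#'
#' A label vector holds five binary indicators in canonical class order. A
#' finalized report label always has at least one indicator set (the `normal`
#' fallback in [label_report()] guarantees this); `make_label()` itself allows
#' the all-zero vector so intermediate, not-yet-finalized states can be
#' represented.
#'
#' @param classes Character vector (possibly empty) of class names, a subset
#'   of `class_names()`.
#' @return Named integer vector of length 5 with values in `{0, 1}`.
#' @export
#' @examples
#' make_label("cancer")
#' make_label(c("high_grade_dysplasia", "low_grade_dysplasia"))
make_label <- function(classes = character()) {
  assert_known_classes(classes)
  setNames(as.integer(class_names() %in% classes), class_names())
}

#' @rdname make_label
#' @param label A label vector as returned by `make_label()`.
#' @return `label_classes()`: the character vector of set classes.
#' @export
label_classes <- function(label) {
  label <- as_label(label)
  class_names()[label == 1L]
}

# Coerce 0/1 vectors (named or positional) to a canonical label vector.
as_label <- function(x) {
  if (is.null(names(x))) {
    stopifnot(length(x) == n_classes())
    return(setNames(as.integer(x != 0), class_names()))
  }
  assert_known_classes(names(x))
  out <- setNames(integer(n_classes()), class_names())
  out[names(x)] <- as.integer(x != 0)
  out
}

#' Elementwise OR of two label vectors
#'
#' Used to merge multilabel findings, e.g. several report sections that refer
#' to the same case.
#'
#' @param a,b Label vectors (see [make_label()]).
#' @return A label vector.
#' @export
union_labels <- function(a, b) {
  a <- as_label(a)
  b <- as_label(b)
  setNames(as.integer(a | b), class_names())
}

#' External label schemes for public-dataset evaluation
#'
#' Public colon datasets annotate with coarser or partial class sets; model
#' predictions are aggregated onto those schemes before scoring. A scheme is a
#' partial mapping from internal classes to external class names; internal
#' classes absent from a scheme are dropped during aggregation. Schemes ship
#' as data (a TSV bundled with the package) so users can add their own.
#'
#' @param path Path to a scheme TSV with columns `scheme_name`,
#'   `internal_class`, `external_class`. Defaults to the bundled table
#'   covering glas, crc, unitopatho, tcga_coad, xu, aida and imp_crc.
#' @return A tibble with one row per (scheme, internal class) pair.
#' @export
read_schemes <- function(path = system.file("extdata", "schemes.tsv", package = "pathmil")) {
  sch <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("scheme_name", "internal_class", "external_class")
  if (!all(need %in% names(sch))) {
    abort("Scheme table must have columns scheme_name, internal_class, external_class",
          class = "pathmil_schema_error")
  }
  assert_known_classes(sch$internal_class)
  dup <- sch %>% count(.data$scheme_name, .data$internal_class) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort("Each internal class may map to at most one external class per scheme",
          class = "pathmil_schema_error")
  }
  sch
}

#' Aggregate a label vector onto an external scheme
#'
#' An external class is present iff at least one of its internal member
#' classes is set (OR semantics). Internal classes the scheme does not map are
#' dropped.
#'
#' @param label A label vector.
#' @param scheme Either a scheme name (looked up in `schemes`) or a tibble of
#'   (`internal_class`, `external_class`) rows for one scheme.
#' @param schemes Scheme table as returned by [read_schemes()].
#' @return Character vector of external class names (possibly empty), sorted.
#' @export
#' @examples
#' map_to_scheme(make_label("high_grade_dysplasia"), "aida")
map_to_scheme <- function(label, scheme, schemes = read_schemes()) {
  label <- as_label(label)
  if (is.character(scheme) && length(scheme) == 1) {
    tab <- schemes %>% filter(.data$scheme_name == scheme)
    if (nrow(tab) == 0) {
      abort(paste0("Unknown scheme: ", scheme), class = "pathmil_schema_error")
    }
  } else {
    tab <- scheme
  }
  set_classes <- label_classes(label)
  dropped <- setdiff(set_classes, tab$internal_class)
  if (length(dropped) > 0) {
    # unmapped predictions are dropped silently; surface at debug verbosity
    signalCondition(structure(
      class = c("pathmil_debug", "condition"),
      list(message = paste0("Classes dropped by scheme: ",
                            paste(dropped, collapse = ", ")), call = NULL)))
  }
  sort(unique(tab$external_class[tab$internal_class %in% set_classes]))
}

#' Read and write label tables
#'
#' A label table is the shared CSV currency between the report labeler, the
#' MIL trainer and the evaluation module: one row per case with columns
#' `case_id`, `cancer`, `hgd`, `lgd`, `hyperplastic`, `normal` (0/1).
#'
#' @param path File path.
#' @return `read_label_csv()`: a tibble with `case_id` plus the five indicator
#'   columns named as in `class_names()`.
#' @export
read_label_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  short <- c(cancer = "cancer", hgd = "high_grade_dysplasia",
             lgd = "low_grade_dysplasia", hyperplastic = "hyperplastic_polyp",
             normal = "normal")
  for (s in names(short)) {
    if (s %in% names(raw) && !short[[s]] %in% names(raw)) {
      names(raw)[names(raw) == s] <- short[[s]]
    }
  }
  miss <- setdiff(c("case_id", class_names()), names(raw))
  if (length(miss) > 0) {
    abort(paste0("Label CSV is missing columns: ", paste(miss, collapse = ", ")),
          class = "pathmil_schema_error")
  }
  raw %>%
    mutate(across(all_of(class_names()), as.integer)) %>%
    select(all_of(c("case_id", class_names())))
}

#' @rdname read_label_csv
#' @param labels Label tibble (`case_id` + five indicator columns).
#' @export
write_label_csv <- function(labels, path) {
  out <- labels %>% select(all_of(c("case_id", class_names())))
  names(out) <- c("case_id", "cancer", "hgd", "lgd", "hyperplastic", "normal")
  readr::write_csv(out, path)
  invisible(path)
}

# Label tibble <-> matrix helpers used across modules.
label_matrix <- function(labels) {
  m <- as.matrix(labels[, class_names()])
  storage.mode(m) <- "integer"
  rownames(m) <- labels$case_id
  m
}

labels_to_tibble <- function(case_id, mat) {
  colnames(mat) <- class_names()
  bind_cols(tibble(case_id = case_id), as_tibble(mat))
}

#' @importFrom dplyr bind_cols
NULL
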