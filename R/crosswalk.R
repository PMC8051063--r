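#' Consolidated answer-code count for a harmonized question
#'
#' When items from several instruments map to one harmonized question, the
#' question's consolidated scale gets as many ordinal codes as the
#' *smallest* source answer scale among the mapped items: a child assessed
#' only with the coarsest instrument must still be able to occupy every
#' code, and a finer response cannot be inferred from a coarser one.
#'
#' @param mapped_scale_sizes Integer vector (a multiset) of source answer
#'   scale sizes, all `>= 2`.
#' @return The number of consolidated answer codes `m` (the minimum size).
#' @examples
#' answer_code_count(c(4, 4, 3, 3, 4)) # 3
#' @export
answer_code_count <- function(mapped_scale_sizes) {
  sizes <- as.integer(mapped_scale_sizes)
  if (length(sizes) == 0L) abort("empty set of scale sizes")
  if (any(is.na(sizes) | sizes < 2L)) abort("all scale sizes must be >= 2")
  min(sizes)
}

#' Default severe-end collapsing answer map
#'
#' Maps a `k`-choice source scale (ordered least to most severe) onto `m`
#' consolidated codes: the `m - 1` least severe choices map one-to-one and
#' all remaining most-severe choices collapse onto the top code `m`. The
#' result is monotone non-decreasing and surjective onto `1..m`.
#'
#' @param k Source scale size, `k >= m`.
#' @param m Consolidated code count, `m >= 2`.
#' @return Integer vector of length `k`; position `i` gives the code
#'   assigned to source choice `i`.
#' @examples
#' default_answer_map(4, 3) # 1 2 3 3
#' @export
default_answer_map <- function(k, m) {
  k <- as.integer(k)
  m <- as.integer(m)
  if (m < 2L) abort("need at least 2 consolidated codes")
  if (k < m) {
    abort(sprintf(
      "source scale (%d) is coarser than the target (%d); no default map exists, supply an explicit one",
      k, m
    ))
  }
  c(seq_len(m - 1L), rep(m, k - m + 1L))
}

#' Build a crosswalk
#'
#' A crosswalk is the central fusion object: an instrument-version registry,
#' the instrument items (one row per item, with its answer-scale size), the
#' harmonized question bank, and the many-to-one item-to-question mappings
#' with per-item answer maps.
#'
#' @param registry Tibble with columns `instrument`, `version`, `reporter`,
#'   `n_items`, `scale_kind` (`"frequency"` or `"quality"`), `scale_size`.
#' @param items Tibble with columns `instrument`, `version`, `item`,
#'   `subject`, `scale_size`.
#' @param questions Tibble with columns `question_id`, `leaf`, `n_codes`
#'   and optionally `phrasing`.
#' @param mappings Tibble with columns `instrument`, `version`, `item`,
#'   `question_id`, `answer_map` (list column of integer vectors).
#' @param hierarchy Optional `rosetta_hierarchy` the question leaves live in.
#' @return A `rosetta_crosswalk` object.
#' @export
crosswalk <- function(registry, items, questions, mappings, hierarchy = NULL) {
  if (!is.null(hierarchy)) stopifnot(inherits(hierarchy, "rosetta_hierarchy"))
  mappings <- tibble::as_tibble(mappings)
  if (!is.list(mappings$answer_map)) {
    abort("mappings$answer_map must be a list column of integer vectors")
  }
  structure(
    list(
      registry = tibble::as_tibble(registry),
      items = tibble::as_tibble(items),
      questions = tibble::as_tibble(questions),
      mappings = mappings,
      hierarchy = hierarchy
    ),
    class = "rosetta_crosswalk"
  )
}

#' @export
print.rosetta_crosswalk <- function(x, ...) {
  cat(sprintf(
    "<rosetta_crosswalk> %d instruments / %d versions, %d items -> %d questions (%d mappings)\n",
    length(unique(x$registry$instrument)), nrow(x$registry),
    nrow(x$items), nrow(x$questions), nrow(x$mappings)
  ))
  invisible(x)
}

item_key <- function(df) paste(df$instrument, df$version, df$item, sep = "\r")

#' Validate a crosswalk
#'
#' Checks referential integrity (mappings refer to registered items and
#' existing questions; items refer to registered instrument versions), the
#' many-to-one rule (each item maps to exactly one question), answer-map
#' shape (length equals the item's scale size, values inside `1..m`,
#' monotone non-decreasing, surjective onto `1..m` whenever the source scale
#' is at least as fine), question-leaf existence when a hierarchy is
#' attached, and -- when `complete = TRUE` -- that no item is left unmapped.
#'
#' @param cw A `rosetta_crosswalk`.
#' @param complete Require every registered item to be mapped.
#' @return A tibble with columns `rule`, `where`, `message`; zero rows iff
#'   valid.
#' @export
validate_crosswalk <- function(cw, complete = TRUE) {
  stopifnot(inherits(cw, "rosetta_crosswalk"))
  out <- no_violations()
  reg_key <- paste(cw$registry$instrument, cw$registry$version, sep = "\r")
  it_key <- item_key(cw$items)
  map_key <- item_key(cw$mappings)

  bad_reg <- !(paste(cw$items$instrument, cw$items$version, sep = "\r") %in% reg_key)
  for (i in which(bad_reg)) {
    out <- dplyr::bind_rows(out, violation(
      "unregistered version",
      paste(cw$items$instrument[i], cw$items$version[i]),
      "item belongs to an instrument version absent from the registry"
    ))
  }

  dup_item <- unique(it_key[duplicated(it_key)])
  for (k in dup_item) {
    out <- dplyr::bind_rows(out, violation("duplicate item", gsub("\r", " ", k), "item declared twice"))
  }

  for (i in which(!(map_key %in% it_key))) {
    out <- dplyr::bind_rows(out, violation(
      "unknown item",
      gsub("\r", " ", map_key[i]), "mapping refers to an undeclared item"
    ))
  }
  for (i in which(!(cw$mappings$question_id %in% cw$questions$question_id))) {
    out <- dplyr::bind_rows(out, violation(
      "unknown question", cw$mappings$question_id[i],
      "mapping refers to an undeclared question"
    ))
  }

  multi <- unique(map_key[duplicated(map_key)])
  for (k in multi) {
    out <- dplyr::bind_rows(out, violation(
      "multiple mapping", gsub("\r", " ", k),
      "item maps to more than one question"
    ))
  }

  scale_of <- setNames(cw$items$scale_size, it_key)
  m_of <- setNames(cw$questions$n_codes, cw$questions$question_id)
  for (i in seq_len(nrow(cw$mappings))) {
    amap <- cw$mappings$answer_map[[i]]
    where <- gsub("\r", " ", map_key[i])
    k <- scale_of[map_key[i]]
    m <- m_of[cw$mappings$question_id[i]]
    if (is.na(k) || is.na(m)) next # already reported as unknown item/question
    if (length(amap) != k) {
      out <- dplyr::bind_rows(out, violation(
        "bad map length", where,
        sprintf("answer map has %d entries for a %d-choice scale", length(amap), k)
      ))
      next
    }
    if (any(amap < 1L | amap > m)) {
      out <- dplyr::bind_rows(out, violation(
        "code out of range", where,
        sprintf("answer map uses codes outside 1..%d", m)
      ))
    }
    if (is.unsorted(amap)) {
      out <- dplyr::bind_rows(out, violation(
        "non-monotone", where,
        "answer map must be non-decreasing in severity"
      ))
    }
    if (k >= m && !all(seq_len(m) %in% amap)) {
      out <- dplyr::bind_rows(out, violation(
        "non-surjective", where,
        sprintf("answer map does not reach every code in 1..%d", m)
      ))
    }
  }

  if (!is.null(cw$hierarchy)) {
    leaves <- hierarchy_leaves(cw$hierarchy)
    for (i in which(!(cw$questions$leaf %in% leaves))) {
      out <- dplyr::bind_rows(out, violation(
        "unknown leaf", cw$questions$question_id[i],
        sprintf("question leaf '%s' is not a hierarchy leaf", cw$questions$leaf[i])
      ))
    }
  }

  if (complete) {
    for (k in setdiff(it_key, map_key)) {
      out <- dplyr::bind_rows(out, violation(
        "unmapped item", gsub("\r", " ", k),
        "item has no question mapping in a complete crosswalk"
      ))
    }
  }
  out
}

#' Read / write a crosswalk file
#'
#' Crosswalks are stored as structured text (YAML, or JSON which YAML
#' parses) with sections `registry`, `items`, `questions`, `mappings`;
#' answer maps are plain integer arrays.
#'
#' @param path File path.
#' @param cw A `rosetta_crosswalk`.
#' @return [read_crosswalk()] returns a `rosetta_crosswalk`;
#'   [write_crosswalk()] returns `path` invisibly.
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("no such file: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
    error = function(e) parse_error(sprintf("cannot parse crosswalk file: %s", conditionMessage(e)))
  )
  need <- c("registry", "items", "questions", "mappings")
  miss <- setdiff(need, names(doc))
  if (length(miss)) parse_error(paste("crosswalk file missing section(s):", paste(miss, collapse = ", ")))
  as_tbl <- function(recs) purrr::map_dfr(recs, ~ tibble::as_tibble(.x[setdiff(names(.x), "answer_map")]))
  mappings <- as_tbl(doc$mappings)
  mappings$answer_map <- purrr::map(doc$mappings, ~ as.integer(.x$answer_map))
  crosswalk(
    registry = as_tbl(doc$registry),
    items = as_tbl(doc$items),
    questions = as_tbl(doc$questions),
    mappings = mappings
  )
}

#' @rdname read_crosswalk
#' @export
write_crosswalk <- function(cw, path) {
  stopifnot(inherits(cw, "rosetta_crosswalk"))
  row_records <- function(df) {
    purrr::pmap(df, function(...) {
      rec <- list(...)
      rec[!vapply(rec, function(v) length(v) == 1L && is.na(v), TRUE)]
    })
  }
  doc <- list(
    registry = row_records(cw$registry),
    items = row_records(cw$items),
    questions = row_records(cw$questions),
    mappings = row_records(cw$mappings)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
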