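#' Fused child-by-question matrix
#'
#' A `rosetta_matrix` is a wide tibble with a `child_id` column and one
#' integer column per harmonized question; `NA` marks a missing cell (no
#' mapped item response contributed). The per-question code counts are kept
#' in the `n_codes` attribute.
#'
#' @param data Tibble with a `child_id` column and integer question columns.
#' @param n_codes Named integer vector: consolidated code count per question
#'   column.
#' @return A `rosetta_matrix`.
#' @export
rosetta_matrix <- function(data, n_codes) {
  data <- tibble::as_tibble(data)
  stopifnot("child_id" %in% names(data))
  qs <- setdiff(names(data), "child_id")
  if (!all(qs %in% names(n_codes))) abort("every question column needs an entry in n_codes")
  structure(data,
    n_codes = n_codes[qs],
    class = c("rosetta_matrix", class(tibble::tibble()))
  )
}

#' @export
print.rosetta_matrix <- function(x, ...) {
  qs <- matrix_questions(x)
  obs <- sum(!is.na(as.matrix(x[qs])))
  cat(sprintf(
    "<rosetta_matrix> %d children x %d questions (%.1f%% observed)\n",
    nrow(x), length(qs), 100 * obs / max(1, nrow(x) * length(qs))
  ))
  NextMethod()
}

#' Question columns of a fused matrix
#' @param m A `rosetta_matrix` (or imputed matrix).
#' @return Character vector of question ids.
#' @export
matrix_questions <- function(m) {
  if (inherits(m, "rosetta_imputed")) {
    return(setdiff(names(m$values), "child_id"))
  }
  setdiff(names(m), "child_id")
}

#' Translate instrument responses into the harmonized question space
#'
#' Applies a crosswalk to a long table of raw instrument responses: each
#' response is recoded through its item's answer map, and all recoded
#' responses a child has for one question are collapsed into a single
#' ordinal cell by the aggregation `policy`. Cells with no contributing
#' response are missing.
#'
#' Policies: `"max"` keeps the most severe code (default; preserves
#' clinical signal and never fabricates fractional codes), `"mean"` takes
#' the rounded mean (half rounds up), `"first"` takes the code of the first
#' item in canonical (instrument, version, item) order, making all policies
#' invariant to response row order.
#'
#' @param cw A complete `rosetta_crosswalk`.
#' @param responses Tibble with columns `child_id`, `instrument`, `version`,
#'   `item`, `raw` (1-based source answer index).
#' @param policy Aggregation policy for several items mapping to one
#'   question.
#' @param children Optional character vector of child ids that must appear
#'   as rows even with no responses (all-missing rows).
#' @return A [rosetta_matrix()] with one column per crosswalk question.
#' @export
translate <- function(cw, responses, policy = c("max", "mean", "first"),
                      children = NULL) {
  stopifnot(inherits(cw, "rosetta_crosswalk"))
  policy <- match.arg(policy)
  responses <- tibble::as_tibble(responses)
  need <- c("child_id", "instrument", "version", "item", "raw")
  if (!all(need %in% names(responses))) {
    abort(paste("responses need columns", paste(need, collapse = ", ")))
  }

  known <- item_key(cw$mappings)
  rkey <- item_key(responses)
  bad <- which(!(rkey %in% known))
  if (length(bad)) {
    abort(sprintf(
      "unknown item in responses (row %d): %s %s item %s",
      bad[1], responses$instrument[bad[1]], responses$version[bad[1]],
      as.character(responses$item[bad[1]])
    ))
  }

  map_tbl <- cw$mappings
  map_tbl$.key <- known
  scale_of <- setNames(cw$items$scale_size, item_key(cw$items))
  idx <- match(rkey, map_tbl$.key)
  k_of <- scale_of[rkey]
  oor <- which(is.na(responses$raw) | responses$raw < 1L | responses$raw > k_of)
  if (length(oor)) {
    i <- oor[1]
    abort(sprintf(
      "raw answer %s out of range 1..%d (row %d: child %s, %s %s item %s)",
      as.character(responses$raw[i]), k_of[i], i, responses$child_id[i],
      responses$instrument[i], responses$version[i], as.character(responses$item[i])
    ))
  }

  coded <- responses
  coded$question_id <- map_tbl$question_id[idx]
  coded$code <- purrr::map2_int(
    map_tbl$answer_map[idx], responses$raw,
    function(am, r) as.integer(am[[r]])
  )

  agg <- switch(policy,
    max = function(d) max(d$code),
    mean = function(d) as.integer(floor(mean(d$code) + 0.5)),
    first = function(d) {
      d <- d[order(d$instrument, d$version, as.character(d$item)), ]
      d$code[[1]]
    }
  )
  cells <- coded |>
    dplyr::group_by(.data$child_id, .data$question_id) |>
    dplyr::group_modify(~ tibble::tibble(code = agg(.x))) |>
    dplyr::ungroup()

  all_children <- sort(unique(c(as.character(children), coded$child_id)))
  qs <- cw$questions$question_id
  wide <- tidyr::pivot_wider(cells,
    id_cols = "child_id", names_from = "question_id",
    values_from = "code"
  )
  wide <- dplyr::right_join(wide, tibble::tibble(child_id = all_children), by = "child_id")
  for (q in setdiff(qs, names(wide))) wide[[q]] <- NA_integer_
  wide <- dplyr::select(wide, dplyr::all_of(c("child_id", qs)))
  wide <- dplyr::arrange(wide, .data$child_id)
  rosetta_matrix(wide, setNames(as.integer(cw$questions$n_codes), cw$questions$question_id))
}

#' Read / write a fused matrix as CSV
#'
#' Wide CSV with a `child_id` column; empty cells are missing. Code counts
#' are not stored in the CSV; supply them (or a crosswalk) when reading.
#'
#' @param m A `rosetta_matrix`.
#' @param path File path.
#' @param n_codes Named integer vector of per-question code counts.
#' @return [read_matrix_csv()] returns a `rosetta_matrix`.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, n_codes) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  qs <- setdiff(names(df), "child_id")
  for (q in qs) df[[q]] <- ifelse(df[[q]] == "", NA_character_, df[[q]])
  for (q in qs) df[[q]] <- as.integer(df[[q]])
  rosetta_matrix(df, n_codes)
}
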