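# Per-question sets of contributing instruments (instrument level, not
# version level, matching how the fusion statistics are reported).
question_instrument_sets <- function(cw) {
  tbl <- dplyr::distinct(cw$mappings, .data$question_id, .data$instrument)
  split(tbl$instrument, factor(tbl$question_id, levels = cw$questions$question_id))
}

#' Instrument overlap matrix
#'
#' For each pair of instruments, counts the harmonized questions that have
#' at least one mapped item from both (the matrix is symmetric off the
#' diagonal). The diagonal counts questions *exclusive* to one instrument
#' (all their mapped items come from it alone), and the totals column
#' counts questions touched by each instrument at all.
#'
#' @param cw A complete `rosetta_crosswalk`.
#' @return A `rosetta_overlap` object: list with `matrix` (named square
#'   integer matrix) and `totals` (named integer vector).
#' @export
overlap_matrix <- function(cw) {
  stopifnot(inherits(cw, "rosetta_crosswalk"))
  insts <- unique(cw$registry$instrument)
  sets <- question_instrument_sets(cw)
  mat <- matrix(0L, length(insts), length(insts), dimnames = list(insts, insts))
  totals <- setNames(integer(length(insts)), insts)
  for (s in sets) {
    s <- unique(s)
    if (length(s) == 0L) next
    totals[s] <- totals[s] + 1L
    if (length(s) == 1L) {
      mat[s, s] <- mat[s, s] + 1L
    } else {
      for (a in s) {
        for (b in setdiff(s, a)) mat[a, b] <- mat[a, b] + 1L
      }
    }
  }
  structure(list(matrix = mat, totals = totals), class = "rosetta_overlap")
}

#' @export
print.rosetta_overlap <- function(x, ...) {
  cat("<rosetta_overlap> question overlap between instruments\n")
  print(cbind(x$matrix, total = x$totals))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an overlap matrix into long form
#' @param x A `rosetta_overlap`.
#' @param ... Unused.
#' @return Tibble with columns `instrument`, `other`, `n_questions`
#'   (diagonal rows count exclusive questions) plus `total` rows under
#'   `other = "(any)"`.
#' @export
#' @exportS3Method generics::tidy
tidy.rosetta_overlap <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE))
  names(long) <- c("instrument", "other", "n_questions")
  long$n_questions <- as.integer(long$n_questions)
  dplyr::bind_rows(
    long,
    tibble::tibble(
      instrument = names(x$totals), other = "(any)",
      n_questions = as.integer(x$totals)
    )
  )
}

#' Heat map of instrument overlap
#' @param object A `rosetta_overlap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.rosetta_overlap <- function(object, ...) {
  d <- tidy(object)
  d$other <- factor(d$other, levels = c(colnames(object$matrix), "(any)"))
  d$instrument <- factor(d$instrument, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$other, y = .data$instrument, fill = .data$n_questions)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_questions), size = 3) +
    ggplot2::scale_fill_gradient(low = "#d95f02", high = "#1f78b4") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "questions",
      title = "Harmonized-question overlap between instruments"
    )
}

#' Per-leaf fusion summary
#'
#' For every leaf category, counts the distinct instruments contributing
#' mapped items, the mapped items themselves, and the harmonized questions
#' created under the leaf, with a grand-total row (`leaf = "(total)"`;
#' its instrument count is the number of distinct instruments overall).
#'
#' @param cw A complete `rosetta_crosswalk`.
#' @param all_leaves Include hierarchy leaves without any question as
#'   zero rows (requires an attached hierarchy).
#' @return Tibble with columns `leaf`, `n_instruments`, `n_items`,
#'   `n_questions`.
#' @export
fusion_summary <- function(cw, all_leaves = FALSE) {
  stopifnot(inherits(cw, "rosetta_crosswalk"))
  leaf_of <- setNames(cw$questions$leaf, cw$questions$question_id)
  maps <- cw$mappings
  maps$leaf <- leaf_of[maps$question_id]
  per_leaf_map <- maps |>
    dplyr::group_by(.data$leaf) |>
    dplyr::summarise(
      n_instruments = dplyr::n_distinct(.data$instrument),
      n_items = dplyr::n(),
      .groups = "drop"
    )
  per_leaf_q <- cw$questions |>
    dplyr::group_by(.data$leaf) |>
    dplyr::summarise(n_questions = dplyr::n(), .groups = "drop")
  out <- dplyr::full_join(per_leaf_map, per_leaf_q, by = "leaf")
  if (all_leaves) {
    if (is.null(cw$hierarchy)) abort("all_leaves = TRUE needs a crosswalk with an attached hierarchy")
    out <- dplyr::full_join(out,
      tibble::tibble(leaf = hierarchy_leaves(cw$hierarchy)),
      by = "leaf"
    )
  }
  out <- out |>
    tidyr::replace_na(list(n_instruments = 0L, n_items = 0L, n_questions = 0L)) |>
    dplyr::arrange(.data$leaf)
  total <- tibble::tibble(
    leaf = "(total)",
    n_instruments = dplyr::n_distinct(cw$mappings$instrument),
    n_items = nrow(cw$mappings),
    n_questions = nrow(cw$questions)
  )
  dplyr::bind_rows(out, total)
}
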