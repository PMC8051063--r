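#' Imputation configuration
#'
#' Controls the constraint-based ensemble imputer. The class-size guard
#' (`min_class_samples = 50`) and the per-cell prediction floor
#' (`min_predictions = 10`) are the documented defaults of the procedure;
#' smaller cohorts need a proportionally smaller guard or most candidate
#' draws are discarded.
#'
#' @param min_class_samples Minimum training rows per labelled class for a
#'   candidate feature subset to be kept.
#' @param min_predictions Minimum accumulated predictions per missing cell
#'   before it is considered imputed.
#' @param subset_size_range Inclusive range for the size of candidate
#'   feature subsets (capped at one less than the number of features).
#' @param trees_per_forest Trees in each random forest.
#' @param max_draws_per_feature Cap on candidate draws per feature; cells
#'   still short of `min_predictions` at the cap are flagged `failed`.
#' @param mode `"regression"` (default; ordinal codes as reals, ensemble
#'   mean clamped to the code range) or `"classification"` (majority-vote
#'   forests whose predicted codes are averaged the same way).
#' @param round Round final imputed values to whole codes.
#' @param seed Integer seed for the draw sequence and forests.
#' @return A `rosetta_impute_config` list.
#' @export
impute_config <- function(min_class_samples = 50,
                          min_predictions = 10,
                          subset_size_range = c(3, 20),
                          trees_per_forest = 100,
                          max_draws_per_feature = 200,
                          mode = c("regression", "classification"),
                          round = FALSE,
                          seed = 11) {
  stopifnot(
    min_class_samples >= 1, min_predictions >= 1,
    length(subset_size_range) == 2, subset_size_range[1] >= 1,
    trees_per_forest >= 1, max_draws_per_feature >= 1
  )
  structure(
    list(
      min_class_samples = as.integer(min_class_samples),
      min_predictions = as.integer(min_predictions),
      subset_size_range = as.integer(subset_size_range),
      trees_per_forest = as.integer(trees_per_forest),
      max_draws_per_feature = as.integer(max_draws_per_feature),
      mode = match.arg(mode),
      round = isTRUE(round),
      seed = as.integer(seed)
    ),
    class = "rosetta_impute_config"
  )
}

#' Constraint-based ensemble random-forest imputation
#'
#' Imputes the missing cells of a fused child-by-question matrix one
#' feature at a time. For a feature `f` with missing values, candidate
#' subsets `S` of *other* features are drawn repeatedly (uniform size
#' inside `subset_size_range`); a draw is used only if the rows fully
#' observed on `S` and observed on `f` contain at least
#' `min_class_samples` rows of every labelled class. A random forest
#' `f ~ S` is fit on those rows and predicts `f` for the rows missing `f`
#' but fully observed on `S`; predictions accumulate per cell until every
#' target cell has at least `min_predictions` of them (or the draw cap is
#' reached). The imputed value is the mean accumulated prediction, clamped
#' to the question's code range; cells that never reach the floor stay
#' missing and are flagged `failed`.
#'
#' Candidate features always enter with their *originally observed* values
#' -- an imputed value is never used as a predictor -- which avoids the
#' cascading errors of chained multiple-imputation schemes. Class labels
#' are used only by the class-size guard, never as predictors.
#'
#' @param m A [rosetta_matrix()].
#' @param labels Tibble with columns `child_id`, `condition` covering every
#'   row of `m`.
#' @param config An [impute_config()].
#' @return A `rosetta_imputed` object: list with `values` (numeric tibble;
#'   observed cells exactly preserved), `provenance` (per cell one of
#'   `"observed"`, `"imputed"`, `"failed"`), `prediction_counts`, and
#'   `n_codes`.
#' @export
impute_ensemble <- function(m, labels, config = impute_config()) {
  impute_engine(m, labels, config, learner = ranger_learner(config))
}

# A learner is function(xtr, ytr, xte, seed) -> numeric predictions; the
# default fits a random forest. Kept separate so the constraint loop can be
# exercised with a deterministic learner.
ranger_learner <- function(config) {
  function(xtr, ytr, xte, seed) {
    if (config$mode == "classification") ytr <- factor(ytr)
    fit <- ranger::ranger(
      x = xtr, y = ytr,
      num.trees = config$trees_per_forest,
      num.threads = 1L, seed = seed, verbose = FALSE
    )
    p <- predict(fit, data = xte, num.threads = 1L)$predictions
    if (config$mode == "classification") p <- as.numeric(as.character(p))
    p
  }
}

impute_engine <- function(m, labels, config, learner) {
  stopifnot(inherits(m, "rosetta_matrix"), inherits(config, "rosetta_impute_config"))
  labels <- tibble::as_tibble(labels)
  if (!all(c("child_id", "condition") %in% names(labels))) {
    abort("labels need columns child_id, condition")
  }
  if (!all(m$child_id %in% labels$child_id)) {
    abort("labels must cover every row of the matrix")
  }
  if (nrow(m) == 0) abort("empty matrix")
  qs <- matrix_questions(m)
  vals <- as.matrix(m[qs])
  storage.mode(vals) <- "double"
  obs <- !is.na(vals)
  if (!any(rowSums(obs) > 0) || all(colSums(obs) == 0)) {
    abort("degenerate matrix: no observed values to train on")
  }
  cls <- factor(labels$condition[match(m$child_id, labels$child_id)])
  classes <- levels(cls)
  n_codes <- attr(m, "n_codes")

  out_vals <- vals
  prov <- matrix("observed", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  prov[!obs] <- "failed"
  counts <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))

  lo <- config$subset_size_range[1]
  hi <- min(config$subset_size_range[2], length(qs) - 1L)
  if (hi < lo) abort("subset_size_range infeasible for this matrix")

  set.seed(config$seed)
  for (f in qs[colSums(!obs[, qs, drop = FALSE]) > 0]) {
    target <- which(!obs[, f])
    others <- setdiff(qs, f)
    sums <- numeric(length(target))
    nacc <- integer(length(target))
    for (draw in seq_len(config$max_draws_per_feature)) {
      if (all(nacc >= config$min_predictions)) break
      s_size <- if (hi > lo) sample(lo:hi, 1) else lo
      S <- sample(others, s_size)
      cover_S <- rowSums(!obs[, S, drop = FALSE]) == 0
      train <- which(obs[, f] & cover_S)
      if (length(train) < 2L) next
      tab <- table(factor(cls[train], levels = classes))
      if (any(tab < config$min_class_samples)) next
      pred_idx <- which(cover_S[target])
      if (length(pred_idx) == 0L) next

      lseed <- sample.int(.Machine$integer.max, 1)
      p <- learner(
        as.data.frame(vals[train, S, drop = FALSE]),
        vals[train, f],
        as.data.frame(vals[target[pred_idx], S, drop = FALSE]),
        lseed
      )
      sums[pred_idx] <- sums[pred_idx] + p
      nacc[pred_idx] <- nacc[pred_idx] + 1L
    }
    done <- nacc >= config$min_predictions
    if (any(done)) {
      est <- sums[done] / nacc[done]
      est <- pmin(pmax(est, 1), n_codes[[f]])
      if (config$round) est <- round(est)
      out_vals[target[done], f] <- est
      prov[target[done], f] <- "imputed"
    }
    counts[target, f] <- nacc
  }

  structure(
    list(
      values = tibble::as_tibble(cbind(tibble::tibble(child_id = m$child_id), out_vals)),
      provenance = tibble::as_tibble(cbind(tibble::tibble(child_id = m$child_id), as.data.frame(prov))),
      prediction_counts = tibble::as_tibble(cbind(tibble::tibble(child_id = m$child_id), as.data.frame(counts))),
      n_codes = n_codes,
      config = config
    ),
    class = "rosetta_imputed"
  )
}

#' @export
print.rosetta_imputed <- function(x, ...) {
  qs <- matrix_questions(x)
  pv <- as.matrix(x$provenance[qs])
  cat(sprintf(
    "<rosetta_imputed> %d children x %d questions: %d observed, %d imputed, %d failed cells\n",
    nrow(x$values), length(qs),
    sum(pv == "observed"), sum(pv == "imputed"), sum(pv == "failed")
  ))
  invisible(x)
}

#' Tidy an imputed matrix into long form
#' @param x A `rosetta_imputed`.
#' @param ... Unused.
#' @return Tibble with columns `child_id`, `question_id`, `value`,
#'   `status`, `n_predictions`.
#' @export
#' @exportS3Method generics::tidy
tidy.rosetta_imputed <- function(x, ...) {
  qs <- matrix_questions(x)
  long <- function(df, name) {
    tidyr::pivot_longer(df, dplyr::all_of(qs),
      names_to = "question_id", values_to = name
    )
  }
  long(x$values, "value") |>
    dplyr::left_join(long(x$provenance, "status"), by = c("child_id", "question_id")) |>
    dplyr::left_join(long(x$prediction_counts, "n_predictions"), by = c("child_id", "question_id"))
}

#' Observed-coverage profile of a fused matrix
#'
#' Per-question and per-child fractions of usable cells. For a raw
#' [rosetta_matrix()] a cell is usable when observed; for a
#' `rosetta_imputed` matrix, when not flagged `failed`.
#'
#' @param m A `rosetta_matrix` or `rosetta_imputed`.
#' @return List with tibbles `questions` (`question_id`, `n_valid`,
#'   `fraction`) and `children` (`child_id`, `n_valid`, `fraction`).
#' @export
coverage_profile <- function(m) {
  qs <- matrix_questions(m)
  valid <- if (inherits(m, "rosetta_imputed")) {
    as.matrix(m$provenance[qs]) != "failed"
  } else {
    !is.na(as.matrix(m[qs]))
  }
  ids <- if (inherits(m, "rosetta_imputed")) m$values$child_id else m$child_id
  list(
    questions = tibble::tibble(
      question_id = qs,
      n_valid = as.integer(unname(colSums(valid))),
      fraction = unname(colSums(valid)) / nrow(valid)
    ),
    children = tibble::tibble(
      child_id = ids,
      n_valid = as.integer(unname(rowSums(valid))),
      fraction = unname(rowSums(valid)) / length(qs)
    )
  )
}
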