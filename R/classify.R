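#' Classifier configuration
#'
#' Settings for the two-stage gradient-boosted assessment. Twenty-fold
#' cross-validation is the documented default; desk-scale analyses
#' typically use `k_folds = 5`. Boosting hyperparameters (depth 3,
#' 200 rounds, learning rate 0.1) are exposed here.
#'
#' @param k_folds Number of stratified CV folds.
#' @param gate_threshold Stage-1 probability above which the stage-2
#'   discriminator is consulted; below it a child is called `neither`.
#' @param max_depth,nrounds,eta Gradient-boosting hyperparameters.
#' @param prune_patience Pruning stops after this many iterations without
#'   a cross-validated improvement.
#' @param prune_objective Which pooled AUC drives pruning: mean of both
#'   stages (default), or a single stage.
#' @param seed Integer seed (fold assignment and boosting).
#' @return A `rosetta_classifier_config` list.
#' @export
classifier_config <- function(k_folds = 20, gate_threshold = 0.5,
                              max_depth = 3, nrounds = 200, eta = 0.1,
                              prune_patience = 3,
                              prune_objective = c("mean", "stage1", "stage2"),
                              seed = 3) {
  stopifnot(
    k_folds >= 2, gate_threshold > 0, gate_threshold <= 1,
    max_depth >= 1, nrounds >= 1, eta > 0
  )
  structure(
    list(
      k_folds = as.integer(k_folds), gate_threshold = gate_threshold,
      max_depth = as.integer(max_depth), nrounds = as.integer(nrounds),
      eta = eta, prune_patience = as.integer(prune_patience),
      prune_objective = match.arg(prune_objective), seed = as.integer(seed)
    ),
    class = "rosetta_classifier_config"
  )
}

# Numeric feature matrix (NA = unusable cell) + child ids from any of the
# containers the pipeline produces.
feature_matrix <- function(x) {
  if (inherits(x, "rosetta_imputed")) {
    qs <- matrix_questions(x)
    vals <- as.matrix(x$values[qs])
    vals[as.matrix(x$provenance[qs]) == "failed"] <- NA_real_
    return(list(x = vals, child_id = x$values$child_id))
  }
  df <- tibble::as_tibble(x)
  stopifnot("child_id" %in% names(df))
  qs <- setdiff(names(df), "child_id")
  list(x = as.matrix(df[qs]), child_id = df$child_id)
}

align_labels <- function(child_id, labels) {
  labels <- tibble::as_tibble(labels)
  if (!all(c("child_id", "condition") %in% names(labels))) {
    abort("labels need columns child_id, condition")
  }
  cond <- labels$condition[match(child_id, labels$child_id)]
  if (any(is.na(cond))) abort("labels must cover every row")
  cond
}

fit_gbdt <- function(x, y01, config) {
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", max_depth = config$max_depth,
      eta = config$eta, nthread = 1
    ),
    data = xgboost::xgb.DMatrix(x, label = y01, nthread = 1),
    nrounds = config$nrounds, verbose = 0
  )
}

pooled_auc <- function(scores, positive) {
  if (requireNamespace("pROC", quietly = TRUE)) {
    as.numeric(pROC::auc(
      response = factor(positive, levels = c(FALSE, TRUE)),
      predictor = scores, quiet = TRUE, direction = "<"
    ))
  } else {
    r <- rank(scores)
    n1 <- sum(positive)
    n0 <- sum(!positive)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
}

make_folds <- function(condition, k, seed) {
  fold <- integer(length(condition))
  with_seed(seed, {
    for (cl in unique(condition)) {
      idx <- which(condition == cl)
      if (length(idx) < k) abort(sprintf("class '%s' has fewer rows than folds", cl))
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Train the two-stage assessment model
#'
#' Stage 1 (the gate) is a gradient-boosted tree model for
#' condition-present (autism or ADHD) versus neither, trained on all rows.
#' Stage 2 (the discriminator) separates autism from ADHD and is trained
#' only on the truly condition-positive rows; at prediction time it is
#' consulted only for children the gate flags.
#'
#' @param x A `rosetta_imputed`, `rosetta_matrix`, or tibble with
#'   `child_id` plus numeric feature columns.
#' @param labels Tibble `child_id`, `condition` in
#'   `{"autism", "adhd", "neither"}`.
#' @param config A [classifier_config()].
#' @param features Optional subset of feature columns to train on (e.g.
#'   from [iterative_prune()]).
#' @return A `rosetta_two_stage` model.
#' @export
train_two_stage <- function(x, labels, config = classifier_config(), features = NULL) {
  fm <- feature_matrix(x)
  cond <- align_labels(fm$child_id, labels)
  features <- features %||% colnames(fm$x)
  stopifnot(all(features %in% colnames(fm$x)))
  xx <- fm$x[, features, drop = FALSE]

  pos <- cond != "neither"
  if (length(unique(pos)) < 2) abort("stage 1 needs both positive and neither rows")
  if (length(unique(cond[pos])) < 2) abort("stage 2 needs both autism and adhd rows")
  with_seed(stage_seed(config$seed, 101), {
    stage1 <- fit_gbdt(xx, as.numeric(pos), config)
    stage2 <- fit_gbdt(xx[pos, , drop = FALSE], as.numeric(cond[pos] == "autism"), config)
  })
  structure(
    list(
      stage1 = stage1, stage2 = stage2, selected_features = features,
      gate_threshold = config$gate_threshold, config = config
    ),
    class = "rosetta_two_stage"
  )
}

#' @export
print.rosetta_two_stage <- function(x, ...) {
  cat(sprintf(
    "<rosetta_two_stage> gate + autism/ADHD discriminator over %d features (gate threshold %.2f)\n",
    length(x$selected_features), x$gate_threshold
  ))
  invisible(x)
}

#' Predict with a two-stage model
#'
#' The gate probability is computed for every row; rows below the gate
#' threshold are labelled `neither` and the discriminator is *not* run for
#' them. For gated rows the discriminator assigns `autism` or `adhd`.
#'
#' @param object A `rosetta_two_stage`.
#' @param newdata A container accepted by [train_two_stage()] carrying the
#'   model's selected features.
#' @param ... Unused.
#' @return Tibble with `child_id`, `p_condition` (gate probability),
#'   `p_autism` (`NA` for ungated rows), `label`; the number of rows the
#'   discriminator was consulted for is in attribute `n_stage2`.
#' @export
predict.rosetta_two_stage <- function(object, newdata, ...) {
  fm <- feature_matrix(newdata)
  miss <- setdiff(object$selected_features, colnames(fm$x))
  if (length(miss)) abort(paste("missing selected features:", paste(head(miss, 3), collapse = ", ")))
  xx <- fm$x[, object$selected_features, drop = FALSE]
  p1 <- predict(object$stage1, xgboost::xgb.DMatrix(xx, nthread = 1))
  gated <- p1 >= object$gate_threshold
  p2 <- rep(NA_real_, length(p1))
  if (any(gated)) {
    p2[gated] <- predict(
      object$stage2,
      xgboost::xgb.DMatrix(xx[gated, , drop = FALSE], nthread = 1)
    )
  }
  label <- ifelse(!gated, "neither", ifelse(p2 >= 0.5, "autism", "adhd"))
  out <- tibble::tibble(
    child_id = fm$child_id, p_condition = p1,
    p_autism = p2, label = label
  )
  attr(out, "n_stage2") <- sum(gated)
  out
}

#' Stratified cross-validation of the two-stage model
#'
#' Splits rows into `k_folds` class-stratified folds (fold sizes differ by
#' at most one within each class), trains an independent two-stage model on
#' each training split, and pools the out-of-fold scores: stage-1 AUC over
#' all rows (condition-present vs neither), stage-2 AUC over the truly
#' condition-positive rows (autism vs ADHD).
#'
#' @inheritParams train_two_stage
#' @param features Optional feature subset.
#' @return A `rosetta_cv` object: list with `pooled` (stage, auc),
#'   `per_fold`, `scores` (out-of-fold probabilities) and `folds`.
#' @export
cross_validate <- function(x, labels, config = classifier_config(), features = NULL) {
  fm <- feature_matrix(x)
  cond <- align_labels(fm$child_id, labels)
  features <- features %||% colnames(fm$x)
  xx <- fm$x[, features, drop = FALSE]
  k <- config$k_folds
  fold <- make_folds(cond, k, stage_seed(config$seed, 7))

  pos <- cond != "neither"
  p1 <- rep(NA_real_, length(cond))
  p2 <- rep(NA_real_, length(cond))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    with_seed(stage_seed(config$seed, 200 + f), {
      m1 <- fit_gbdt(xx[tr, , drop = FALSE], as.numeric(pos[tr]), config)
      m2 <- fit_gbdt(
        xx[tr & pos, , drop = FALSE],
        as.numeric(cond[tr & pos] == "autism"), config
      )
    })
    p1[te] <- predict(m1, xgboost::xgb.DMatrix(xx[te, , drop = FALSE], nthread = 1))
    if (any(te & pos)) {
      p2[te & pos] <- predict(
        m2, xgboost::xgb.DMatrix(xx[te & pos, , drop = FALSE], nthread = 1)
      )
    }
  }

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    te <- fold == f
    tibble::tibble(
      fold = f,
      auc_stage1 = if (length(unique(pos[te])) == 2) pooled_auc(p1[te], pos[te]) else NA_real_,
      auc_stage2 = if (length(unique(cond[te & pos])) == 2) {
        pooled_auc(p2[te & pos], cond[te & pos] == "autism")
      } else {
        NA_real_
      }
    )
  })
  pooled <- tibble::tibble(
    stage = c("stage1", "stage2"),
    auc = c(
      pooled_auc(p1, pos),
      pooled_auc(p2[pos], cond[pos] == "autism")
    )
  )
  structure(
    list(
      pooled = pooled, per_fold = per_fold,
      scores = tibble::tibble(
        child_id = fm$child_id, condition = cond, fold = fold,
        p_condition = p1, p_autism = p2
      ),
      folds = tibble::tibble(child_id = fm$child_id, fold = fold),
      config = config
    ),
    class = "rosetta_cv"
  )
}

#' @export
print.rosetta_cv <- function(x, ...) {
  cat(sprintf(
    "<rosetta_cv> %d-fold stratified CV: stage1 AUC %.3f, stage2 AUC %.3f\n",
    max(x$folds$fold), x$pooled$auc[1], x$pooled$auc[2]
  ))
  invisible(x)
}

#' Tidy per-fold cross-validation results
#' @param x A `rosetta_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold and stage.
#' @export
#' @exportS3Method generics::tidy
tidy.rosetta_cv <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold", names_to = "stage", values_to = "auc") |>
    dplyr::mutate(stage = sub("auc_", "", .data$stage))
}

#' One-row cross-validation summary
#' @param x A `rosetta_cv`.
#' @param ... Unused.
#' @return Tibble with `k_folds`, `auc_stage1`, `auc_stage2`.
#' @export
#' @exportS3Method generics::glance
glance.rosetta_cv <- function(x, ...) {
  tibble::tibble(
    k_folds = max(x$folds$fold),
    auc_stage1 = x$pooled$auc[x$pooled$stage == "stage1"],
    auc_stage2 = x$pooled$auc[x$pooled$stage == "stage2"]
  )
}

#' Out-of-fold score distributions
#' @param object A `rosetta_cv`.
#' @param ... Unused.
#' @return A ggplot of gate scores by true condition.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.rosetta_cv <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$p_condition, fill = .data$condition)
  ) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(
      x = "out-of-fold gate probability", y = "children",
      title = "Cross-validated gate scores by condition"
    )
}

combined_importance <- function(model) {
  imp <- function(booster) {
    tab <- tryCatch(xgboost::xgb.importance(model = booster), error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) {
      return(setNames(numeric(0), character(0)))
    }
    setNames(tab$Gain, tab$Feature)
  }
  i1 <- imp(model$stage1)
  i2 <- imp(model$stage2)
  feats <- model$selected_features
  total <- setNames(numeric(length(feats)), feats)
  total[names(i1)] <- total[names(i1)] + i1
  total[names(i2)] <- total[names(i2)] + i2
  if (max(total) > 0) total <- total / max(total)
  total
}

#' Iterative worst-row / worst-feature pruning
#'
#' Starting from all rows and features, repeatedly evaluates the
#' cross-validated objective, then removes the single globally worst
#' element: the candidate feature is the one with the lowest
#' normalized-importance-times-coverage product (importance from the
#' boosted trees, coverage the post-imputation valid fraction), the
#' candidate row the one with the highest failed-cell fraction, and
#' whichever of the two is worse on the common badness scale (one minus
#' the feature product vs the row's failed fraction) is dropped. Pruning
#' stops once the objective has not improved for `prune_patience`
#' iterations (or a stage would become untrainable) and returns the
#' best-scoring state seen.
#'
#' @inheritParams cross_validate
#' @return List with `child_ids` and `features` of the best state, and
#'   `trace`: one row per iteration with the CV objective and the element
#'   removed afterwards.
#' @export
iterative_prune <- function(x, labels, config = classifier_config()) {
  fm <- feature_matrix(x)
  cond_all <- align_labels(fm$child_id, labels)
  failed <- is.na(fm$x)
  labels <- tibble::tibble(child_id = fm$child_id, condition = cond_all)

  rows <- seq_len(nrow(fm$x))
  feats <- colnames(fm$x)
  objective <- function(p) {
    switch(config$prune_objective,
      mean = mean(p$auc),
      stage1 = p$auc[p$stage == "stage1"],
      stage2 = p$auc[p$stage == "stage2"]
    )
  }

  trace <- tibble::tibble(
    iteration = integer(), n_rows = integer(), n_features = integer(),
    score = double(), removed_type = character(), removed = character()
  )
  best <- list(score = -Inf, rows = rows, feats = feats)
  since_best <- 0L
  iter <- 0L

  repeat {
    iter <- iter + 1L
    dat <- tibble::as_tibble(cbind(
      tibble::tibble(child_id = fm$child_id[rows]),
      as.data.frame(fm$x[rows, feats, drop = FALSE])
    ))
    cv <- cross_validate(dat, labels,
      config = classifier_config(
        k_folds = config$k_folds, gate_threshold = config$gate_threshold,
        max_depth = config$max_depth, nrounds = config$nrounds, eta = config$eta,
        prune_patience = config$prune_patience,
        prune_objective = config$prune_objective,
        seed = stage_seed(config$seed, iter)
      )
    )
    score <- objective(cv$pooled)
    if (score > best$score) {
      best <- list(score = score, rows = rows, feats = feats)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }

    # score candidates on the current state
    model <- train_two_stage(dat, labels, config)
    imp <- combined_importance(model)
    cov <- 1 - colMeans(failed[rows, feats, drop = FALSE])
    feat_bad <- 1 - unname(imp[feats]) * cov
    row_bad <- rowMeans(failed[rows, feats, drop = FALSE])
    # ties on badness break toward lower coverage, then lower importance
    worst_feat <- feats[order(-feat_bad, cov, unname(imp[feats]))][1]
    worst_row <- which.max(row_bad)

    remove_row <- max(row_bad) > max(feat_bad)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      iteration = iter, n_rows = length(rows), n_features = length(feats),
      score = score,
      removed_type = if (remove_row) "row" else "feature",
      removed = if (remove_row) fm$child_id[rows[worst_row]] else worst_feat
    ))

    if (since_best >= config$prune_patience) break
    # feasibility guards: never prune a stage below trainability
    if (remove_row) {
      remaining <- cond_all[rows[-worst_row]]
      if (length(feats) < 2 || any(table(remaining) < config$k_folds)) break
      rows <- rows[-worst_row]
    } else {
      if (length(feats) <= 2) break
      feats <- setdiff(feats, worst_feat)
    }
  }

  list(
    child_ids = fm$child_id[best$rows],
    features = best$feats,
    score = best$score,
    trace = trace
  )
}
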