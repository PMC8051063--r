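test_that("a fully observed matrix comes back unchanged with zero imputed cells", {
  m <- rosetta_matrix(
    tibble::tibble(
      child_id = sprintf("c%d", 1:6),
      Q1 = c(1L, 2L, 3L, 1L, 2L, 3L),
      Q2 = c(3L, 3L, 2L, 1L, 1L, 2L)
    ),
    n_codes = c(Q1 = 3L, Q2 = 3L)
  )
  labels <- tibble::tibble(child_id = m$child_id, condition = rep(c("autism", "adhd"), 3))
  out <- impute_ensemble(m, labels, impute_config(min_class_samples = 1, subset_size_range = c(1, 1)))
  expect_equal(as.matrix(out$values[c("Q1", "Q2")]), as.matrix(m[c("Q1", "Q2")]),
    ignore_attr = TRUE
  )
  expect_true(all(as.matrix(out$provenance[c("Q1", "Q2")]) == "observed"))
})

test_that("the class-size guard failing on every draw leaves cells failed", {
  m <- rosetta_matrix(
    tibble::tibble(
      child_id = sprintf("c%d", 1:8),
      Q1 = c(1L, 2L, NA, NA, 1L, 2L, 1L, 2L),
      Q2 = 1:8 %% 3L + 1L,
      Q3 = rep(1:2, 4)
    ),
    n_codes = c(Q1 = 3L, Q2 = 3L, Q3 = 3L)
  )
  labels <- tibble::tibble(child_id = m$child_id, condition = rep(c("autism", "adhd"), 4))
  out <- impute_ensemble(m, labels, impute_config(
    min_class_samples = 100, # unattainable with 8 rows
    subset_size_range = c(1, 2), max_draws_per_feature = 20
  ))
  expect_true(all(as.matrix(out$provenance[["Q1"]])[is.na(m$Q1)] == "failed"))
  expect_true(all(is.na(out$values$Q1[is.na(m$Q1)])))
})

test_that("coverage profile equals direct counting on a random mask", {
  withr::with_seed(10, {
    vals <- matrix(sample(c(1:3, NA), 80, replace = TRUE), nrow = 10)
    colnames(vals) <- sprintf("Q%d", 1:8)
    m <- rosetta_matrix(
      tibble::as_tibble(cbind(tibble::tibble(child_id = sprintf("c%d", 1:10)), as.data.frame(vals))),
      n_codes = setNames(rep(3L, 8), colnames(vals))
    )
  })
  cp <- coverage_profile(m)
  expect_equal(cp$questions$fraction, unname(colMeans(!is.na(vals))))
  expect_equal(cp$children$fraction, unname(rowMeans(!is.na(vals))))
  expect_equal(sum(cp$questions$n_valid), sum(cp$children$n_valid))
  # fully observed and empty-row limits
  vals2 <- vals
  vals2[2, ] <- NA
  m2 <- rosetta_matrix(
    tibble::as_tibble(cbind(tibble::tibble(child_id = sprintf("c%d", 1:10)), as.data.frame(vals2))),
    n_codes = setNames(rep(3L, 8), colnames(vals))
  )
  expect_equal(coverage_profile(m2)$children$fraction[2], 0)
})

test_that("the constraint loop matches a naive independent re-implementation", {
  # deterministic learner (training-column mean) so both routes are exact
  mean_learner <- function(xtr, ytr, xte, seed) rep(mean(ytr), nrow(xte))

  withr::with_seed(77, {
    n <- 40
    vals <- matrix(sample(1:3, n * 5, replace = TRUE), nrow = n)
    colnames(vals) <- sprintf("Q%d", 1:5)
    vals[sample(length(vals), 30)] <- NA
  })
  m <- rosetta_matrix(
    tibble::as_tibble(cbind(tibble::tibble(child_id = sprintf("c%02d", 1:40)), as.data.frame(vals))),
    n_codes = setNames(rep(3L, 5), colnames(vals))
  )
  labels <- tibble::tibble(
    child_id = m$child_id,
    condition = rep(c("autism", "adhd"), 20)
  )
  config <- impute_config(
    min_class_samples = 5, min_predictions = 3,
    subset_size_range = c(1, 3), max_draws_per_feature = 50, seed = 123
  )
  got <- rosettabank:::impute_engine(m, labels, config, learner = mean_learner)

  # naive re-implementation: plain loops over the same draw sequence
  obs <- !is.na(vals)
  cls <- labels$condition
  out_vals <- vals
  storage.mode(out_vals) <- "double"
  prov <- ifelse(obs, "observed", "failed")
  set.seed(config$seed)
  for (f in colnames(vals)[colSums(!obs) > 0]) {
    target <- which(!obs[, f])
    others <- setdiff(colnames(vals), f)
    sums <- numeric(length(target))
    nacc <- integer(length(target))
    for (draw in seq_len(config$max_draws_per_feature)) {
      if (all(nacc >= config$min_predictions)) break
      s_size <- sample(1:3, 1)
      S <- sample(others, s_size)
      cover <- rowSums(!obs[, S, drop = FALSE]) == 0
      train <- which(obs[, f] & cover)
      if (length(train) < 2) next
      if (any(table(factor(cls[train], levels = c("adhd", "autism"))) < 5)) next
      pred <- which(cover[target])
      if (!length(pred)) next
      sample.int(.Machine$integer.max, 1) # mirrors the engine's learner seed draw
      sums[pred] <- sums[pred] + mean(vals[train, f])
      nacc[pred] <- nacc[pred] + 1L
    }
    done <- nacc >= config$min_predictions
    out_vals[target[done], f] <- pmin(pmax(sums[done] / nacc[done], 1), 3)
    prov[target[done], f] <- "imputed"
  }
  qs <- colnames(vals)
  expect_equal(as.matrix(got$values[qs]), out_vals, ignore_attr = TRUE)
  expect_equal(as.matrix(got$provenance[qs]), prov, ignore_attr = TRUE)
})

test_that("observed cells are conserved and imputed cells respect the floor and range", {
  smc <- make_small_cohort_matrix(n_questions = 10, seed = 4)
  mh <- mask_holdout(smc$matrix, 0.15, seed = 21)
  cfg <- impute_config(
    min_class_samples = 15, min_predictions = 5,
    subset_size_range = c(3, 5), trees_per_forest = 25,
    max_draws_per_feature = 50, seed = 8
  )
  out <- impute_ensemble(mh$masked, smc$labels, cfg)
  qs <- matrix_questions(out)
  vals <- as.matrix(out$values[qs])
  prov <- as.matrix(out$provenance[qs])
  counts <- as.matrix(out$prediction_counts[qs])
  orig <- as.matrix(mh$masked[qs])

  expect_true(all(vals[!is.na(orig)] == orig[!is.na(orig)]))
  expect_true(all(prov[!is.na(orig)] == "observed"))
  expect_true(all(counts[prov == "imputed"] >= cfg$min_predictions))
  nc <- out$n_codes
  for (q in qs) {
    imp <- vals[prov[, q] == "imputed", q]
    expect_true(all(imp >= 1 & imp <= nc[[q]]))
  }
  # determinism under a fixed seed
  out2 <- impute_ensemble(mh$masked, smc$labels, cfg)
  expect_identical(out2$values, out$values)
  expect_identical(out2$prediction_counts, out$prediction_counts)

  # degenerate input: nothing observed anywhere
  empty <- rosetta_matrix(
    tibble::tibble(child_id = c("a", "b"), Q1 = NA_integer_, Q2 = NA_integer_),
    n_codes = c(Q1 = 3L, Q2 = 3L)
  )
  expect_error(
    impute_ensemble(empty, tibble::tibble(child_id = c("a", "b"), condition = c("autism", "adhd"))),
    "degenerate"
  )
})
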