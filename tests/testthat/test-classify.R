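cfg_fast <- classifier_config(k_folds = 4, nrounds = 40, seed = 3)

test_that("perfectly separable features give training AUC 1 and exact gate logic", {
  fd <- make_feature_data(
    n_per_class = c(autism = 30, adhd = 20, neither = 20),
    n_informative = 4, n_noise = 4, shift = 8, seed = 2
  )
  model <- train_two_stage(fd$data, fd$labels, cfg_fast)
  pred <- predict(model, fd$data)
  pos <- fd$labels$condition != "neither"
  r <- rank(pred$p_condition)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  expect_equal(auc, 1.0)
  expect_gt(mean(pred$label[pos] == fd$labels$condition[pos]), 0.95)
})

test_that("an all-neither cohort cannot train the discriminator", {
  fd <- make_feature_data(n_per_class = c(autism = 0, adhd = 0, neither = 30), seed = 1)
  expect_error(train_two_stage(fd$data, fd$labels, cfg_fast), "stage 1")
  fd2 <- make_feature_data(n_per_class = c(autism = 30, adhd = 0, neither = 20), seed = 1)
  expect_error(train_two_stage(fd2$data, fd2$labels, cfg_fast), "stage 2")
})

test_that("the discriminator is consulted exactly for gated rows", {
  fd <- make_feature_data(
    n_per_class = c(autism = 25, adhd = 20, neither = 25),
    shift = 3, seed = 4
  )
  model <- train_two_stage(fd$data, fd$labels, cfg_fast)
  pred <- predict(model, fd$data)
  expect_equal(attr(pred, "n_stage2"), sum(pred$p_condition >= model$gate_threshold))
  expect_true(all(is.na(pred$p_autism[pred$p_condition < model$gate_threshold])))
  expect_true(all(pred$label[pred$p_condition < model$gate_threshold] == "neither"))

  # brute-force application of the two decision rules to the probabilities
  manual <- ifelse(pred$p_condition < model$gate_threshold, "neither",
    ifelse(pred$p_autism >= 0.5, "autism", "adhd")
  )
  expect_identical(pred$label, manual)

  # degenerate threshold: nothing passes the gate
  model$gate_threshold <- 1.0
  pred1 <- predict(model, fd$data)
  expect_true(all(pred1$label == "neither"))
  expect_equal(attr(pred1, "n_stage2"), 0L)

  # missing selected features at predict time
  expect_error(predict(model, fd$data[, 1:3]), "missing selected features")
})

test_that("stratified folds balance classes and pooled AUC matches a rank oracle", {
  fd <- make_feature_data(
    n_per_class = c(autism = 33, adhd = 21, neither = 26),
    shift = 2, seed = 5
  )
  cv <- cross_validate(fd$data, fd$labels, cfg_fast)
  # fold sizes differ by at most one within each class
  tab <- table(
    fd$labels$condition[match(cv$folds$child_id, fd$labels$child_id)],
    cv$folds$fold
  )
  expect_true(all(apply(tab, 1, function(r) diff(range(r)) <= 1)))

  # Mann-Whitney rank recomputation of the pooled stage-1 AUC
  pos <- cv$scores$condition != "neither"
  r <- rank(cv$scores$p_condition)
  auc_rank <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  expect_equal(cv$pooled$auc[cv$pooled$stage == "stage1"], auc_rank, tolerance = 1e-10)

  auc2 <- cv$pooled$auc[cv$pooled$stage == "stage2"]
  sc2 <- cv$scores[pos, ]
  isaut <- sc2$condition == "autism"
  r2 <- rank(sc2$p_autism)
  auc2_rank <- (sum(r2[isaut]) - sum(isaut) * (sum(isaut) + 1) / 2) /
    (sum(isaut) * sum(!isaut))
  expect_equal(auc2, auc2_rank, tolerance = 1e-10)

  expect_error(
    cross_validate(fd$data, fd$labels, classifier_config(k_folds = 30)),
    "fewer rows than folds"
  )
})

test_that("cross-validation is reproducible under a fixed seed", {
  fd <- make_feature_data(n_per_class = c(autism = 20, adhd = 15, neither = 15), seed = 6)
  a <- cross_validate(fd$data, fd$labels, cfg_fast)
  b <- cross_validate(fd$data, fd$labels, cfg_fast)
  expect_identical(a$scores, b$scores)
  expect_identical(glance(a), glance(b))
})

test_that("pruning removes a dead feature before informative ones and keeps its best state", {
  fd <- make_feature_data(
    n_per_class = c(autism = 24, adhd = 16, neither = 16),
    n_informative = 3, n_noise = 5, shift = 4, seed = 7
  )
  # a feature that is always unusable: zero coverage, zero importance
  fd$data$dead <- NA_real_
  cfg <- classifier_config(k_folds = 4, nrounds = 30, prune_patience = 2, seed = 1)
  res <- iterative_prune(fd$data, fd$labels, cfg)
  removed_feats <- res$trace$removed[res$trace$removed_type == "feature"]
  expect_equal(removed_feats[1], "dead")
  # trace is bounded by one removal per element
  expect_lte(nrow(res$trace), nrow(fd$data) + ncol(fd$data) - 1)
  # the returned state is the best recorded score
  expect_equal(res$score, max(res$trace$score))
  # informative features survive
  expect_true(all(fd$informative %in% res$features))
})

test_that("tidy and glance summarise cross-validation results", {
  fd <- make_feature_data(n_per_class = c(autism = 16, adhd = 12, neither = 12), seed = 8)
  cv <- cross_validate(fd$data, fd$labels, classifier_config(k_folds = 3, nrounds = 20))
  td <- tidy(cv)
  expect_setequal(unique(td$stage), c("stage1", "stage2"))
  expect_equal(nrow(td), 6L)
  gl <- glance(cv)
  expect_true(all(gl$auc_stage1 >= 0 & gl$auc_stage1 <= 1))
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})
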