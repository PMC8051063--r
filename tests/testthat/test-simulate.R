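test_that("class counts and structural invariants hold", {
  cw <- synthetic_crosswalk(n_questions = 10)
  cfg <- cohort_config(n_per_class = c(autism = 100, adhd = 50, neither = 50), seed = 1)
  coh <- simulate_cohort(cw, cfg)
  expect_equal(unname(table(coh$truth$condition)[c("autism", "adhd", "neither")]),
    c(100L, 50L, 50L),
    ignore_attr = TRUE
  )
  # every response's child is in truth and belongs to an assigned version
  expect_true(all(coh$responses$child_id %in% coh$truth$child_id))
  rkey <- paste(coh$responses$child_id, coh$responses$instrument, coh$responses$version)
  akey <- paste(coh$assignments$child_id, coh$assignments$instrument, coh$assignments$version)
  expect_true(all(rkey %in% akey))
  # raw answers inside each item's native scale
  ksz <- cw$items$scale_size[match(
    paste(coh$responses$instrument, coh$responses$version, coh$responses$item),
    paste(cw$items$instrument, cw$items$version, cw$items$item)
  )]
  expect_true(all(coh$responses$raw >= 1 & coh$responses$raw <= ksz))
  # assignment range respected
  per_child <- table(coh$assignments$child_id)
  expect_true(all(per_child >= 1 & per_child <= 2))
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  cw <- synthetic_crosswalk(n_questions = 8)
  cfg <- cohort_config(n_per_class = c(autism = 30, adhd = 20, neither = 20), seed = 42)
  a <- simulate_cohort(cw, cfg)
  b <- simulate_cohort(cw, cfg)
  expect_identical(a$theta, b$theta)
  expect_identical(a$responses, b$responses)
})

test_that("changing the assignment range leaves latent severities untouched", {
  cw <- synthetic_crosswalk(n_questions = 8)
  base <- cohort_config(n_per_class = c(autism = 30, adhd = 20, neither = 20), seed = 5)
  wide <- cohort_config(
    n_per_class = c(autism = 30, adhd = 20, neither = 20),
    instruments_per_child = c(2, 4), seed = 5
  )
  expect_identical(simulate_cohort(cw, base)$theta, simulate_cohort(cw, wide)$theta)
})

test_that("expected raw answers are monotone in latent severity (Monte-Carlo oracle)", {
  # oracle: direct Monte-Carlo of the threshold response model at fixed theta
  mc_mean <- function(theta, k, item_sd = 0.5, n = 4000) {
    z <- theta + withr::with_seed(1234, rnorm(n, 0, item_sd))
    cuts <- seq(0.5, 2.0, length.out = k - 1)
    mean(1 + rowSums(outer(z, cuts, `>`)))
  }
  for (k in c(3, 4, 5)) {
    ms <- vapply(c(-1, 0, 0.8, 1.6, 2.5, 3.5), mc_mean, 0, k = k)
    expect_false(is.unsorted(ms))
  }

  # and the simulator's responses reproduce the oracle's marginal means:
  # one question, many children at a fixed severity via zero noise around a shift
  cw <- synthetic_crosswalk(n_questions = 6)
  eff <- default_effects()
  eff$shift[eff$condition == "autism"] <- 1.6
  cfg <- cohort_config(
    n_per_class = c(autism = 300, adhd = 2, neither = 2),
    effects = eff, noise_sd = 1e-6, item_noise_sd = 0.5, seed = 11,
    instruments_per_child = c(15, 15)
  )
  coh <- simulate_cohort(cw, cfg)
  aut <- coh$responses[coh$responses$child_id %in%
    coh$truth$child_id[coh$truth$condition == "autism"], ]
  ksz <- cw$items$scale_size[match(
    paste(aut$instrument, aut$version, aut$item),
    paste(cw$items$instrument, cw$items$version, cw$items$item)
  )]
  for (k in unique(ksz)) {
    expect_equal(mean(aut$raw[ksz == k]), mc_mean(1.6, k), tolerance = 0.05)
  }
})

test_that("zero effects leave per-class response marginals indistinguishable", {
  cw <- synthetic_crosswalk(n_questions = 8)
  eff <- default_effects()
  eff$shift <- 0
  pvals <- vapply(1:20, function(s) {
    coh <- simulate_cohort(cw, cohort_config(
      n_per_class = c(autism = 60, adhd = 60, neither = 60),
      effects = eff, seed = s
    ))
    cond <- coh$truth$condition[match(coh$responses$child_id, coh$truth$child_id)]
    suppressWarnings(stats::chisq.test(table(cond, coh$responses$raw))$p.value)
  }, 0)
  # no signal by construction: at alpha = 0.01 essentially all seeds look null
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("class-conditional mean codes order as configured under default effects", {
  cw <- synthetic_crosswalk(n_questions = 15)
  coh <- simulate_cohort(cw, cohort_config(
    n_per_class = c(autism = 80, adhd = 80, neither = 80), seed = 2,
    instruments_per_child = c(15, 15)
  ))
  m <- translate(cw, coh$responses, children = coh$truth$child_id)
  cond <- coh$truth$condition[match(m$child_id, coh$truth$child_id)]
  social_qs <- grep("_Social_|_LanguageCommunication_", matrix_questions(m), value = TRUE)
  adhd_qs <- grep("_Attention_|_Hyperactivity_|_Impulsivity_", matrix_questions(m), value = TRUE)
  mean_codes <- function(qs, cl) mean(as.matrix(m[cond == cl, qs]), na.rm = TRUE)
  expect_gt(mean_codes(social_qs, "autism"), mean_codes(social_qs, "adhd"))
  expect_gt(mean_codes(social_qs, "autism"), mean_codes(social_qs, "neither"))
  expect_gt(mean_codes(adhd_qs, "adhd"), mean_codes(adhd_qs, "autism"))
  expect_gt(mean_codes(adhd_qs, "adhd"), mean_codes(adhd_qs, "neither"))
  # configured asymmetry: autism gets a milder attention shift than ADHD
  eff <- default_effects()
  att <- "Cognitive/Executive Functioning/Attention"
  expect_lt(
    eff$shift[eff$condition == "autism" & eff$leaf == att],
    eff$shift[eff$condition == "adhd" & eff$leaf == att]
  )
  expect_true(all(eff$shift[eff$condition == "neither"] == 0))
})

test_that("mask_holdout partitions observed cells deterministically", {
  smc <- make_small_cohort_matrix(n_questions = 8, seed = 3,
    n_per_class = c(autism = 15, adhd = 10, neither = 10)
  )
  m <- smc$matrix
  qs <- matrix_questions(m)
  n_obs <- sum(!is.na(as.matrix(m[qs])))

  mh <- mask_holdout(m, 0.2, seed = 9)
  expect_equal(nrow(mh$holdout), floor(0.2 * n_obs))
  # conservation: masked observed + holdout = original observed
  expect_equal(sum(!is.na(as.matrix(mh$masked[qs]))) + nrow(mh$holdout), n_obs)
  # held-out values match the original cells
  for (i in seq_len(min(20, nrow(mh$holdout)))) {
    expect_equal(
      m[[mh$holdout$question_id[i]]][m$child_id == mh$holdout$child_id[i]],
      mh$holdout$value[i]
    )
  }
  # determinism and fraction validation
  mh2 <- mask_holdout(m, 0.2, seed = 9)
  expect_identical(mh2$holdout, mh$holdout)
  expect_identical(tibble::as_tibble(mh2$masked), tibble::as_tibble(mh$masked))
  expect_error(mask_holdout(m, 0, seed = 1), "between 0 and 1")
  expect_error(mask_holdout(m, 1, seed = 1), "between 0 and 1")
  # vanishing fraction: no cells masked
  tiny <- mask_holdout(m, 1e-6, seed = 1)
  expect_equal(nrow(tiny$holdout), 0L)
})
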