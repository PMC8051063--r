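adapt_cw <- load_fixture("adaptability_excerpt")
rc <- "Cognoa_Cognitive_Behavioral_Emotional_Adaptability_RoutineChange"

test_that("the most severe ADI-R routine-change answer lands on the top code", {
  resp <- tibble::tibble(
    child_id = "c1", instrument = "ADI-R", version = "Standard",
    item = "74", raw = 4L
  )
  m <- translate(adapt_cw, resp)
  expect_equal(m[[rc]][m$child_id == "c1"], 3L)
  # and the two most severe source choices collapse onto the same code
  resp$raw <- 3L
  expect_equal(translate(adapt_cw, resp)[[rc]][1], 3L)
})

test_that("children without responses become all-missing rows", {
  resp <- tibble::tibble(
    child_id = "c1", instrument = "CBCL", version = "School-age",
    item = "21", raw = 2L
  )
  m <- translate(adapt_cw, resp, children = c("c1", "ghost"))
  expect_setequal(m$child_id, c("c1", "ghost"))
  qcols <- matrix_questions(m)
  expect_true(all(is.na(unlist(m[m$child_id == "ghost", qcols]))))
  expect_equal(m[[rc]][m$child_id == "c1"], 2L)
})

test_that("aggregation policies match a brute-force re-aggregation of the long table", {
  cw <- make_random_crosswalk(n_instruments = 4, n_questions = 8, seed = 9)
  withr::with_seed(99, {
    long <- cw$mappings[sample.int(nrow(cw$mappings), 60, replace = TRUE), ]
    resp <- tibble::tibble(
      child_id = sample(sprintf("c%d", 1:12), 60, replace = TRUE),
      instrument = long$instrument, version = long$version, item = long$item
    )
    ksz <- cw$items$scale_size[match(
      paste(resp$instrument, resp$item),
      paste(cw$items$instrument, cw$items$item)
    )]
    resp$raw <- vapply(ksz, function(k) sample.int(k, 1), 0L)
  })

  # independent oracle: recode and group by hand
  amap_of <- setNames(cw$mappings$answer_map, paste(cw$mappings$instrument, cw$mappings$item))
  q_of <- setNames(cw$mappings$question_id, paste(cw$mappings$instrument, cw$mappings$item))
  codes <- mapply(function(i, it, r) amap_of[[paste(i, it)]][r], resp$instrument, resp$item, resp$raw)
  key <- paste(resp$child_id, q_of[paste(resp$instrument, resp$item)])

  for (policy in c("max", "mean")) {
    m <- translate(cw, resp, policy = policy)
    agg <- tapply(codes, key, function(v) {
      if (policy == "max") max(v) else as.integer(floor(mean(v) + 0.5))
    })
    for (k in names(agg)) {
      parts <- strsplit(k, " ")[[1]]
      expect_equal(m[[parts[2]]][m$child_id == parts[1]], as.integer(agg[[k]]),
        info = paste(policy, k)
      )
    }
  }
})

test_that("translation is invariant to response row order and repeatable", {
  cw <- make_random_crosswalk(seed = 5)
  withr::with_seed(7, {
    long <- cw$mappings[sample.int(nrow(cw$mappings), 40, replace = TRUE), ]
    resp <- tibble::tibble(
      child_id = sample(sprintf("c%d", 1:8), 40, replace = TRUE),
      instrument = long$instrument, version = long$version, item = long$item,
      raw = 1L
    )
  })
  for (policy in c("max", "mean", "first")) {
    m1 <- translate(cw, resp, policy = policy)
    m2 <- translate(cw, resp[rev(seq_len(nrow(resp))), ], policy = policy)
    m3 <- translate(cw, resp, policy = policy)
    expect_equal(m2, m1, info = policy)
    expect_equal(m3, m1, info = policy)
  }
})

test_that("unknown items and out-of-range answers fail with row context", {
  expect_error(
    translate(adapt_cw, tibble::tibble(
      child_id = "c1", instrument = "ADI-R", version = "Standard",
      item = "999", raw = 1L
    )),
    "unknown item"
  )
  expect_error(
    translate(adapt_cw, tibble::tibble(
      child_id = "c1", instrument = "ADI-R", version = "Standard",
      item = "74", raw = 5L
    )),
    "out of range"
  )
})

test_that("matrix cells always sit inside their question's code range", {
  cw <- synthetic_crosswalk(n_questions = 12)
  coh <- simulate_cohort(cw, cohort_config(
    n_per_class = c(autism = 20, adhd = 15, neither = 15), seed = 3
  ))
  m <- translate(cw, coh$responses, children = coh$truth$child_id)
  nc <- attr(m, "n_codes")
  for (q in matrix_questions(m)) {
    v <- m[[q]][!is.na(m[[q]])]
    expect_true(all(v >= 1 & v <= nc[[q]]))
  }
})

test_that("matrix CSV round-trips with empty cells as missing", {
  smc <- make_small_cohort_matrix(n_questions = 8, seed = 2,
    n_per_class = c(autism = 10, adhd = 8, neither = 8)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(smc$matrix, path)
  m2 <- read_matrix_csv(path, attr(smc$matrix, "n_codes"))
  expect_equal(tibble::as_tibble(m2), tibble::as_tibble(smc$matrix))
})
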