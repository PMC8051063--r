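# Small in-code builders shared across tests.

# A random complete crosswalk over `n_instruments` single-version
# instruments and `n_questions` questions; each question draws a nonempty
# random instrument subset, one item per (instrument, question).
make_random_crosswalk <- function(n_instruments = 3, n_questions = 6, seed = 1) {
  withr::with_seed(seed, {
    insts <- paste0("Inst", seq_len(n_instruments))
    sizes <- sample(3:5, n_instruments, replace = TRUE)
    registry <- tibble::tibble(
      instrument = insts, version = "v1", reporter = "parent",
      n_items = 10L, scale_kind = "frequency", scale_size = sizes
    )
    qids <- sprintf("Q%02d", seq_len(n_questions))
    rows <- list()
    n_codes <- integer(n_questions)
    for (q in seq_len(n_questions)) {
      sub <- sample(insts, sample.int(n_instruments, 1))
      n_codes[q] <- answer_code_count(sizes[match(sub, insts)])
      rows[[q]] <- tibble::tibble(
        instrument = sub, version = "v1",
        item = paste0("i", q), question_id = qids[q],
        scale_size = sizes[match(sub, insts)]
      )
    }
    long <- dplyr::bind_rows(rows)
    items <- dplyr::transmute(long,
      instrument, version, item,
      subject = paste("toy", item), scale_size
    )
    mappings <- dplyr::transmute(long, instrument, version, item, question_id)
    mappings$answer_map <- purrr::map2(
      long$scale_size, n_codes[match(mappings$question_id, qids)],
      default_answer_map
    )
    questions <- tibble::tibble(
      question_id = qids,
      leaf = rep(hierarchy_leaves(build_default_hierarchy())[1:3], length.out = n_questions),
      n_codes = n_codes
    )
    crosswalk(registry, items, questions, mappings, hierarchy = build_default_hierarchy())
  })
}

# A fully observed feature tibble with class-shifted informative columns.
make_feature_data <- function(n_per_class = c(autism = 60, adhd = 40, neither = 40),
                              n_informative = 5, n_noise = 20, shift = 2,
                              seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per_class)
    cond <- rep(names(n_per_class), times = n_per_class)
    x <- matrix(rnorm(n * (n_informative + n_noise)), nrow = n)
    colnames(x) <- c(
      sprintf("inf%02d", seq_len(n_informative)),
      sprintf("noise%02d", seq_len(n_noise))
    )
    half <- ceiling(n_informative / 2)
    x[cond == "autism", seq_len(half)] <- x[cond == "autism", seq_len(half)] + shift
    x[cond == "adhd", (half + 1):n_informative] <-
      x[cond == "adhd", (half + 1):n_informative] + shift
    list(
      data = tibble::as_tibble(cbind(
        tibble::tibble(child_id = sprintf("c%03d", seq_len(n))),
        as.data.frame(x)
      )),
      labels = tibble::tibble(child_id = sprintf("c%03d", seq_len(n)), condition = cond),
      informative = colnames(x)[seq_len(n_informative)]
    )
  })
}

# A small fused matrix with latent class structure and uniform missingness,
# for imputation tests that do not need the full simulator.
make_small_cohort_matrix <- function(n_questions = 12, seed = 1,
                                     n_per_class = c(autism = 60, adhd = 45, neither = 45)) {
  cw <- synthetic_crosswalk(n_questions = n_questions)
  cfg <- cohort_config(
    n_per_class = n_per_class,
    instruments_per_child = c(15, 15), seed = seed
  )
  coh <- simulate_cohort(cw, cfg)
  m <- translate(cw, coh$responses, children = coh$truth$child_id)
  list(matrix = m, labels = coh$truth, crosswalk = cw)
}
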