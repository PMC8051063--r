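#' Cohort simulation configuration
#'
#' Configures the latent-trait cohort generator. Defaults emulate the
#' multi-instrument case-study regime at desk scale: 746 children in
#' class proportions 588 autism / 69 ADHD / 89 neither (one fifth of the
#' 2,941 / 343 / 447 source cohort), 15 instrument versions with each child
#' completing only 1--2 of them ("little overlap").
#'
#' @param n_per_class Named counts for `autism`, `adhd`, `neither`.
#' @param effects Leaf-by-condition severity-shift table from
#'   [default_effects()] (columns `leaf`, `condition`, `shift`).
#' @param noise_sd Child-level latent noise standard deviation.
#' @param item_noise_sd Item-level response noise standard deviation.
#' @param instruments_per_child Inclusive range of instrument versions a
#'   child completes.
#' @param version_weights Optional sampling weights over the registry's
#'   instrument versions.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return A `rosetta_cohort_config` list.
#' @export
cohort_config <- function(n_per_class = c(autism = 588, adhd = 69, neither = 89),
                          effects = default_effects(),
                          noise_sd = 0.5,
                          item_noise_sd = 0.5,
                          instruments_per_child = c(1, 2),
                          version_weights = NULL,
                          seed = 7) {
  stopifnot(
    all(n_per_class >= 0), noise_sd > 0, item_noise_sd > 0,
    length(instruments_per_child) == 2, instruments_per_child[1] >= 1
  )
  if (is.null(names(n_per_class)) || !all(c("autism", "adhd", "neither") %in% names(n_per_class))) {
    abort("n_per_class must be named with autism, adhd, neither")
  }
  structure(
    list(
      n_per_class = n_per_class, effects = tibble::as_tibble(effects),
      noise_sd = noise_sd, item_noise_sd = item_noise_sd,
      instruments_per_child = as.integer(instruments_per_child),
      version_weights = version_weights, seed = as.integer(seed)
    ),
    class = "rosetta_cohort_config"
  )
}

#' Default condition effects on latent leaf severities
#'
#' Documented default severity shifts (in latent standard-normal units) per
#' condition and leaf category: autism shifts the Social,
#' Language & Communication and Sensory leaves by `+2.5` (plus a mild
#' `+0.5` on Attention); ADHD shifts Attention, Hyperactivity, Impulsivity
#' and Inhibitory Control by `+2.5` and Memory by `+1.5`; the neither class
#' has all shifts zero. Every other (condition, leaf) shift is zero.
#'
#' @param leaves Leaf ids to cover; defaults to all leaves of the default
#'   hierarchy.
#' @return Tibble with columns `leaf`, `condition`, `shift`, fully crossed
#'   over the three conditions.
#' @export
default_effects <- function(leaves = hierarchy_leaves(build_default_hierarchy())) {
  grid <- tidyr::expand_grid(
    leaf = leaves,
    condition = c("autism", "adhd", "neither")
  )
  grid$shift <- 0
  social <- grepl("^Cognitive/Behavioral/Social/", leaves) |
    grepl("^Cognitive/Language & Communication/", leaves) |
    grepl("^Cognitive/Behavioral/Sensory/", leaves)
  adhd_strong <- leaves %in% paste0(
    "Cognitive/Executive Functioning/",
    c("Attention", "Hyperactivity", "Impulsivity", "Inhibitory Control")
  )
  att <- leaves == "Cognitive/Executive Functioning/Attention"
  mem <- leaves == "Cognitive/Executive Functioning/Memory"
  set_shift <- function(grid, cond, lvs, value) {
    idx <- grid$condition == cond & grid$leaf %in% lvs
    grid$shift[idx] <- value
    grid
  }
  grid <- set_shift(grid, "autism", leaves[social], 2.5)
  grid <- set_shift(grid, "autism", leaves[att], 0.5)
  grid <- set_shift(grid, "adhd", leaves[adhd_strong], 2.5)
  grid <- set_shift(grid, "adhd", leaves[mem], 1.5)
  grid
}

#' Synthetic case-study-style crosswalk
#'
#' Builds a complete crosswalk over the packaged 15-version instrument
#' registry for use with [simulate_cohort()]: `n_questions` harmonized
#' questions spread over autism-related (Social, Language & Communication,
#' Sensory), ADHD-related (Executive Functioning) and neutral (Emotional,
#' Somatic) leaves. Each version covers each question with probability
#' `coverage`, with at least `min_versions` versions per question and six
#' questions per version, one item per (version, question). Answer maps use
#' the default severe-end collapse onto the question's consolidated code
#' count (the minimum scale size among its covering versions). The layout
#' is deterministic given `seed`; mark it synthetic wherever it is written.
#'
#' @param n_questions Number of harmonized questions.
#' @param coverage Per-version question coverage probability.
#' @param min_versions Minimum covering versions per question.
#' @param seed Layout seed.
#' @return A complete `rosetta_crosswalk` with the default hierarchy
#'   attached.
#' @export
synthetic_crosswalk <- function(n_questions = 30, coverage = 0.5,
                                min_versions = 4, seed = 20210415) {
  h <- build_default_hierarchy()
  registry <- load_fixture("instrument_registry")
  leaf_pool <- c(
    paste0("Cognitive/Behavioral/Social/", c(
      "Atypicality", "Awareness", "Group Play", "Shared Interests",
      "Withdrawal", "Eye Contact", "Joint Attention", "Imitation"
    )),
    paste0("Cognitive/Language & Communication/", c("Expressive", "Receptive", "Speech")),
    "Cognitive/Behavioral/Sensory/Intrigued",
    paste0("Cognitive/Executive Functioning/", c(
      "Attention", "Hyperactivity", "Impulsivity", "Inhibitory Control", "Memory"
    )),
    paste0("Cognitive/Behavioral/Emotional/", c("Anxiety", "Mood")),
    "Somatic/Sleep"
  )
  leaves <- rep(leaf_pool, length.out = n_questions)
  qids <- sprintf(
    "Cognoa_%s_S%02d",
    vapply(leaves, function(l) leaf_token(h, l), ""), seq_len(n_questions)
  )

  with_seed(seed, {
    cover <- matrix(
      stats::runif(nrow(registry) * n_questions) < coverage,
      nrow = nrow(registry)
    )
    for (q in seq_len(n_questions)) {
      short <- min_versions - sum(cover[, q])
      if (short > 0) {
        cover[sample(which(!cover[, q]), short), q] <- TRUE
      }
    }
    for (v in seq_len(nrow(registry))) {
      short <- 6L - sum(cover[v, ])
      if (short > 0) {
        cover[v, sample(which(!cover[v, ]), short)] <- TRUE
      }
    }
  })

  n_codes <- vapply(seq_len(n_questions), function(q) {
    answer_code_count(registry$scale_size[cover[, q]])
  }, 0L)
  questions <- tibble::tibble(question_id = qids, leaf = leaves, n_codes = n_codes)

  pairs <- which(cover, arr.ind = TRUE)
  items <- tibble::tibble(
    instrument = registry$instrument[pairs[, 1]],
    version = registry$version[pairs[, 1]],
    item = sprintf("i%02d", pairs[, 2]),
    subject = paste0("synthetic item for ", qids[pairs[, 2]]),
    scale_size = registry$scale_size[pairs[, 1]]
  )
  mappings <- tibble::tibble(
    instrument = items$instrument, version = items$version, item = items$item,
    question_id = qids[pairs[, 2]],
    answer_map = purrr::map2(items$scale_size, n_codes[pairs[, 2]], default_answer_map)
  )
  crosswalk(registry, items, questions, mappings, hierarchy = h)
}

#' Simulate a multi-instrument cohort
#'
#' Generative model: each child has a condition (autism / ADHD / neither)
#' and a latent severity per leaf category,
#' `theta = shift(condition, leaf) + Normal(0, noise_sd^2)`. Each child is
#' assigned a small random set of instrument versions (block missingness),
#' and answers every crosswalk item of an assigned version on its native
#' `k`-point scale by thresholding `theta + Normal(0, item_noise_sd^2)` at
#' `k - 1` cut-points equally spaced between 0.5 and 2.0. Latent draws,
#' version assignment and response noise use three disjoint seed streams,
#' so changing `instruments_per_child` does not perturb the latent
#' severities.
#'
#' @param cw A complete `rosetta_crosswalk` (e.g. [synthetic_crosswalk()]).
#' @param config A [cohort_config()].
#' @return A `rosetta_cohort`: list with `truth` (child, condition),
#'   `theta` (wide tibble of latent severities), `assignments`, and
#'   `responses` in the long format accepted by [translate()].
#' @export
simulate_cohort <- function(cw, config = cohort_config()) {
  stopifnot(inherits(cw, "rosetta_crosswalk"), inherits(config, "rosetta_cohort_config"))
  if (nrow(cw$questions) == 0) abort("empty crosswalk")
  leaf_of_q <- setNames(cw$questions$leaf, cw$questions$question_id)
  leaves <- unique(cw$questions$leaf)
  eff <- config$effects
  conds <- names(config$n_per_class)
  missing_leaf <- setdiff(leaves, eff$leaf)
  if (length(missing_leaf)) {
    abort(paste("effects table missing leaf/leaves:", paste(missing_leaf, collapse = ", ")))
  }

  n <- sum(config$n_per_class)
  truth <- tibble::tibble(
    child_id = sprintf("child_%04d", seq_len(n)),
    condition = rep(conds, times = config$n_per_class)
  )

  shift <- matrix(0, nrow = length(conds), ncol = length(leaves),
    dimnames = list(conds, leaves)
  )
  eff_use <- eff[eff$leaf %in% leaves & eff$condition %in% conds, ]
  shift[cbind(eff_use$condition, eff_use$leaf)] <- eff_use$shift

  theta <- with_seed(stage_seed(config$seed, 1), {
    shift[truth$condition, , drop = FALSE] +
      matrix(rnorm(n * length(leaves), 0, config$noise_sd), nrow = n)
  })
  rownames(theta) <- truth$child_id

  versions <- paste(cw$registry$instrument, cw$registry$version, sep = "\r")
  lo <- config$instruments_per_child[1]
  hi <- min(config$instruments_per_child[2], length(versions))
  assignments <- with_seed(stage_seed(config$seed, 2), {
    purrr::map_dfr(seq_len(n), function(i) {
      nv <- if (hi > lo) sample(lo:hi, 1) else lo
      v <- sample(versions, nv, prob = config$version_weights)
      tibble::tibble(child_id = truth$child_id[i], .vkey = v)
    })
  })

  item_tbl <- dplyr::inner_join(
    cw$items,
    dplyr::select(cw$mappings, "instrument", "version", "item", "question_id"),
    by = c("instrument", "version", "item")
  )
  item_tbl$.vkey <- paste(item_tbl$instrument, item_tbl$version, sep = "\r")
  long <- dplyr::inner_join(assignments, item_tbl,
    by = ".vkey",
    relationship = "many-to-many"
  )

  responses <- with_seed(stage_seed(config$seed, 3), {
    z <- theta[cbind(long$child_id, unname(leaf_of_q[long$question_id]))] +
      rnorm(nrow(long), 0, config$item_noise_sd)
    raw <- rep(1L, nrow(long))
    for (k in unique(long$scale_size)) {
      idx <- long$scale_size == k
      cuts <- seq(0.5, 2.0, length.out = k - 1)
      raw[idx] <- 1L + rowSums(outer(z[idx], cuts, `>`))
    }
    tibble::tibble(
      child_id = long$child_id, instrument = long$instrument,
      version = long$version, item = long$item, raw = as.integer(raw)
    )
  })

  structure(
    list(
      truth = truth,
      theta = tibble::as_tibble(cbind(tibble::tibble(child_id = truth$child_id), theta)),
      assignments = dplyr::transmute(assignments,
        child_id = .data$child_id,
        instrument = sub("\r.*", "", .data$.vkey),
        version = sub(".*\r", "", .data$.vkey)
      ),
      responses = responses,
      config = config
    ),
    class = "rosetta_cohort"
  )
}

#' @export
print.rosetta_cohort <- function(x, ...) {
  tab <- table(x$truth$condition)
  cat(sprintf(
    "<rosetta_cohort> %d children (%s), %d responses over %d instrument versions\n",
    nrow(x$truth), paste(names(tab), tab, sep = "=", collapse = ", "),
    nrow(x$responses),
    nrow(dplyr::distinct(x$assignments, .data$instrument, .data$version))
  ))
  invisible(x)
}

#' Hide a fraction of observed cells for imputation scoring
#'
#' Hides exactly `floor(fraction * n_observed)` observed cells of a fused
#' matrix, uniformly at random, and returns both the masked matrix and the
#' held-out cells so imputation error can be scored against the truth.
#'
#' @param m A [rosetta_matrix()].
#' @param fraction Fraction of observed cells to hide, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @return List with `masked` (a `rosetta_matrix`) and `holdout` (tibble
#'   `child_id`, `question_id`, `value`).
#' @export
mask_holdout <- function(m, fraction, seed) {
  stopifnot(inherits(m, "rosetta_matrix"))
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be strictly between 0 and 1")
  qs <- matrix_questions(m)
  vals <- as.matrix(m[qs])
  obs <- which(!is.na(vals))
  n_hide <- floor(fraction * length(obs))
  hide <- with_seed(seed, sample(obs, n_hide))
  rc <- arrayInd(hide, dim(vals))
  holdout <- tibble::tibble(
    child_id = m$child_id[rc[, 1]],
    question_id = qs[rc[, 2]],
    value = as.integer(vals[hide])
  )
  vals[hide] <- NA_integer_
  masked <- m
  masked[qs] <- tibble::as_tibble(vals)
  list(masked = rosetta_matrix(masked, attr(m, "n_codes")), holdout = holdout)
}
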