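# brute-force oracle: enumerate each question's instrument set directly
oracle_overlap <- function(cw) {
  insts <- unique(cw$registry$instrument)
  sets <- lapply(cw$questions$question_id, function(q) {
    unique(cw$mappings$instrument[cw$mappings$question_id == q])
  })
  mat <- matrix(0L, length(insts), length(insts), dimnames = list(insts, insts))
  totals <- setNames(integer(length(insts)), insts)
  for (a in insts) {
    totals[a] <- sum(vapply(sets, function(s) a %in% s, TRUE))
    for (b in insts) {
      mat[a, b] <- if (a == b) {
        sum(vapply(sets, function(s) identical(s, a), TRUE))
      } else {
        sum(vapply(sets, function(s) a %in% s && b %in% s, TRUE))
      }
    }
  }
  list(matrix = mat, totals = totals)
}

oracle_fusion <- function(cw) {
  leaf_of <- setNames(cw$questions$leaf, cw$questions$question_id)
  out <- list()
  for (leaf in unique(cw$questions$leaf)) {
    maps <- cw$mappings[leaf_of[cw$mappings$question_id] == leaf, ]
    out[[leaf]] <- c(
      n_instruments = length(unique(maps$instrument)),
      n_items = nrow(maps),
      n_questions = sum(leaf_of == leaf)
    )
  }
  out
}
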