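# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force and share no code with the package internals.

# Maximum one-to-one matching between predicted and gold slots: enumerate
# every injective assignment of predicted slots to gold slots and take the
# best. Predicted may have 0, 1 or 2 present alleles; gold always has 2.
oracle_score_pair <- function(pred, gold) {
  pred <- pred[!is.na(pred)]
  stopifnot(length(gold) == 2L, !anyNA(gold))
  if (length(pred) == 0L) return(0L)
  if (length(pred) == 1L) return(as.integer(pred %in% gold))
  # both slots: two possible assignments
  max(
    as.integer(pred[1] == gold[1]) + as.integer(pred[2] == gold[2]),
    as.integer(pred[1] == gold[2]) + as.integer(pred[2] == gold[1])
  )
}

# All unordered pairs (with repetition) over an alphabet, plus, when
# partial = TRUE, single-allele and empty predictions.
enumerate_pairs <- function(alphabet, partial = FALSE) {
  idx <- expand.grid(i = seq_along(alphabet), j = seq_along(alphabet))
  idx <- idx[idx$i <= idx$j, ]
  pairs <- lapply(seq_len(nrow(idx)), function(k) {
    c(alphabet[idx$i[k]], alphabet[idx$j[k]])
  })
  if (partial) {
    pairs <- c(pairs,
               lapply(alphabet, function(a) c(a, NA_character_)),
               list(c(NA_character_, NA_character_)))
  }
  pairs
}

# Mann-Whitney U of group x against group y by direct pair counting
# (0.5 per tie) -- the exact definition, independent of stats::wilcox.test.
oracle_mann_whitney_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Mean consensus accuracy of a tool subset, via the package's public
# surface only (used by the greedy oracle, which re-evaluates every
# candidate extension exhaustively).
subset_consensus_accuracy <- function(calls, gold, subset, priority,
                                      genes) {
  cons <- hla_consensus(calls, subset, priority)
  mean(hla_accuracy(cons, gold, "consensus", genes)$accuracy)
}
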