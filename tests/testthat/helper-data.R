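# In-code fixture builders shared across test files.

g_group_fixture_path <- function() {
  system.file("extdata", "hla_nom_g_fixture.txt", package = "hlabench")
}

make_calls <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, character(1), 1),
    gene = vapply(rows, `[[`, character(1), 2),
    tool = vapply(rows, `[[`, character(1), 3),
    allele1 = vapply(rows, `[[`, character(1), 4),
    allele2 = vapply(rows, `[[`, character(1), 5)
  )
}

make_gold <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, character(1), 1),
    gene = vapply(rows, `[[`, character(1), 2),
    allele1 = vapply(rows, `[[`, character(1), 3),
    allele2 = vapply(rows, `[[`, character(1), 4)
  )
}

# A planted call table where each tool is fully correct on a stated sample
# range for one gene and wrong (off-by-one allele) elsewhere. Sample ids
# are S001..Sn. Alleles are drawn from a pool of second-field names.
planted_instance <- function(n_samples, correct_ranges, gene = "A") {
  ids <- sprintf("S%03d", seq_len(n_samples))
  pool <- sprintf("%s*%02d:01", gene, 1:20)
  gold <- tibble::tibble(
    sample_id = ids, gene = gene,
    allele1 = pool[1 + (seq_len(n_samples) %% 5)],
    allele2 = pool[6 + (seq_len(n_samples) %% 5)]
  )
  calls <- lapply(names(correct_ranges), function(tl) {
    ok <- seq_len(n_samples) %in% correct_ranges[[tl]]
    tibble::tibble(
      sample_id = ids, gene = gene, tool = tl,
      allele1 = ifelse(ok, gold$allele1, pool[11 + (seq_len(n_samples) %% 5)]),
      allele2 = ifelse(ok, gold$allele2, pool[16 + (seq_len(n_samples) %% 5)])
    )
  })
  list(gold = gold, calls = dplyr::bind_rows(calls))
}
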