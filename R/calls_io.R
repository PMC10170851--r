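# Canonical tabular representation:
#   calls: tibble(sample_id, gene, tool, allele1, allele2), NA = missing slot
#   gold:  tibble(sample_id, gene, allele1, allele2), both present
#   depths: tibble(sample_id, gene, mean_depth)
# Storage order of a present pair is lexicographic on the rendering; all
# comparisons downstream are unordered.

# Put a single present allele in slot 1, sort present pairs lexicographically.
canonicalize_pair <- function(df) {
  a1 <- df$allele1
  a2 <- df$allele2
  only2 <- is.na(a1) & !is.na(a2)
  a1[only2] <- a2[only2]
  a2[only2] <- NA_character_
  both <- !is.na(a1) & !is.na(a2)
  swap <- both & a2 < a1
  tmp <- a1[swap]
  a1[swap] <- a2[swap]
  a2[swap] <- tmp
  df$allele1 <- a1
  df$allele2 <- a2
  df
}

validate_alleles <- function(x, what) {
  ok <- !is.na(x)
  if (any(ok)) invisible(hla_parse(x[ok]))
  invisible(NULL)
}

check_unique_key <- function(df, key, what) {
  dup <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(key))) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate ", what, " key: ",
         paste(unlist(dup[1, key]), collapse = "/"), call. = FALSE)
  }
  invisible(df)
}

#' Read a tool call table
#'
#' Canonical TSV with header `sample_id`, `gene`, `tool`, `allele1`,
#' `allele2`; the literal string `NA` marks a missing allele slot. A row of
#' two `NA`s records an explicit no-call; a wholly absent row means the
#' same thing to the evaluation functions.
#'
#' @param path TSV file path.
#' @return A call tibble with canonical pair ordering (single present
#'   allele in slot 1, pairs sorted lexicographically).
#' @export
read_hla_calls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = "NA", progress = FALSE)
  need <- c("sample_id", "gene", "tool", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("call table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df[need])
  if (!all(df$gene %in% HLA_GENES)) {
    stop("unknown gene in call table: ",
         paste(setdiff(unique(df$gene), HLA_GENES), collapse = ", "),
         call. = FALSE)
  }
  validate_alleles(c(df$allele1, df$allele2))
  check_unique_key(df, c("sample_id", "gene", "tool"), "(sample, gene, tool)")
  canonicalize_pair(df)
}

#' Read a gold-standard genotype table
#'
#' TSV with header `sample_id`, `gene`, `allele1`, `allele2`. Gold
#' genotypes must be complete: a missing slot is an error, and alleles
#' recorded at first-field resolution are rejected rather than guessed at.
#'
#' @param path TSV file path.
#' @return A gold tibble, one row per (sample, gene), canonically ordered.
#' @export
read_hla_gold <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = "NA", progress = FALSE)
  need <- c("sample_id", "gene", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("gold table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as_tibble(df[need])
  if (anyNA(df$allele1) || anyNA(df$allele2)) {
    stop("gold standard must be complete: missing allele slot found",
         call. = FALSE)
  }
  if (!all(df$gene %in% HLA_GENES)) {
    stop("unknown gene in gold table: ",
         paste(setdiff(unique(df$gene), HLA_GENES), collapse = ", "),
         call. = FALSE)
  }
  p <- hla_parse(c(df$allele1, df$allele2))
  if (any(p$n_fields == 1L & !p$is_g_group)) {
    stop("gold allele at first-field resolution rejected: ",
         p$allele[which(p$n_fields == 1L & !p$is_g_group)[1]], call. = FALSE)
  }
  if (!all(p$gene == rep(df$gene, 2L))) {
    stop("gold allele gene does not match its row's gene column",
         call. = FALSE)
  }
  check_unique_key(df, c("sample_id", "gene"), "(sample, gene)")
  canonicalize_pair(df)
}

#' Read a per-sample per-gene mean read-depth table
#'
#' TSV with header `sample_id`, `gene`, `mean_depth` (mean coverage over
#' the peptide-binding-region exons, in x).
#'
#' @param path TSV file path.
#' @return A depth tibble; `mean_depth` is numeric and non-negative.
#' @export
read_hla_depths <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", gene = "c", mean_depth = "d"), progress = FALSE)
  if (any(df$mean_depth < 0)) stop("mean_depth must be >= 0", call. = FALSE)
  check_unique_key(df, c("sample_id", "gene"), "(sample, gene)")
  as_tibble(df)
}

#' Read a population frequency study table
#'
#' CSV with columns `study_id`, `population`, `gene`, `allele`,
#' `frequency`, `sample_size`.
#'
#' @param path CSV file path.
#' @return A study tibble.
#' @export
read_freq_studies <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    study_id = "c", population = "c", gene = "c", allele = "c",
    frequency = "d", sample_size = "d"), progress = FALSE)
  if (any(df$frequency < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (any(df$sample_size <= 0)) {
    stop("study sample sizes must be positive", call. = FALSE)
  }
  as_tibble(df)
}

# Fixed sort order shared by the writers, so output is byte-stable.
write_sorted_tsv <- function(df, path, key) {
  df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(key)))
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(df)
}

#' Write a call table
#'
#' Emits the canonical TSV under a fixed (sample, gene, tool) sort order,
#' so identical tables produce byte-identical files.
#'
#' @param calls Call tibble.
#' @param path Output path.
#' @return The sorted tibble, invisibly.
#' @export
write_hla_calls <- function(calls, path) {
  write_sorted_tsv(canonicalize_pair(calls), path,
                   c("sample_id", "gene", "tool"))
}

#' Write a gold-standard table
#' @param gold Gold tibble.
#' @param path Output path.
#' @return The sorted tibble, invisibly.
#' @export
write_hla_gold <- function(gold, path) {
  write_sorted_tsv(canonicalize_pair(gold), path, c("sample_id", "gene"))
}

#' Normalize the alleles of a call or gold table
#'
#' Applies [hla_normalize()] to both allele columns and restores the
#' canonical pair ordering.
#'
#' @param df Call or gold tibble.
#' @param g_groups Mapping tibble from [read_g_groups()], or `NULL`.
#' @param n_fields Trimming resolution (default 2).
#' @return The tibble with normalized alleles.
#' @export
normalize_table <- function(df, g_groups = NULL, n_fields = 2L) {
  for (col in c("allele1", "allele2")) {
    ok <- !is.na(df[[col]])
    if (any(ok)) df[[col]][ok] <- hla_normalize(df[[col]][ok], g_groups, n_fields)
  }
  canonicalize_pair(df)
}
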