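# Observed allele frequencies from call tables and expected frequencies
# from published typing studies, combined by sample-size-weighted
# averaging. The headline use is the Pearson correlation between the two,
# which is invariant to the divisor convention of the observed side.

#' Observed allele frequencies of a tool's calls
#'
#' Counts each allele across both slots of the complete calls for (tool,
#' gene). Two conventions are reported side by side: `freq` divides the
#' count by the number of called samples (so a gene's frequencies sum
#' to 2 — the convention used when comparing with study tables built the
#' same way), and `freq_per_chromosome` divides by twice that number
#' (summing to 1). Homozygotes count twice.
#'
#' @param calls Call tibble (normalized).
#' @param tool A single tool id.
#' @param genes Genes to tabulate (default: all genes the tool called).
#' @return A tibble `tool`, `gene`, `allele`, `count`, `n_samples`,
#'   `freq`, `freq_per_chromosome`.
#' @export
observed_frequencies <- function(calls, tool, genes = NULL) {
  stopifnot(length(tool) == 1L)
  tool_id <- tool
  sub <- calls |>
    dplyr::filter(.data$tool == tool_id, !is.na(.data$allele1),
                  !is.na(.data$allele2))
  if (!is.null(genes)) sub <- dplyr::filter(sub, .data$gene %in% genes)
  if (nrow(sub) == 0L) {
    stop("no complete calls for tool '", tool_id, "'",
         if (!is.null(genes)) paste0(" on gene(s) ",
                                     paste(genes, collapse = ", ")),
         call. = FALSE)
  }
  long <- sub |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::group_by(.data$gene)
  long |>
    dplyr::mutate(n_samples = dplyr::n() / 2) |>
    dplyr::group_by(.data$gene, .data$allele, .data$n_samples) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(tool = tool_id,
                  freq = .data$count / .data$n_samples,
                  freq_per_chromosome = .data$count / (2 * .data$n_samples)) |>
    dplyr::select("tool", "gene", "allele", "count", "n_samples", "freq",
                  "freq_per_chromosome") |>
    dplyr::arrange(.data$gene, .data$allele)
}

#' Combine allele-frequency studies by weighted averaging
#'
#' Per gene and allele, the expected frequency is the mean of the studies'
#' frequencies weighted by study sample size. An allele a study does not
#' report contributes frequency 0 for that study with the study's full
#' weight (`drop_missing = TRUE` instead averages only over the studies
#' that report the allele).
#'
#' @param studies Study tibble with columns `study_id`, `gene`, `allele`,
#'   `frequency`, `sample_size` (as from [read_freq_studies()]); an
#'   optional `population` column is preserved if constant.
#' @param drop_missing Average only over reporting studies.
#' @return A tibble `gene`, `allele`, `frequency`, `n_studies`,
#'   `total_sample_size`.
#' @export
#' @examples
#' studies <- tibble::tibble(
#'   study_id = c("s1", "s2"), gene = "A",
#'   allele = "A*01:01", frequency = c(0.1, 0.2),
#'   sample_size = c(100, 300)
#' )
#' combine_study_frequencies(studies)  # 0.175
combine_study_frequencies <- function(studies, drop_missing = FALSE) {
  if (any(studies$sample_size <= 0)) {
    stop("study sample sizes must be positive", call. = FALSE)
  }
  dup <- studies |>
    dplyr::count(.data$study_id, .data$gene, .data$allele) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("study '", dup$study_id[1], "' reports allele '", dup$allele[1],
         "' more than once", call. = FALSE)
  }
  weights <- studies |>
    dplyr::distinct(.data$study_id, .data$gene, .data$sample_size)
  full <- studies |>
    dplyr::select("study_id", "gene", "allele", "frequency") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("gene"), !!rlang::sym("allele")),
      .data$study_id,
      fill = list(frequency = NA_real_)
    ) |>
    dplyr::inner_join(weights, by = c("study_id", "gene"))
  if (!drop_missing) {
    full$frequency[is.na(full$frequency)] <- 0
  }
  full |>
    dplyr::filter(!is.na(.data$frequency)) |>
    dplyr::group_by(.data$gene, .data$allele) |>
    dplyr::summarise(
      frequency = sum(.data$sample_size * .data$frequency) /
        sum(.data$sample_size),
      n_studies = dplyr::n(),
      total_sample_size = sum(.data$sample_size),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene, .data$allele)
}

#' Pearson correlation of observed vs expected allele frequencies
#'
#' Correlates a tool's observed frequencies with expected population
#' frequencies per gene. By default the allele universe is the union of
#' the two tables with absentees as 0 (`universe = "intersection"`
#' restricts to alleles present in both). The correlation is invariant to
#' the observed table's divisor convention, since Pearson r is invariant
#' to positive rescaling.
#'
#' @param observed Tibble from [observed_frequencies()] (or any tibble
#'   with `gene`, `allele` and the column named by `observed_col`).
#' @param expected Tibble from [combine_study_frequencies()] (columns
#'   `gene`, `allele`, `frequency`).
#' @param genes Genes to correlate (default: genes present in both).
#' @param universe `"union"` (absent alleles count as frequency 0) or
#'   `"intersection"`.
#' @param observed_col Column of `observed` to use.
#' @return A tibble `gene`, `r`, `p_value`, `n_alleles` (two-sided
#'   t-distributed p, no multiplicity adjustment).
#' @export
frequency_correlation <- function(observed, expected, genes = NULL,
                                  universe = c("union", "intersection"),
                                  observed_col = "freq") {
  universe <- match.arg(universe)
  if (is.null(genes)) {
    genes <- intersect(unique(observed$gene), unique(expected$gene))
  }
  purrr::map(genes, function(g) {
    obs <- observed |>
      dplyr::filter(.data$gene == g) |>
      dplyr::select("allele", obs = dplyr::all_of(observed_col))
    exp <- expected |>
      dplyr::filter(.data$gene == g) |>
      dplyr::select("allele", exp = "frequency")
    joined <- switch(universe,
      union = dplyr::full_join(obs, exp, by = "allele") |>
        tidyr::replace_na(list(obs = 0, exp = 0)),
      intersection = dplyr::inner_join(obs, exp, by = "allele")
    )
    if (nrow(joined) < 3L) {
      stop("gene ", g, ": need at least 3 alleles to correlate",
           call. = FALSE)
    }
    if (stats::sd(joined$obs) == 0 || stats::sd(joined$exp) == 0) {
      stop("gene ", g, ": zero variance, correlation undefined",
           call. = FALSE)
    }
    ct <- stats::cor.test(joined$obs, joined$exp, method = "pearson",
                          alternative = "two.sided")
    tibble(gene = g, r = unname(ct$estimate), p_value = ct$p.value,
           n_alleles = nrow(joined))
  }) |> dplyr::bind_rows()
}
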