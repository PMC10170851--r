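# Accuracy metric: an allele prediction is correct when it is listed as one
# of the two gold alleles; a homozygous prediction against a heterozygous
# gold earns at most one correct allele; no-calls earn zero. Per tool and
# gene, accuracy = correct alleles / (2 * samples with a gold entry).

#' Score one predicted pair against a gold pair
#'
#' Returns the size of the multiset intersection between the predicted
#' alleles (0, 1 or 2 of them) and the two gold alleles: each gold allele
#' can be "used up" by at most one prediction, so a homozygous prediction
#' against a heterozygous gold scores at most 1, and a no-call scores 0.
#' Vectorized over rows.
#'
#' @param pred1,pred2 Predicted allele slots (character; `NA` = missing).
#' @param gold1,gold2 Gold allele slots (both required).
#' @return Integer vector in 0..2.
#' @export
#' @examples
#' score_pair("A*01:01", "A*01:01", "A*01:01", "A*02:01")  # 1
score_pair <- function(pred1, pred2, gold1, gold2) {
  if (anyNA(gold1) || anyNA(gold2)) {
    stop("gold pair must be complete", call. = FALSE)
  }
  n <- max(length(pred1), length(pred2), length(gold1), length(gold2))
  pred1 <- rep_len(pred1, n); pred2 <- rep_len(pred2, n)
  gold1 <- rep_len(gold1, n); gold2 <- rep_len(gold2, n)
  vapply(seq_len(n), function(i) {
    gold <- c(gold1[i], gold2[i])
    score <- 0L
    for (p in c(pred1[i], pred2[i])) {
      if (is.na(p)) next
      hit <- match(p, gold)
      if (!is.na(hit)) {
        score <- score + 1L
        gold <- gold[-hit]
      }
    }
    score
  }, integer(1))
}

# Gold keys joined with one tool's calls; absent or partial calls kept
# (score counts them as 0 or via the multiset rule).
scored_calls <- function(calls, gold, tools = NULL, genes = NULL) {
  if (is.null(tools)) tools <- sort(unique(calls$tool))
  missing_tools <- setdiff(tools, unique(calls$tool))
  if (length(missing_tools) > 0L) {
    stop("tool(s) absent from call table: ",
         paste(missing_tools, collapse = ", "), call. = FALSE)
  }
  if (is.null(genes)) genes <- sort(unique(gold$gene))
  gold <- dplyr::filter(gold, .data$gene %in% genes)
  grid <- tidyr::expand_grid(
    gold |> dplyr::select("sample_id", "gene",
                          gold1 = "allele1", gold2 = "allele2"),
    tool = tools
  )
  grid |>
    dplyr::left_join(
      calls |> dplyr::select("sample_id", "gene", "tool",
                             "allele1", "allele2"),
      by = c("sample_id", "gene", "tool")
    ) |>
    dplyr::mutate(score = score_pair(.data$allele1, .data$allele2,
                                     .data$gold1, .data$gold2))
}

#' Per-tool, per-gene allele-level accuracy
#'
#' For each tool and gene, sums correct alleles over the samples that have
#' a gold entry for that gene and divides by twice their number. Samples
#' without a gold entry for a gene are ignored for that gene; samples with
#' gold but no call contribute 0 correct out of 2. Calls and gold are
#' expected to be normalized already (see [normalize_table()]).
#'
#' @param calls Call tibble.
#' @param gold Gold tibble.
#' @param tools Tools to evaluate (default: all in `calls`).
#' @param genes Genes to evaluate (default: all in `gold`).
#' @return A tibble `tool`, `gene`, `mhc_class`, `n_samples`, `n_correct`,
#'   `accuracy`, of class `"hla_accuracy"`.
#' @export
hla_accuracy <- function(calls, gold, tools = NULL, genes = NULL) {
  out <- scored_calls(calls, gold, tools, genes) |>
    dplyr::group_by(.data$tool, .data$gene) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_correct = sum(.data$score),
                     .groups = "drop") |>
    dplyr::mutate(mhc_class = hla_class_of(.data$gene),
                  accuracy = .data$n_correct / (2 * .data$n_samples)) |>
    dplyr::select("tool", "gene", "mhc_class", "n_samples", "n_correct",
                  "accuracy") |>
    dplyr::arrange(.data$tool, .data$gene)
  class(out) <- c("hla_accuracy", class(out))
  out
}

#' Aggregate accuracy per MHC class
#'
#' Default aggregation is the unweighted mean of per-gene accuracies within
#' each class; `pooled = TRUE` instead pools correct alleles and sample
#' counts across the class's genes. Both are useful because per-gene sample
#' counts may differ.
#'
#' @param report An `"hla_accuracy"` tibble from [hla_accuracy()].
#' @param pooled Pool alleles across genes instead of averaging per-gene
#'   accuracies.
#' @return A tibble `tool`, `mhc_class`, `n_genes`, `accuracy`.
#' @export
hla_class_accuracy <- function(report, pooled = FALSE) {
  report |>
    dplyr::group_by(.data$tool, .data$mhc_class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      accuracy = if (pooled) {
        sum(.data$n_correct) / (2 * sum(.data$n_samples))
      } else {
        mean(.data$accuracy)
      },
      .groups = "drop"
    )
}

#' Sample-gene keys a tool got wrong
#'
#' "Wrong" means not both alleles correct (score < 2), including partial
#' scores and no-calls — the complement of a fully correct prediction, as
#' used by the greedy tool-selection step.
#'
#' @inheritParams hla_accuracy
#' @param tool A single tool id.
#' @return A tibble `sample_id`, `gene`, `score`.
#' @export
wrong_samples <- function(calls, gold, tool, genes = NULL) {
  stopifnot(length(tool) == 1L)
  scored_calls(calls, gold, tool, genes) |>
    dplyr::filter(.data$score < 2L) |>
    dplyr::select("sample_id", "gene", "score")
}

#' @export
#' @method autoplot hla_accuracy
#' @importFrom ggplot2 autoplot
autoplot.hla_accuracy <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$gene, y = .data$accuracy,
                               fill = .data$tool)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$mhc_class),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "HLA gene", y = "Allele-level accuracy",
                  fill = "Tool") +
    ggplot2::theme_minimal()
}
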