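# Pairwise between-tool agreement at the allele-pair level. A "prediction"
# is a complete unordered pair; samples where either tool made no (or a
# partial) prediction are not considered.

#' Concordance between two tools for one gene
#'
#' Over the samples where both tools produced a complete pair for `gene`,
#' counts exact unordered-pair agreement (homozygous pairs compare as
#' multisets: \{X,X\} differs from \{X,Y\}).
#'
#' @param calls Call tibble (normalized).
#' @param tool_a,tool_b Tool ids.
#' @param gene Gene symbol.
#' @return A one-row tibble `gene`, `tool_a`, `tool_b`, `n_shared`,
#'   `n_concordant`, `fraction` (`NA` when no shared samples).
#' @export
pairwise_concordance <- function(calls, tool_a, tool_b, gene) {
  genes <- gene
  if (!all(c(tool_a, tool_b) %in% calls$tool)) {
    stop("unknown tool: ",
         paste(setdiff(c(tool_a, tool_b), calls$tool), collapse = ", "),
         call. = FALSE)
  }
  if (!gene %in% calls$gene) stop("unknown gene: ", gene, call. = FALSE)
  complete <- canonicalize_pair(calls) |>
    dplyr::filter(.data$gene %in% genes, !is.na(.data$allele1),
                  !is.na(.data$allele2)) |>
    dplyr::mutate(pair = paste(.data$allele1, .data$allele2, sep = "|"))
  a <- dplyr::filter(complete, .data$tool == tool_a)
  b <- dplyr::filter(complete, .data$tool == tool_b)
  shared <- dplyr::inner_join(
    a |> dplyr::select("sample_id", pair_a = "pair"),
    b |> dplyr::select("sample_id", pair_b = "pair"),
    by = "sample_id"
  )
  n_shared <- nrow(shared)
  n_conc <- sum(shared$pair_a == shared$pair_b)
  tibble(
    gene = gene, tool_a = tool_a, tool_b = tool_b,
    n_shared = n_shared, n_concordant = n_conc,
    fraction = if (n_shared > 0L) n_conc / n_shared else NA_real_
  )
}

#' Full concordance matrix in long format
#'
#' [pairwise_concordance()] for every gene and ordered tool pair
#' (including the diagonal, which is 1 wherever a tool shares samples with
#' itself). The fraction matrix is symmetric because unordered-pair
#' equality is.
#'
#' @param calls Call tibble (normalized).
#' @param tools Tools to include (default: all).
#' @param genes Genes to include (default: all).
#' @return A long tibble of class `"hla_concordance"`.
#' @export
hla_concordance <- function(calls, tools = NULL, genes = NULL) {
  if (is.null(tools)) tools <- sort(unique(calls$tool))
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  grid <- tidyr::expand_grid(gene = genes, tool_a = tools, tool_b = tools)
  out <- purrr::pmap(grid, function(gene, tool_a, tool_b) {
    pairwise_concordance(calls, tool_a, tool_b, gene)
  }) |> dplyr::bind_rows()
  class(out) <- c("hla_concordance", class(out))
  out
}

#' @export
#' @method autoplot hla_concordance
autoplot.hla_concordance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tool_a, y = .data$tool_b,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
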