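# Majority-vote metaclassifier. Votes are cast by complete (two-allele)
# pairs; tools with a no-call or partial call abstain for that sample-gene.
# Ties go to the pair supported by the tool with the best individual
# performance for the gene (rank 1), then to the lexicographically smaller
# pair rendering.

#' Rank tools per gene by individual accuracy
#'
#' The default tie-break oracle for majority voting: rank 1 is the tool
#' with the best individual allele-level accuracy for that gene (ties
#' broken by tool id, for determinism). A precomputed ranking — e.g. from
#' an external benchmark — can be passed to the consensus functions
#' instead.
#'
#' @inheritParams hla_accuracy
#' @return A tibble `gene`, `tool`, `accuracy`, `rank` (1 = best).
#' @export
hla_tool_priority <- function(calls, gold, tools = NULL, genes = NULL) {
  hla_accuracy(calls, gold, tools, genes) |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$tool,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "tool", "accuracy", "rank")
}

# Collapse a per-gene priority to a single global ranking (mean rank).
globalize_priority <- function(priority) {
  priority |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$mean_rank, .data$tool) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("tool", "rank")
}


#' Majority-vote consensus calls for a tool subset
#'
#' For every (sample, gene) covered by at least one subset tool, selects
#' the unordered allele pair predicted by the most tools. Only complete
#' pairs vote. Ties go to the pair predicted by the tool with the best
#' individual performance for that gene; if the tied pairs' best
#' supporting tools share a rank the lexicographically smaller pair wins.
#' If no subset tool produced a complete pair the consensus is a no-call.
#'
#' @param calls Call tibble (normalized).
#' @param tools Character vector of tool ids forming the ensemble.
#' @param priority Ranking tibble from [hla_tool_priority()] (columns
#'   `gene`, `tool`, `rank`), or a global ranking (columns `tool`, `rank`)
#'   applied to every gene.
#' @param tool_id Pseudo-tool id of the output rows.
#' @return A call tibble with `tool = tool_id`.
#' @export
hla_consensus <- function(calls, tools, priority, tool_id = "consensus") {
  stopifnot(length(tools) >= 1L)
  missing <- setdiff(tools, unique(priority$tool))
  if (length(missing) > 0L) {
    stop("priority ranking missing tool(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- canonicalize_pair(dplyr::filter(calls, .data$tool %in% tools))
  keys <- dplyr::distinct(sub, .data$sample_id, .data$gene)

  ranks <- if ("gene" %in% names(priority)) {
    dplyr::select(priority, "gene", "tool", "rank")
  } else {
    tidyr::expand_grid(gene = unique(sub$gene),
                       dplyr::select(priority, "tool", "rank"))
  }
  covered <- dplyr::distinct(sub, .data$gene, .data$tool) |>
    dplyr::anti_join(ranks, by = c("gene", "tool"))
  if (nrow(covered) > 0L) {
    stop("priority ranking missing tool '", covered$tool[1],
         "' for gene ", covered$gene[1], call. = FALSE)
  }

  winners <- sub |>
    dplyr::filter(!is.na(.data$allele1), !is.na(.data$allele2)) |>
    dplyr::inner_join(ranks, by = c("gene", "tool")) |>
    dplyr::group_by(.data$sample_id, .data$gene,
                    .data$allele1, .data$allele2) |>
    dplyr::summarise(n_votes = dplyr::n(), best_rank = min(.data$rank),
                     .groups = "drop") |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::arrange(dplyr::desc(.data$n_votes), .data$best_rank,
                   .data$allele1, .data$allele2, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "gene", "allele1", "allele2")

  out <- keys |>
    dplyr::left_join(winners, by = c("sample_id", "gene")) |>
    dplyr::mutate(tool = tool_id) |>
    dplyr::select("sample_id", "gene", "tool", "allele1", "allele2") |>
    dplyr::arrange(.data$sample_id, .data$gene)
  canonicalize_pair(out)
}

#' Greedy forward selection of a minimal tool subset
#'
#' Builds nested majority-vote models of growing size. The first tool is
#' the one with the best mean accuracy over the requested genes; the
#' second is the tool that most often makes a fully correct prediction on
#' the first tool's wrongly predicted sample-gene keys. Each later step
#' adds the unselected tool whose addition gives the largest increase (or
#' smallest decrease) in mean consensus accuracy, until every tool is in
#' the model. Candidate ties are broken by better individual mean
#' accuracy, then tool id.
#'
#' @inheritParams hla_accuracy
#' @param priority Optional ranking tibble (see [hla_consensus()]);
#'   computed from `calls` and `gold` via [hla_tool_priority()] when
#'   omitted.
#' @param global_priority Use a single global ranking for vote tie-breaks
#'   instead of per-gene ranks.
#' @return An object of class `"hla_selection"`: list with `trajectory`
#'   (tibble `step`, `tool_added`, `accuracy` — mean consensus accuracy
#'   over genes), `tools` (selection order), `by_gene` (per-step per-gene
#'   accuracies), `genes`, `priority`.
#' @export
hla_select_tools <- function(calls, gold, tools = NULL, genes = NULL,
                             priority = NULL, global_priority = FALSE) {
  if (is.null(tools)) tools <- sort(unique(calls$tool))
  if (length(tools) < 2L) {
    stop("greedy selection needs at least 2 tools", call. = FALSE)
  }
  if (is.null(genes)) genes <- sort(unique(gold$gene))
  gold <- dplyr::filter(gold, .data$gene %in% genes)
  if (is.null(priority)) {
    priority <- hla_tool_priority(calls, gold, tools, genes)
  }
  if (global_priority && "gene" %in% names(priority)) {
    priority <- globalize_priority(priority)
  }

  indiv <- hla_accuracy(calls, gold, tools, genes) |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  mean_acc <- stats::setNames(indiv$accuracy, indiv$tool)

  consensus_mean_acc <- function(subset) {
    cons <- hla_consensus(calls, subset, priority)
    rep <- hla_accuracy(cons, gold, "consensus", genes)
    list(mean = mean(rep$accuracy), by_gene = rep)
  }

  pick <- function(cands, gain) {
    ord <- order(-gain, -mean_acc[cands], cands)
    cands[ord[1]]
  }

  best <- pick(tools, mean_acc[tools])
  selected <- best
  step1 <- consensus_mean_acc(selected)

  # Complement: tool most often fully correct on the best tool's misses.
  wrong <- wrong_samples(calls, gold, best, genes)
  others <- setdiff(tools, best)
  rescued <- vapply(others, function(t) {
    sc <- scored_calls(calls, gold, t, genes) |>
      dplyr::semi_join(wrong, by = c("sample_id", "gene"))
    sum(sc$score == 2L)
  }, numeric(1))
  complement <- pick(others, rescued)
  selected <- c(selected, complement)

  steps <- vector("list", length(tools))
  steps[[1]] <- step1
  steps[[2]] <- consensus_mean_acc(selected)
  while (length(selected) < length(tools)) {
    cands <- setdiff(tools, selected)
    evals <- lapply(cands, function(t) consensus_mean_acc(c(selected, t)))
    gains <- vapply(evals, `[[`, numeric(1), "mean")
    chosen <- pick(cands, gains)
    steps[[length(selected) + 1L]] <- evals[[match(chosen, cands)]]
    selected <- c(selected, chosen)
  }

  trajectory <- tibble(
    step = seq_along(selected),
    tool_added = selected,
    accuracy = vapply(steps, `[[`, numeric(1), "mean")
  )
  by_gene <- purrr::map2(steps, seq_along(steps), function(s, k) {
    dplyr::mutate(s$by_gene, step = k, .before = 1)
  }) |> dplyr::bind_rows()
  structure(
    list(trajectory = trajectory, tools = selected, by_gene = by_gene,
         genes = genes, priority = priority),
    class = "hla_selection"
  )
}

#' @export
print.hla_selection <- function(x, ...) {
  cat("Greedy tool selection over genes:",
      paste(x$genes, collapse = ", "), "\n")
  print(x$trajectory)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @method tidy hla_selection
tidy.hla_selection <- function(x, ...) x$trajectory

#' @export
#' @method glance hla_selection
glance.hla_selection <- function(x, ...) {
  best <- which.max(x$trajectory$accuracy)
  tibble(
    n_tools = nrow(x$trajectory),
    best_step = best,
    best_accuracy = x$trajectory$accuracy[best],
    full_model_accuracy = x$trajectory$accuracy[nrow(x$trajectory)]
  )
}

#' @export
#' @method autoplot hla_selection
autoplot.hla_selection <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$step, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$tool_added),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_x_continuous(breaks = object$trajectory$step) +
    ggplot2::labs(x = "Tools in consensus model (k)",
                  y = "Mean consensus accuracy over genes") +
    ggplot2::theme_minimal()
}
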