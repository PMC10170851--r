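# Synthetic benchmark generator: Hardy-Weinberg gold standards drawn from a
# population frequency table, and per-tool call tables with tool-specific
# no-call and miscall rates, optional depth-dependent error and optional
# between-tool error correlation through a shared per-sample difficulty.
#
# All randomness flows from a single seed through named streams (one per
# tool, plus "gold", "depth" and "difficulty"), so adding a tool to a
# configuration does not perturb any other tool's draws.

hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

seed_stream <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (name in as.character(c(...))) {
    h <- (h * 1000003 + hash_string(name)) %% 2147483647
  }
  as.integer(h)
}

#' Symmetric-Dirichlet allele frequencies
#'
#' Draws a per-gene allele frequency table from a symmetric Dirichlet
#' distribution. Allele names follow the canonical second-field pattern
#' (`GENE*kk:01`).
#'
#' @param genes Gene symbols.
#' @param n_alleles Alleles per gene.
#' @param concentration Dirichlet concentration (1 = flat; smaller values
#'   give the skewed, few-common-many-rare profiles typical of real HLA
#'   loci).
#' @param seed Integer seed.
#' @return A tibble `gene`, `allele`, `freq` with per-gene frequencies
#'   summing to 1.
#' @export
sim_frequencies <- function(genes, n_alleles = 12L, concentration = 0.5,
                            seed) {
  stopifnot(n_alleles >= 1L, concentration > 0)
  purrr::map(genes, function(g) {
    set.seed(seed_stream(seed, "freqs", g))
    w <- stats::rgamma(n_alleles, shape = concentration)
    while (sum(w) == 0) w <- stats::rgamma(n_alleles, shape = concentration)
    tibble(
      gene = g,
      allele = sprintf("%s*%02d:01", g, seq_len(n_alleles)),
      freq = w / sum(w)
    )
  }) |> dplyr::bind_rows()
}

#' Tool error profile for the simulator
#'
#' @param tool Tool id.
#' @param error_rate Per-allele miscall probability (epsilon).
#' @param no_call_rate Probability of emitting no call for a sample-gene
#'   key (nu).
#' @param depth_intercept,depth_slope Optional logistic coupling: when
#'   both are given the per-allele miscall probability becomes
#'   `plogis(depth_intercept + depth_slope * depth)` and a depth table is
#'   required (a negative slope makes shallow samples harder).
#' @param shared_load Loading lambda in \[0, 1\] on a per-sample-gene latent
#'   difficulty shared by all tools; 0 gives conditionally independent
#'   errors, larger values correlate errors between tools while keeping
#'   each tool's marginal miscall rate exact (Gaussian copula).
#' @return A one-row profile tibble.
#' @export
tool_profile <- function(tool, error_rate = 0.05, no_call_rate = 0.02,
                         depth_intercept = NULL, depth_slope = NULL,
                         shared_load = 0) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            no_call_rate >= 0, no_call_rate <= 1,
            shared_load >= 0, shared_load <= 1)
  coupled <- !is.null(depth_intercept) && !is.null(depth_slope)
  tibble(
    tool = tool,
    error_rate = error_rate,
    no_call_rate = no_call_rate,
    depth_intercept = if (coupled) depth_intercept else NA_real_,
    depth_slope = if (coupled) depth_slope else NA_real_,
    shared_load = shared_load
  )
}

#' Simulation configuration
#'
#' Bundles everything the generator needs. Frequencies are validated to
#' sum to 1 per gene (within 1e-9); the seed is mandatory.
#'
#' @param n_samples Number of samples.
#' @param genes Gene symbols.
#' @param frequencies Frequency tibble (`gene`, `allele`, `freq`), or
#'   `NULL` to draw one via [sim_frequencies()].
#' @param profiles Row-bound [tool_profile()] tibble.
#' @param n_alleles,concentration Passed to [sim_frequencies()] when
#'   `frequencies` is `NULL`.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of the
#'   per-sample-gene mean read depth (defaults centred near 40x, the
#'   scale of typical exome coverage over the HLA exons).
#' @param seed Integer seed (required).
#' @return A list of class `"hla_sim_config"`.
#' @export
sim_config <- function(n_samples, genes = c("A", "B", "C"),
                       frequencies = NULL,
                       profiles = dplyr::bind_rows(
                         tool_profile("tool1"), tool_profile("tool2"),
                         tool_profile("tool3")
                       ),
                       n_alleles = 12L, concentration = 0.5,
                       depth_meanlog = log(40), depth_sdlog = 0.6,
                       seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_samples >= 1L, all(genes %in% HLA_GENES))
  if (is.null(frequencies)) {
    frequencies <- sim_frequencies(genes, n_alleles, concentration, seed)
  }
  sums <- frequencies |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(s = sum(.data$freq), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    stop("allele frequencies must sum to 1 per gene", call. = FALSE)
  }
  if (!all(genes %in% frequencies$gene)) {
    stop("frequency table missing gene(s)", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), genes = genes,
         frequencies = frequencies, profiles = profiles,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         seed = as.integer(seed)),
    class = "hla_sim_config"
  )
}

sim_sample_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Hardy-Weinberg gold-standard genotypes
#'
#' For every sample and gene, draws two independent alleles from the
#' gene's frequency table (Hardy-Weinberg equilibrium), standing in for
#' PCR-typed genotypes.
#'
#' @param config An [sim_config()] object.
#' @return A gold tibble (`sample_id`, `gene`, `allele1`, `allele2`).
#' @export
sample_gold <- function(config) {
  stopifnot(inherits(config, "hla_sim_config"))
  ids <- sim_sample_ids(config$n_samples)
  out <- purrr::map(config$genes, function(g) {
    ft <- dplyr::filter(config$frequencies, .data$gene == g)
    set.seed(seed_stream(config$seed, "gold", g))
    a1 <- sample(ft$allele, config$n_samples, replace = TRUE, prob = ft$freq)
    a2 <- sample(ft$allele, config$n_samples, replace = TRUE, prob = ft$freq)
    tibble(sample_id = ids, gene = g, allele1 = a1, allele2 = a2)
  }) |> dplyr::bind_rows()
  canonicalize_pair(dplyr::arrange(out, .data$sample_id, .data$gene))
}

#' Simulated per-sample read depths
#'
#' @param config An [sim_config()] object.
#' @return A depth tibble (`sample_id`, `gene`, `mean_depth`), log-normal.
#' @export
sim_depths <- function(config) {
  stopifnot(inherits(config, "hla_sim_config"))
  ids <- sim_sample_ids(config$n_samples)
  purrr::map(config$genes, function(g) {
    set.seed(seed_stream(config$seed, "depth", g))
    tibble(sample_id = ids, gene = g,
           mean_depth = stats::rlnorm(config$n_samples,
                                      config$depth_meanlog,
                                      config$depth_sdlog))
  }) |> dplyr::bind_rows() |>
    dplyr::arrange(.data$sample_id, .data$gene)
}

# Frequency-weighted replacement draw, truth excluded and renormalized.
# `u` is a uniform variate from the tool's private stream.
miscall_allele <- function(truth, alleles, freqs, u) {
  keep <- alleles != truth
  if (!any(keep)) {
    stop("cannot miscall: gene has a single allele", call. = FALSE)
  }
  w <- freqs[keep] / sum(freqs[keep])
  cw <- cumsum(w)
  alleles[keep][min(1L + sum(u > cw), length(cw))]
}

#' Simulate tool call tables from a gold standard
#'
#' Per tool, sample and gene: with probability `no_call_rate` the tool
#' emits a no-call; otherwise each of the two true alleles is
#' independently miscalled with the tool's per-allele error probability
#' (constant, or logistic in read depth when the profile couples to
#' depth), the wrong allele being drawn frequency-weighted from the
#' gene's other alleles. A `shared_load` above 0 mixes a per-sample-gene
#' latent difficulty into every tool's error indicator through a Gaussian
#' copula, correlating errors between tools without changing marginal
#' rates.
#'
#' @param gold Gold tibble (e.g. from [sample_gold()]).
#' @param profiles Row-bound [tool_profile()] tibble.
#' @param frequencies Frequency tibble used for miscall draws; when `NULL`
#'   the empirical allele frequencies of `gold` are used.
#' @param depths Depth tibble; required when any profile couples errors to
#'   depth.
#' @param seed Integer seed.
#' @return A call tibble covering every tool and gold key.
#' @export
simulate_calls <- function(gold, profiles, frequencies = NULL,
                           depths = NULL, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  gold <- dplyr::arrange(gold, .data$sample_id, .data$gene)
  if (is.null(frequencies)) {
    frequencies <- gold |>
      tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
      dplyr::count(.data$gene, .data$allele) |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::select("gene", "allele", "freq")
    }
  coupled <- !is.na(profiles$depth_intercept) & !is.na(profiles$depth_slope)
  if (any(coupled) && is.null(depths)) {
    stop("depth-coupled profiles require a depth table", call. = FALSE)
  }
  if (!is.null(depths)) {
    gold <- dplyr::left_join(gold, depths, by = c("sample_id", "gene"))
  }
  n_keys <- nrow(gold)

  # shared difficulty: one latent normal per sample-gene key
  set.seed(seed_stream(seed, "difficulty"))
  h <- stats::rnorm(n_keys)

  freq_by_gene <- split(frequencies, frequencies$gene)

  out <- purrr::map(seq_len(nrow(profiles)), function(ti) {
    prof <- profiles[ti, ]
    set.seed(seed_stream(seed, "tool", prof$tool))
    u_nc <- stats::runif(n_keys)
    e1 <- stats::rnorm(n_keys); e2 <- stats::rnorm(n_keys)
    r1 <- stats::runif(n_keys); r2 <- stats::runif(n_keys)

    eps <- if (coupled[ti]) {
      stats::plogis(prof$depth_intercept +
                      prof$depth_slope * gold$mean_depth)
    } else {
      rep(prof$error_rate, n_keys)
    }
    lam <- prof$shared_load
    z1 <- stats::pnorm(sqrt(lam) * h + sqrt(1 - lam) * e1)
    z2 <- stats::pnorm(sqrt(lam) * h + sqrt(1 - lam) * e2)
    no_call <- u_nc < prof$no_call_rate
    a1 <- gold$allele1
    a2 <- gold$allele2
    for (i in which(!no_call & z1 < eps)) {
      ft <- freq_by_gene[[gold$gene[i]]]
      a1[i] <- miscall_allele(gold$allele1[i], ft$allele, ft$freq, r1[i])
    }
    for (i in which(!no_call & z2 < eps)) {
      ft <- freq_by_gene[[gold$gene[i]]]
      a2[i] <- miscall_allele(gold$allele2[i], ft$allele, ft$freq, r2[i])
    }
    a1[no_call] <- NA_character_
    a2[no_call] <- NA_character_
    tibble(sample_id = gold$sample_id, gene = gold$gene, tool = prof$tool,
           allele1 = a1, allele2 = a2)
  }) |> dplyr::bind_rows()
  canonicalize_pair(dplyr::arrange(out, .data$sample_id, .data$gene,
                                   .data$tool))
}

#' Simulate a full benchmark in one call
#'
#' @param config An [sim_config()] object.
#' @return A list `gold`, `calls`, `depths`, `frequencies`.
#' @export
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "hla_sim_config"))
  gold <- sample_gold(config)
  depths <- sim_depths(config)
  calls <- simulate_calls(gold, config$profiles, config$frequencies,
                          depths, config$seed)
  list(gold = gold, calls = calls, depths = depths,
       frequencies = config$frequencies)
}

#' Write a complete desk-scale fixture bundle
#'
#' Generates a gold standard, call table and depth table from `config`
#' and writes them together with a study CSV (the generating frequencies
#' split into two pseudo-studies with stated sample sizes) and a
#' self-consistent G-group mapping file (each simulated allele as a
#' singleton), so the bundle round-trips through every reader and
#' analysis function. Identical configurations produce byte-identical
#' bundles.
#'
#' @param config An [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @param study_sizes Sample sizes of the two pseudo-studies.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture <- function(config, dir, study_sizes = c(120L, 240L)) {
  stopifnot(inherits(config, "hla_sim_config"), length(study_sizes) >= 2L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_benchmark(config)
  paths <- c(
    gold = file.path(dir, "gold.tsv"),
    calls = file.path(dir, "calls.tsv"),
    depths = file.path(dir, "depths.tsv"),
    studies = file.path(dir, "studies.csv"),
    g_groups = file.path(dir, "g_groups.txt")
  )
  write_hla_gold(sim$gold, paths[["gold"]])
  write_hla_calls(sim$calls, paths[["calls"]])
  readr::write_tsv(dplyr::arrange(sim$depths, .data$sample_id, .data$gene),
                   paths[["depths"]], progress = FALSE)
  studies <- purrr::imap(as.integer(study_sizes), function(n, i) {
    sim$frequencies |>
      dplyr::transmute(study_id = sprintf("synth%02d", i),
                       population = "SYN", gene = .data$gene,
                       allele = .data$allele, frequency = .data$freq,
                       sample_size = n)
  }) |> dplyr::bind_rows()
  readr::write_csv(studies, paths[["studies"]], progress = FALSE)
  g_lines <- c(
    "# synthetic self-mapping G-group fixture (hla_nom_g dialect)",
    sim$frequencies |>
      dplyr::arrange(.data$gene, .data$allele) |>
      dplyr::mutate(line = paste0(.data$gene, "*;",
                                  sub("^[^*]+\\*", "", .data$allele),
                                  ";")) |>
      dplyr::pull("line")
  )
  writeLines(g_lines, paths[["g_groups"]])
  invisible(paths)
}
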