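test_that("configs validate frequencies and require a seed", {
  expect_error(sim_config(10), "seed")
  bad <- tibble::tibble(gene = "A", allele = c("A*01:01", "A*02:01"),
                        freq = c(0.6, 0.5))
  expect_error(sim_config(10, genes = "A", frequencies = bad, seed = 1),
               "sum to 1")
  expect_error(tool_profile("t", error_rate = 1.2), "error_rate")
})

test_that("gold standards are Hardy-Weinberg draws from the table", {
  # degenerate table: everyone homozygous
  mono <- tibble::tibble(gene = "A", allele = "A*01:01", freq = 1)
  cfg <- sim_config(20, genes = "A", frequencies = mono, seed = 3)
  gold <- sample_gold(cfg)
  expect_true(all(gold$allele1 == "A*01:01" & gold$allele2 == "A*01:01"))

  # two equifrequent alleles: heterozygosity near 1/2
  duo <- tibble::tibble(gene = "A", allele = c("A*01:01", "A*02:01"),
                        freq = c(0.5, 0.5))
  n <- 4000
  cfg2 <- sim_config(n, genes = "A", frequencies = duo, seed = 4)
  gold2 <- sample_gold(cfg2)
  het <- mean(gold2$allele1 != gold2$allele2)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / n))

  # determinism
  expect_identical(sample_gold(cfg2), sample_gold(cfg2))
})

test_that("noise-free and all-failure limits behave exactly", {
  cfg <- sim_config(50, genes = c("A", "B"),
                    profiles = tool_profile("t", error_rate = 0,
                                            no_call_rate = 0),
                    seed = 9)
  sim <- simulate_benchmark(cfg)
  expect_equal(hla_accuracy(sim$calls, sim$gold)$accuracy, c(1, 1))

  cfg2 <- sim_config(50, genes = "A",
                     profiles = tool_profile("t", error_rate = 0,
                                             no_call_rate = 1),
                     seed = 9)
  sim2 <- simulate_benchmark(cfg2)
  expect_true(all(is.na(sim2$calls$allele1)))
  expect_equal(hla_accuracy(sim2$calls, sim2$gold)$accuracy, 0)
})

test_that("measured accuracy tracks the per-allele error rate", {
  n <- 2000
  eps <- 0.1
  cfg <- sim_config(n, genes = "A",
                    profiles = tool_profile("t", error_rate = eps,
                                            no_call_rate = 0),
                    seed = 12)
  sim <- simulate_benchmark(cfg)
  acc <- hla_accuracy(sim$calls, sim$gold)$accuracy
  se <- sqrt((1 - eps) * eps / (2 * n))
  # a miscall can land on the partner allele, so accuracy can only exceed
  # the naive 1 - eps bound by a whisker; allow 4 SE around it
  expect_lt(abs(acc - (1 - eps)), 4 * se + 0.01)
})

test_that("independent tools' errors factorize; shared load correlates them", {
  n <- 1500
  mk <- function(lambda, seed) {
    profiles <- dplyr::bind_rows(lapply(paste0("t", 1:3), function(t)
      tool_profile(t, error_rate = 0.2, no_call_rate = 0,
                   shared_load = lambda)))
    cfg <- sim_config(n, genes = "A", n_alleles = 20, concentration = 5,
                      profiles = profiles, seed = seed)
    sim <- simulate_benchmark(cfg)
    sc <- lapply(paste0("t", 1:3), function(t) {
      s <- hlabench:::scored_calls(sim$calls, sim$gold, t, "A")
      s$score < 2
    })
    do.call(cbind, sc)
  }

  wrong0 <- mk(0, 21)
  per_tool <- colMeans(wrong0)
  all_wrong <- mean(rowSums(wrong0) == 3)
  expected <- prod(per_tool)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(all_wrong - expected), 4 * se + 0.005)

  # monotone increase of between-tool error correlation with lambda
  cors <- vapply(c(0, 0.5, 0.95), function(l) {
    w <- mk(l, 22)
    mean(c(cor(w[, 1], w[, 2]), cor(w[, 1], w[, 3]), cor(w[, 2], w[, 3])))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("depth-coupled profiles make shallow samples fail more", {
  n <- 1500
  profiles <- tool_profile("t", depth_intercept = 1, depth_slope = -0.15)
  cfg <- sim_config(n, genes = "A", profiles = profiles,
                    depth_meanlog = log(15), depth_sdlog = 0.9, seed = 33)
  expect_error(
    simulate_calls(sample_gold(cfg), profiles, cfg$frequencies,
                   depths = NULL, seed = 33),
    "depth table")
  sim <- simulate_benchmark(cfg)
  sc <- hlabench:::scored_calls(sim$calls, sim$gold, "t", "A") |>
    dplyr::inner_join(sim$depths, by = c("sample_id", "gene"))
  shallow <- sc$score[sc$mean_depth < stats::median(sc$mean_depth)]
  deep <- sc$score[sc$mean_depth >= stats::median(sc$mean_depth)]
  expect_lt(mean(shallow), mean(deep))
})

test_that("single-allele genes cannot absorb a forced miscall", {
  mono <- tibble::tibble(gene = "A", allele = "A*01:01", freq = 1)
  cfg <- sim_config(30, genes = "A", frequencies = mono,
                    profiles = tool_profile("t", error_rate = 1,
                                            no_call_rate = 0),
                    seed = 2)
  expect_error(simulate_benchmark(cfg), "single allele")
})

test_that("fixture bundles are complete, consistent and reproducible", {
  cfg <- sim_config(40, genes = c("A", "B"),
                    profiles = dplyr::bind_rows(
                      tool_profile("t1", 0.05, 0.02),
                      tool_profile("t2", 0.1, 0.05)),
                    seed = 55)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, dir1)
  p2 <- make_fixture(cfg, dir2)

  # byte-identical under the same config
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = f)
  }

  # every reader accepts its file, and the analyses run end to end
  calls <- read_hla_calls(p1[["calls"]])
  gold <- read_hla_gold(p1[["gold"]])
  depths <- read_hla_depths(p1[["depths"]])
  studies <- read_freq_studies(p1[["studies"]])
  g <- read_g_groups(p1[["g_groups"]])

  ncalls <- normalize_table(calls, g)
  ngold <- normalize_table(gold, g)
  expect_equal(ncalls, calls)     # bundle alleles already canonical
  acc <- hla_accuracy(ncalls, ngold)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
  expect_s3_class(hla_concordance(ncalls), "hla_concordance")

  expected <- combine_study_frequencies(studies)
  obs <- observed_frequencies(ncalls, "t1")
  r <- frequency_correlation(obs, expected)
  expect_true(all(r$r > 0.8))
  expect_equal(nrow(depths), 80L)
})

test_that("noiseless fixture frequencies correlate near-perfectly", {
  cfg <- sim_config(2000, genes = "A", n_alleles = 10,
                    profiles = tool_profile("t", error_rate = 0,
                                            no_call_rate = 0),
                    seed = 66)
  dir <- withr::local_tempdir()
  p <- make_fixture(cfg, dir)
  calls <- read_hla_calls(p[["calls"]])
  studies <- read_freq_studies(p[["studies"]])
  r <- frequency_correlation(observed_frequencies(calls, "t"),
                             combine_study_frequencies(studies),
                             observed_col = "freq_per_chromosome")
  expect_gte(r$r, 0.99)
})
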