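priority_for <- function(tools, gene = "A") {
  tibble::tibble(gene = gene, tool = tools, accuracy = NA_real_,
                 rank = seq_along(tools))
}

test_that("majority vote picks the most frequent complete pair", {
  calls <- make_calls(
    list("S1", "A", "t1", "A*01:01", "A*02:01"),
    list("S1", "A", "t2", "A*01:01", "A*02:01"),
    list("S1", "A", "t3", "A*01:01", "A*03:01"),
    list("S1", "A", "t4", NA_character_, NA_character_),  # abstains
    list("S1", "A", "t5", "A*01:01", NA_character_)       # partial abstains
  )
  cons <- hla_consensus(calls, paste0("t", 1:5),
                        priority_for(paste0("t", 1:5)))
  expect_equal(cons$allele1, "A*01:01")
  expect_equal(cons$allele2, "A*02:01")
})

test_that("vote ties go to the pair backed by the better-ranked tool", {
  calls <- make_calls(
    list("S1", "A", "worse", "A*01:01", "A*03:01"),
    list("S1", "A", "better", "A*01:01", "A*02:01")
  )
  pri <- priority_for(c("better", "worse"))   # better = rank 1
  cons <- hla_consensus(calls, c("better", "worse"), pri)
  expect_equal(cons$allele2, "A*02:01")
  # flipping the ranking flips the winner
  pri2 <- priority_for(c("worse", "better"))
  cons2 <- hla_consensus(calls, c("better", "worse"), pri2)
  expect_equal(cons2$allele2, "A*03:01")
})

test_that("degenerate ensembles behave as documented", {
  calls <- make_calls(
    list("S1", "A", "t1", "A*01:01", "A*02:01"),
    list("S2", "A", "t1", NA_character_, NA_character_),
    list("S3", "A", "t2", "A*03:01", "A*03:01")
  )
  pri <- priority_for(c("t1", "t2"))
  # subset of size 1 reproduces that tool's complete calls
  solo <- hla_consensus(calls, "t1", pri)
  expect_equal(solo$sample_id, c("S1", "S2"))
  expect_equal(solo$allele1, c("A*01:01", NA))
  # disjoint coverage -> union coverage
  both <- hla_consensus(calls, c("t1", "t2"), pri)
  expect_setequal(both$sample_id, c("S1", "S2", "S3"))
  # all tools no-call -> no-call row
  expect_true(is.na(both$allele1[both$sample_id == "S2"]))
  expect_error(hla_consensus(calls, c("t1", "missing"), pri), "missing")
})

test_that("consensus is deterministic under row permutation", {
  set.seed(31)
  cfg <- sim_config(40, genes = c("A", "B"), seed = 99)
  sim <- simulate_benchmark(cfg)
  pri <- hla_tool_priority(sim$calls, sim$gold)
  tools <- unique(sim$calls$tool)
  base <- hla_consensus(sim$calls, tools, pri)
  for (i in 1:3) {
    shuffled <- sim$calls[sample(nrow(sim$calls)), ]
    expect_equal(hla_consensus(shuffled, tools, pri), base)
  }
})

test_that("greedy selection seeds with best tool plus best complement", {
  # planted: t_a correct on 1-80, t_b on 41-100, t_c on 1-60
  inst <- planted_instance(100, list(t_a = 1:80, t_b = 41:100, t_c = 1:60))
  sel <- hla_select_tools(inst$calls, inst$gold)
  # best individual: t_a (80) over t_b (60), t_c (60)
  expect_equal(sel$tools[1], "t_a")
  # complement on t_a's misses (81-100): t_b rescues 20, t_c rescues 0
  expect_equal(sel$tools[2], "t_b")
  # nested trajectory covering all tools
  expect_equal(sel$trajectory$step, 1:3)
  expect_setequal(sel$tools, c("t_a", "t_b", "t_c"))

  # two identical tools plus one complementary: complement chosen
  inst2 <- planted_instance(60, list(t1 = 1:40, t2 = 1:40, t3 = 31:60))
  sel2 <- hla_select_tools(inst2$calls, inst2$gold)
  expect_equal(sel2$tools[1], "t1")
  expect_equal(sel2$tools[2], "t3")
})

test_that("each greedy step ties the exhaustive best extension", {
  set.seed(17)
  for (rep in 1:3) {
    cfg <- sim_config(30, genes = "A",
                      profiles = dplyr::bind_rows(lapply(
                        paste0("t", 1:5),
                        function(t) tool_profile(t, error_rate = 0.25,
                                                 no_call_rate = 0.05))),
                      seed = 100 + rep)
    sim <- simulate_benchmark(cfg)
    pri <- hla_tool_priority(sim$calls, sim$gold)
    sel <- hla_select_tools(sim$calls, sim$gold, priority = pri)
    genes <- sel$genes
    for (k in 3:length(sel$tools)) {
      prev <- sel$tools[seq_len(k - 1L)]
      cands <- setdiff(sel$tools, prev)
      best <- max(vapply(cands, function(t) {
        subset_consensus_accuracy(sim$calls, sim$gold, c(prev, t), pri,
                                  genes)
      }, numeric(1)))
      expect_equal(sel$trajectory$accuracy[k], best, tolerance = 1e-12)
    }
  }
})

test_that("tidy, glance and autoplot summarize a selection", {
  inst <- planted_instance(30, list(t1 = 1:20, t2 = 11:30, t3 = 1:15))
  sel <- hla_select_tools(inst$calls, inst$gold)
  expect_equal(tidy(sel), sel$trajectory)
  g <- glance(sel)
  expect_equal(g$n_tools, 3L)
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
})

test_that("an odd independent ensemble calls wherever any tool called", {
  set.seed(5)
  cfg <- sim_config(200, genes = "A",
                    profiles = dplyr::bind_rows(lapply(
                      paste0("t", 1:5),
                      function(t) tool_profile(t, error_rate = 0.1,
                                               no_call_rate = 0))),
                    seed = 41)
  sim <- simulate_benchmark(cfg)
  pri <- hla_tool_priority(sim$calls, sim$gold)
  cons <- hla_consensus(sim$calls, paste0("t", 1:5), pri)
  expect_false(anyNA(cons$allele1))
  expect_equal(nrow(cons), 200L)
})
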