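test_that("the shipped benchmark config has the canonical panel structure", {
  cfg <- lqts_replica_config(seed = 1)
  expect_equal(sum(cfg$genes$n_pathogenic + cfg$genes$n_benign), 312)
  expect_equal(cfg$genes[cfg$genes$gene == "KCNQ1", c("n_pathogenic", "n_benign")],
               data.frame(n_pathogenic = 101L, n_benign = 8L, row.names = 1L))
  expect_equal(unlist(cfg$genes[cfg$genes$gene == "SCN5A",
                                c("n_pathogenic", "n_benign")], use.names = FALSE),
               c(99L, 14L))
  expect_equal(nrow(cfg$tools), 7)
  expect_equal(sum(cfg$tools$metaserver), 2)
  expect_identical(cfg$tools$polarity[cfg$tools$tool == "SIFT"],
                   "low_is_damaging")
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- lqts_replica_config(seed = 42)
  p1 <- generate_panel(cfg)
  set.seed(999); before <- runif(3)
  set.seed(999)
  p2 <- generate_panel(cfg)
  after <- runif(3)
  expect_identical(p1, p2)
  expect_identical(before, after)   # caller RNG state untouched
  p3 <- generate_panel(lqts_replica_config(seed = 43))
  expect_false(identical(p1$calls, p3$calls))
})

test_that("perfect tools reproduce the truth exactly", {
  cfg <- simulation_config(
    genes = data.frame(gene = "G", n_pathogenic = 50L, n_benign = 50L),
    tools = data.frame(tool = c("A", "B"), sensitivity = 1, specificity = 1),
    rho = 0.5, missing_rate = 0, seed = 2
  )
  panel <- generate_panel(cfg)
  truth_call <- ifelse(panel$variants$truth == "pathogenic",
                       "damaging", "tolerated")
  expect_identical(unname(panel$calls[, "A"]), truth_call)
  expect_identical(unname(panel$calls[, "B"]), truth_call)
})

test_that("generated panels satisfy the data contracts end to end", {
  panel <- generate_panel(lqts_replica_config(seed = 3))
  # every variant passes the inclusion filter by construction
  res <- apply_inclusion_filter(panel$variants)
  expect_equal(nrow(res$rejected), 0)
  expect_true(all(panel$variants$region %in%
                  c("n_term", "transmembrane", "c_term", "loop")))
  # scores exist wherever calls do
  expect_identical(is.na(panel$calls), is.na(panel$scores))
  # round-trips through the TSV layer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  p2 <- read_panel(path, panel_schema(panel))
  expect_identical(unname(p2$calls), unname(panel$calls))
})

test_that("configured error rates are recovered at large n", {
  cfg <- simulation_config(
    genes = data.frame(gene = "G", n_pathogenic = 2000L, n_benign = 2000L),
    tools = data.frame(tool = "T1", sensitivity = 0.9, specificity = 0.8),
    rho = 0, missing_rate = 0, seed = 4
  )
  panel <- generate_panel(cfg)
  path <- panel$variants$truth == "pathogenic"
  sens_hat <- mean(panel$calls[path, "T1"] == "damaging")
  spec_hat <- mean(panel$calls[!path, "T1"] == "tolerated")
  # 3-sigma binomial bands at n = 2000 per class
  expect_lt(abs(sens_hat - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))
  expect_lt(abs(spec_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
})

test_that("score separation drives the score AUC monotonically", {
  auc_at <- function(sep) {
    cfg <- simulation_config(
      genes = data.frame(gene = "G", n_pathogenic = 600L, n_benign = 600L),
      tools = data.frame(tool = "T1", sensitivity = 0.85, specificity = 0.85,
                         polarity = "high_is_damaging", separation = sep,
                         metaserver = FALSE),
      rho = 0, missing_rate = 0, seed = 5
    )
    panel <- generate_panel(cfg)
    roc_curve(panel$scores[, "T1"], panel$variants$truth)$auc
  }
  aucs <- vapply(c(0.5, 2, 6), auc_at, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("invalid configurations are rejected", {
  genes <- data.frame(gene = "G", n_pathogenic = 5L, n_benign = 5L)
  tools <- data.frame(tool = "T1", sensitivity = 0.9, specificity = 0.9)
  expect_error(simulation_config(genes, tools, rho = 1, seed = 1), "rho")
  expect_error(simulation_config(genes, tools, missing_rate = 1, seed = 1),
               "missing_rate")
  expect_error(simulation_config(genes, tools, seed = NULL), "seed")
  bad <- tools; bad$sensitivity <- 1.2
  expect_error(simulation_config(genes, bad, seed = 1), "sensitivity")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- lqts_replica_config(seed = 6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_equal(cfg2$genes, cfg$genes)
  expect_equal(cfg2$tools, cfg$tools)
  expect_equal(cfg2$rho, cfg$rho)
  expect_identical(generate_panel(cfg2)$calls, generate_panel(cfg)$calls)
})
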