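test_that("the winner-take-all call follows the floor, tie and sign rules", {
  expect_identical(call_sample(0, 0), "indeterminate")
  expect_identical(call_sample(5, 5), "indeterminate")
  expect_identical(call_sample(8, 2), "positive")
  expect_identical(call_sample(2, 8), "negative")
  expect_identical(call_sample(0.4, 0.3), "indeterminate")  # below floor
  expect_identical(call_sample(0.6, 0.6005), "indeterminate")  # within eps
  expect_error(call_sample(-1, 2), "non-negative")
})

test_that("read_out returns grid-aligned channel signals", {
  spec <- compile_diagnostic_circuit(make_panel4(), make_sample())
  traj <- simulate_ode(spec)
  expect_equal(unname(read_out(traj, readout_time = 0)), c(0, 0))
  final <- read_out(traj)
  expect_true(all(final >= 0))
  expect_error(read_out(traj, readout_time = 123.4), "sampling grid")
  naked <- traj; naked$readout <- NULL
  expect_error(read_out(naked), "readout")
})

test_that("a clearly tumor-dominated sample lights the FAM channel", {
  spec <- compile_diagnostic_circuit(make_panel4(c(1, 1, -1, -1)),
                                     make_sample(c(15, 15), c(5, 5)),
                                     gate3_conc = 17)
  sig <- read_out(simulate_ode(spec))
  expect_gt(sig[["fam"]], sig[["rox"]])
})

test_that("lymph-node binning matches the printed boundaries exactly", {
  expect_identical(bin_lymph_nodes(c(10, 20, 50)),
                   c("part1", "part2", "part3"))
  expect_identical(bin_lymph_nodes(c(15, 16, 28, 29)),
                   c("part1", "part2", "part2", "part3"))
  expect_error(bin_lymph_nodes(-1), ">= 0")
  expect_error(bin_lymph_nodes(5, boundaries = c(20, 10)), "increasing")
  # exhaustive scan against an explicit piecewise rule
  cnt <- 0:120
  manual <- vapply(cnt, function(x)
    if (x <= 15) "part1" else if (x <= 28) "part2" else "part3",
    character(1))
  expect_identical(bin_lymph_nodes(cnt), manual)
})

test_that("confusion bookkeeping sums to cohort size and ignores order", {
  res <- data.frame(
    true_class = c("tumor", "tumor", "tumor", "normal", "normal"),
    call = c("positive", "negative", "indeterminate", "negative", "positive"))
  s <- confusion_summary(res)
  expect_equal(sum(s$counts), 5)
  expect_equal(s$overall_accuracy, 2 / 5)
  expect_equal(s$binary_accuracy, 2 / 4)
  expect_equal(unname(s$per_class_accuracy["tumor"]), 1 / 3)
  s2 <- confusion_summary(res[sample(5), ])
  expect_identical(s$counts, s2$counts)
})

test_that("a separable synthetic cohort classifies perfectly", {
  co <- generate_cohort(marker_cohort_spec(15, 10, n_genes = 30, sigma = 0.3,
                                           seed = 2))
  de <- compute_de(co$expr, co$clinical)
  pan <- select_top_markers(filter_degs(de))
  cls <- classify_cohort(co$expr, co$clinical, pan)
  expect_equal(cls$summary$overall_accuracy, 1)
  expect_equal(nrow(cls$results), 25)
})

test_that("an all-zero cohort is entirely indeterminate", {
  expr <- matrix(0, nrow = 4, ncol = 6,
                 dimnames = list(c("gp1", "gp2", "gn1", "gn2"),
                                 paste0("s", 1:6)))
  clin <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("tumor", "normal"), 3))
  cls <- classify_cohort(expr, clin, make_panel4(), gate3_conc = 17)
  expect_true(all(cls$results$call == "indeterminate"))
  expect_equal(cls$summary$overall_accuracy, 0)
})

test_that("swapping channel inputs swaps positive and negative calls", {
  co <- generate_cohort(marker_cohort_spec(8, 8, n_genes = 20, seed = 6))
  de <- compute_de(co$expr, co$clinical)
  pan <- select_top_markers(filter_degs(de))
  swapped <- structure(list(
    positive = transform(pan$negative, log2FC = -log2FC),
    negative = transform(pan$positive, log2FC = -log2FC)),
    class = "biomarker_panel")
  # gate 3 pinned so the only difference between runs is the channel swap
  a <- classify_cohort(co$expr, co$clinical, pan, gate3_conc = 17)$results
  b <- classify_cohort(co$expr, co$clinical, swapped, gate3_conc = 17)$results
  remap <- c(positive = "negative", negative = "positive",
             indeterminate = "indeterminate")
  expect_identical(unname(remap[a$call]), b$call)
  expect_equal(a$fam_final_nM, b$rox_final_nM, tolerance = 1e-9)
})

test_that("trait classification scores per level against expected channels", {
  # hub expressions perfectly coupled to the binned trait
  n <- 30
  counts <- rep(c(5, 20, 60), each = 10)
  pos <- ifelse(counts <= 28, 40, 2)
  neg <- ifelse(counts <= 28, 5, 30)
  expr <- rbind(hubP = pos, hubN = neg)
  colnames(expr) <- paste0("s", 1:n)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     lymph_node_count = counts)
  res <- classify_trait_cohort(expr, clin, "hubP", "hubN",
                               trait = "lymph_node_count",
                               expected_channel = c(part1 = "FAM",
                                                    part2 = "FAM",
                                                    part3 = "ROX"))
  expect_equal(res$per_level$accuracy, c(1, 1, 1))

  # an empty level reports NA, not zero
  clin2 <- clin; clin2$lymph_node_count <- rep(c(5, 60), 15)
  res2 <- classify_trait_cohort(expr, clin2, "hubP", "hubN",
                                trait = "lymph_node_count",
                                expected_channel = c(part1 = "FAM",
                                                     part2 = "FAM",
                                                     part3 = "ROX"))
  expect_true(is.na(res2$per_level$accuracy[res2$per_level$level == "part2"]))
})

test_that("hub expression independent of the trait scores near chance", {
  set.seed(77)
  n <- 200
  expr <- rbind(hubP = exp(rnorm(n, 3, 0.4)), hubN = exp(rnorm(n, 3, 0.4)))
  colnames(expr) <- paste0("s", 1:n)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     tissue_indicator = rep(0:1, each = n / 2))
  res <- classify_trait_cohort(expr, clin, "hubP", "hubN",
                               trait = "tissue_indicator",
                               expected_channel = c("0" = "ROX", "1" = "FAM"))
  acc <- sum(res$per_level$n_correct) / n
  # binomial 99% band around 0.5 at n = 200
  expect_gt(acc, 0.5 - 2.58 * sqrt(0.25 / n) - 0.05)
  expect_lt(acc, 0.5 + 2.58 * sqrt(0.25 / n) + 0.05)
})

test_that("run_pipeline writes its artifact bundle deterministically", {
  cfg <- default_config(seed = 5)
  cfg$cohort$synthetic$n_genes <- 20L
  cfg$cohort$synthetic$n_case <- 12L
  cfg$cohort$synthetic$n_control <- 8L
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  r1 <- run_pipeline(cfg, out1)
  r2 <- run_pipeline(cfg, out2)
  for (f in c("cohort/expression.tsv", "cohort/clinical.tsv", "de_table.tsv",
              "panel.tsv", "results.csv", "confusion.json", "manifest.json",
              "config.yaml"))
    expect_true(file.exists(file.path(out1, f)), label = f)
  expect_identical(readBin(file.path(out1, "results.csv"), "raw", 1e6),
                   readBin(file.path(out2, "results.csv"), "raw", 1e6))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 5)
  expect_true(nzchar(man$config_md5))
  expect_length(list.files(file.path(out1, "trajectories")), 5L)
})

test_that("ambiguous or incomplete configs are rejected before compute", {
  cfg <- default_config(1)
  cfg$cohort$files <- list(dir = "somewhere")
  expect_error(run_pipeline(cfg, tempfile()), "ambiguous")
  expect_error(run_pipeline(list(seed = 1), tempfile()), "cohort block")
  expect_error(run_pipeline(list(cohort = list(synthetic = list())),
                            tempfile()), "seed")
})
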