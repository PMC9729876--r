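test_that("adjacency equals |cor|^beta with zero diagonal", {
  # perfectly correlated pair stays at 1 for any power
  y <- rbind(a = 1:8, b = 2 * (1:8) + 3, c = c(5, 3, 8, 1, 9, 2, 7, 4))
  adj <- adjacency_matrix(y, beta = 7, log_transform = FALSE)
  expect_equal(adj["a", "b"], 1)
  expect_equal(diag(adj), rep(0, 3), ignore_attr = TRUE)

  # forced arithmetic: cor 0.5 at beta 7
  expect_equal(abs(0.5)^7, 0.0078125)

  # 5x8 toy matrix against a naive double loop
  set.seed(11)
  y2 <- matrix(rnorm(40), nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  adj2 <- adjacency_matrix(y2, beta = 6, log_transform = FALSE)
  for (i in 1:5) for (j in 1:5) {
    want <- if (i == j) 0 else abs(cor(y2[i, ], y2[j, ]))^6
    expect_equal(adj2[i, j], want, tolerance = 1e-12)
  }
  expect_lt(max(abs(adj2 - t(adj2))), 1e-10)
})

test_that("zero-variance genes get zero correlations with a warning", {
  y <- rbind(a = rnorm(6), flat = rep(2, 6), b = rnorm(6))
  expect_warning(adj <- adjacency_matrix(y, 4, log_transform = FALSE),
                 "zero-variance")
  expect_equal(adj["flat", ], c(a = 0, flat = 0, b = 0))
})

test_that("TOM matches the shared-neighbour formula", {
  # no adjacency and no shared neighbours: overlap 0
  a0 <- matrix(0, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  a0["a", "b"] <- a0["b", "a"] <- 0.9
  expect_equal(topological_overlap(a0)["a", "c"], 0)

  # saturated clique: off-diagonal overlap 1
  a1 <- matrix(1, 4, 4); diag(a1) <- 0
  tom1 <- topological_overlap(a1)
  expect_equal(unique(tom1[upper.tri(tom1)]), 1)

  # 3-node toy adjacency evaluated by hand
  a <- matrix(c(0, .5, .2,
                .5, 0, .4,
                .2, .4, 0), 3, 3, byrow = TRUE)
  tom <- topological_overlap(a)
  k <- rowSums(a)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    expect_equal(tom[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(diag(tom), rep(1, 3))
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("module detection separates planted blocks and enforces min size", {
  n <- 80
  tom <- matrix(0.02, n, n,
                dimnames = rep(list(sprintf("g%02d", 1:n)), 2))
  tom[1:40, 1:40] <- 0.9
  tom[41:80, 41:80] <- 0.9
  diag(tom) <- 1
  lab <- detect_modules(tom, cut_height = 0.5)
  expect_length(unique(lab[1:40]), 1L)
  expect_length(unique(lab[41:80]), 1L)
  expect_length(setdiff(unique(lab), 0L), 2L)

  # min size above the largest cluster sends everything to grey
  expect_true(all(detect_modules(tom, cut_height = 0.5,
                                 min_module_size = 50) == 0L))
  expect_error(detect_modules(tom, cut_height = 1.4), "cut_height")
  # determinism
  expect_identical(lab, detect_modules(tom, cut_height = 0.5))
})

test_that("eigengene of identical genes is their z-scored profile", {
  prof <- c(2, 4, 6, 8, 5, 3)
  y <- rbind(a = prof, b = prof, c = prof)
  colnames(y) <- paste0("s", 1:6)
  me <- module_eigengene(y, c(a = 1L, b = 1L, c = 1L), log_transform = FALSE)
  z <- as.numeric(scale(prof)); z <- z / sd(z)
  expect_equal(unname(me[, "ME1"]), z, tolerance = 1e-10)
  # orientation contract: mean correlation with members is positive
  expect_gt(mean(cor(me[, 1], t(y))), 0)
  # flipping all expression values must not break the orientation contract
  me2 <- module_eigengene(-y, c(a = 1L, b = 1L, c = 1L),
                          log_transform = FALSE)
  expect_gt(mean(cor(me2[, 1], t(-y))), 0)
})

test_that("eigengene recovers a planted latent factor", {
  set.seed(17)
  f <- rnorm(60)
  y <- t(sapply(1:10, function(i) 0.9 * f + rnorm(60, sd = 0.3)))
  rownames(y) <- paste0("g", 1:10); colnames(y) <- paste0("s", 1:60)
  me <- module_eigengene(y, setNames(rep(1L, 10), rownames(y)),
                         log_transform = FALSE)
  expect_gte(abs(cor(me[, 1], f)), 0.95)
})

test_that("module-trait correlation propagates value, sign and degeneracy", {
  set.seed(23)
  me <- matrix(rnorm(50), ncol = 1,
               dimnames = list(paste0("s", 1:50), "ME1"))
  clin <- data.frame(sample_id = paste0("s", 1:50),
                     exact = me[, 1], flipped = -2 * me[, 1],
                     flat = rep(1, 50))
  res <- suppressWarnings(
    module_trait_correlation(me, clin, traits = c("exact", "flipped", "flat")))
  expect_equal(res$pearson_r[res$trait == "exact"], 1)
  expect_equal(res$pearson_r[res$trait == "flipped"], -1)
  expect_equal(res$pearson_r[res$trait == "flat"], 0)
  expect_equal(res$p_value[res$trait == "flat"], 1)
  expect_warning(module_trait_correlation(me, clin, traits = "flat"),
                 "constant")
  # agreement with cor.test on a noisy trait
  clin$noisy <- me[, 1] + rnorm(50)
  res2 <- module_trait_correlation(me, clin, traits = "noisy")
  ct <- cor.test(me[, 1], clin$noisy)
  expect_equal(res2$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("independent eigengene-trait pairs rarely exceed |r| 0.1 at n 1000", {
  set.seed(31)
  hits <- 0L
  for (s in 1:100) {
    r <- cor(rnorm(1000), rnorm(1000))
    hits <- hits + (abs(r) < 0.1)
  }
  expect_gte(hits, 95L)
})

test_that("hub gene is the kWithin argmax, optionally trait-weighted", {
  ids <- paste0("g", 1:5)
  a <- matrix(0.1, 5, 5, dimnames = list(ids, ids)); diag(a) <- 0
  a[1, ] <- a[, 1] <- 0.9; a[1, 1] <- 0
  lab <- setNames(rep(1L, 5), ids)
  expect_identical(hub_gene(a, lab, 1)$gene_id, "g1")

  # 4-node toy adjacency: argmax of row sums, verified by hand
  set.seed(3)
  b <- matrix(runif(16), 4, 4); b <- (b + t(b)) / 2; diag(b) <- 0
  dimnames(b) <- list(paste0("h", 1:4), paste0("h", 1:4))
  labb <- setNames(rep(1L, 4), rownames(b))
  expect_identical(hub_gene(b, labb, 1)$gene_id,
                   rownames(b)[which.max(rowSums(b))])
  expect_error(hub_gene(b, labb, 99), "unknown or empty")

  # trait weighting can move the hub to a better-correlated gene
  set.seed(5)
  tr <- rnorm(30)
  y <- rbind(g1 = rnorm(30, sd = 0.1) + 0.2 * tr,
             g2 = tr + rnorm(30, sd = 0.01),
             g3 = rnorm(30), g4 = rnorm(30), g5 = rnorm(30))
  colnames(y) <- paste0("s", 1:30)
  plain <- hub_gene(a, lab, 1)
  weighted <- hub_gene(a, lab, 1, expr = fpkm_from_log2(abs(y) + 2),
                       trait = tr)
  expect_identical(plain$gene_id, "g1")
  expect_true(is.character(weighted$gene_id))
})

test_that("soft-threshold search falls back to the argmax with a warning", {
  set.seed(13)
  y <- matrix(rnorm(30 * 10), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  expect_warning(
    pst <- pick_soft_threshold(y, powers = 1:6, log_transform = FALSE),
    "argmax")
  expect_false(pst$reached_target)
  expect_identical(pst$beta,
                   pst$fit$power[which.max(pst$fit$fit_r2)])
  expect_error(pick_soft_threshold(matrix(1, 5, 6)), "constant")
})

test_that("the scale-free testbed reaches the topology fit target", {
  tb <- network_testbed("scale_free", seed = 4)
  co <- generate_cohort(tb$spec)
  pst <- suppressWarnings(pick_soft_threshold(co$expr))
  expect_gte(max(pst$fit$fit_r2), 0.8)
})

test_that("the modular testbed yields full module and hub recovery", {
  tb <- network_testbed("modular", seed = 1)
  co <- generate_cohort(tb$spec)
  pst <- suppressWarnings(pick_soft_threshold(co$expr))
  adj <- adjacency_matrix(co$expr, pst$beta)
  tom <- topological_overlap(adj)
  expect_lt(max(abs(tom - t(tom))), 1e-10)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  lab <- detect_modules(tom)
  expect_gte(adjusted_rand_index(tb$planted_labels, lab), 0.8)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(c(1, 2, 2, 1), 25))), 0.2)
})
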