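test_that("gene_signature enforces disjoint, duplicate-free sets", {
  expect_error(gene_signature(up = c("a", "a")), "duplicate")
  expect_error(gene_signature(up = "a", down = "a"), "disjoint")
  expect_error(gene_signature(), "non-empty")
  sig <- gene_signature(up = c("a", "b"), down = "c")
  expect_s3_class(sig, "gene_signature")
  expect_length(intersect(sig$up, sig$down), 0)
})

test_that("genewise Welch statistics agree with stats::t.test", {
  set.seed(11)
  expr <- matrix(rnorm(50 * 9, mean = 6), 50, 9,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:9)))
  groups <- rep(c("A", "B"), c(4, 5))
  res <- compute_deg_signature(expr, groups, p_threshold = 1)$deg_table
  for (i in c(1, 17, 50)) {
    tt <- t.test(expr[i, groups == "A"], expr[i, groups == "B"])
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2_fold_change[i],
                 unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("planted DEGs are recovered with the paper-style top-ranked cut", {
  sim <- simulate_expression(n_genes = 2000, n_up = 100, n_down = 150,
                             effect = 2, noise_sd = 0.5,
                             n_per_group = c(6, 6), seed = 101)
  res <- compute_deg_signature(sim$expr, sim$groups, p_threshold = 0.05,
                               max_up = 100, max_down = 150)
  sens <- (sum(res$signature$up %in% sim$truth$up) +
             sum(res$signature$down %in% sim$truth$down)) /
    (length(sim$truth$up) + length(sim$truth$down))
  null_genes <- setdiff(rownames(sim$expr),
                        c(sim$truth$up, sim$truth$down))
  fp <- sum(c(res$signature$up, res$signature$down) %in% null_genes)
  expect_gte(sens, 0.95)
  expect_lte(fp / length(null_genes), 0.01)
})

test_that("null P values are uniform: pass fraction ~ alpha", {
  sim <- simulate_expression(n_genes = 10000, n_up = 0, n_down = 0,
                             effect = 0, noise_sd = 0.5, seed = 202)
  tab <- compute_deg_signature(sim$expr, sim$groups,
                               p_threshold = 0.05)$deg_table
  frac <- mean(tab$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("DEG calling is invariant to sample and gene order", {
  set.seed(5)
  sim <- simulate_expression(n_genes = 300, n_up = 20, n_down = 20,
                             seed = 30)
  base <- compute_deg_signature(sim$expr, sim$groups,
                                contrast = c("A", "B"))
  perm_s <- sample(ncol(sim$expr))
  perm_g <- sample(nrow(sim$expr))
  shuf <- compute_deg_signature(sim$expr[perm_g, perm_s],
                                sim$groups[perm_s],
                                contrast = c("A", "B"))
  expect_setequal(base$signature$up, shuf$signature$up)
  expect_setequal(base$signature$down, shuf$signature$down)
  reord <- shuf$deg_table[match(base$deg_table$gene_id,
                                shuf$deg_table$gene_id), ]
  expect_equal(base$deg_table$p_value, reord$p_value, tolerance = 1e-12)
})

test_that("sensitivity is non-decreasing in planted effect size", {
  sens_at <- function(effect) {
    sim <- simulate_expression(n_genes = 1000, n_up = 50, n_down = 50,
                               effect = effect, noise_sd = 0.5, seed = 404)
    res <- compute_deg_signature(sim$expr, sim$groups)
    (sum(res$signature$up %in% sim$truth$up) +
       sum(res$signature$down %in% sim$truth$down)) / 100
  }
  s <- vapply(c(0.25, 0.75, 2), sens_at, numeric(1))
  expect_true(all(diff(s) >= 0))
  expect_gt(s[3], s[1])
})

test_that("degenerate rows and insufficient replication are handled", {
  expr <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expr[1, ] <- 3 # all-constant row -> p = 1
  groups <- c("A", "A", "B", "B")
  tab <- compute_deg_signature(expr, groups, p_threshold = 1)$deg_table
  expect_equal(tab$p_value[tab$gene_id == "g1"], 1)
  expect_error(compute_deg_signature(expr, c("A", "B", "B", "B")),
               "insufficient replication")
})

test_that("signature sides always come from the expression genes", {
  sim <- simulate_expression(n_genes = 500, n_up = 30, n_down = 30,
                             seed = 77)
  res <- compute_deg_signature(sim$expr, sim$groups)
  expect_true(all(c(res$signature$up, res$signature$down) %in%
                    rownames(sim$expr)))
  expect_length(intersect(res$signature$up, res$signature$down), 0)
  up_rows <- res$deg_table[match(res$signature$up, res$deg_table$gene_id), ]
  expect_true(all(up_rows$log2_fold_change > 0))
})

test_that("restrict_to_universe drops absent genes with one warning each", {
  sig <- gene_signature(up = c("Nes", "Sox2", "Nanog", "Ddx56", "Pou5f1"),
                        name = "stemness")
  universe <- c("Nes", "Sox2", "Nanog", "other1", "other2")
  warns <- character()
  res <- withCallingHandlers(
    restrict_to_universe(sig, universe),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_setequal(res$up, c("Nes", "Sox2", "Nanog"))
  expect_length(res$down, 0)
  expect_length(warns, 2)
  expect_true(any(grepl("Ddx56", warns)) && any(grepl("Pou5f1", warns)))

  # fully inside -> identity; fully outside -> error
  full <- gene_signature(up = c("a", "b"), down = "c")
  expect_identical(restrict_to_universe(full, c("a", "b", "c", "d"))[1:2],
                   full[1:2])
  expect_error(suppressWarnings(restrict_to_universe(full, c("x", "y"))),
               "disjoint from universe")
})

test_that("one side can be emptied by restriction, warnings match drops", {
  sig <- gene_signature(up = c("u1", "u2"), down = c("d1", "d2", "d3"))
  universe <- c("d1", "d3", "zz")
  warns <- testthat::capture_warnings(res <- restrict_to_universe(sig,
                                                                  universe))
  expect_length(res$up, 0)
  expect_setequal(res$down, c("d1", "d3"))
  expect_length(warns, 3)
})
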