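make_sigs <- function(universe) {
  list(stem = gene_signature(up = universe[1:5], name = "stemness"),
       tendon = gene_signature(up = universe[6:15], down = universe[16:25],
                               name = "tendon"))
}

test_that("planted reversers occupy the top reverse-orientation scores", {
  genes <- sprintf("g%04d", 1:300)
  sigs <- make_sigs(genes)
  sim <- simulate_ctp_library(genes, sigs$stem, sigs$tendon,
                              n_compounds = 105, n_tendon_hits = 5,
                              reversal_strength = 4, seed = 91)
  scores <- suppressWarnings(
    score_library(sim$library, sigs$tendon, orientation = "reverse"))
  top5 <- names(sort(scores, decreasing = TRUE))[1:5]
  expect_setequal(top5, sim$truth$tendon_hits)
  expect_identical(names(scores), rownames(sim$library$delta))
})

test_that("a compound mimicking the signature scores maximal", {
  genes <- sprintf("g%04d", 1:100)
  sig <- gene_signature(up = genes[1:5], down = genes[6:10], name = "s")
  set.seed(17)
  delta <- matrix(rnorm(20 * 100), 20, 100,
                  dimnames = list(sprintf("c%02d", 1:20), genes))
  delta["c07", sig$up] <- 10
  delta["c07", sig$down] <- -10
  scores <- score_library(compound_library(delta), sig, "mimic")
  expect_identical(names(which.max(scores)), "c07")
})

test_that("empty library gives an empty result", {
  m <- matrix(numeric(0), 0, 3,
              dimnames = list(character(0), c("a", "b", "c")))
  sig <- gene_signature(up = "a")
  expect_length(score_library(compound_library(m), sig), 0)
})

test_that("dual screen recovers planted dual hits exactly", {
  genes <- sprintf("g%04d", 1:500)
  sigs <- make_sigs(genes)
  sim <- simulate_ctp_library(genes, sigs$stem, sigs$tendon,
                              n_compounds = 400, n_stemness_hits = 10,
                              n_tendon_hits = 10, n_dual_hits = 5,
                              reversal_strength = 4, seed = 123)
  # 15 compounds are planted on each axis (10 single-axis + 5 dual); the
  # matching depth selects exactly the dual hits
  tab <- suppressWarnings(
    dual_score_screen(sim$library, sigs$stem, sigs$tendon,
                      top_k_stemness = 15, top_k_tendon = 15))
  expect_setequal(tab$compound_id[tab$selected], sim$truth$dual_hits)
})

test_that("selection is monotone in top_k and degenerate at full depth", {
  genes <- sprintf("g%04d", 1:200)
  sigs <- make_sigs(genes)
  sim <- simulate_ctp_library(genes, sigs$stem, sigs$tendon,
                              n_compounds = 60, n_dual_hits = 4,
                              reversal_strength = 3, seed = 7)
  screen_at <- function(k) suppressWarnings(
    dual_score_screen(sim$library, sigs$stem, sigs$tendon,
                      top_k_stemness = k, top_k_tendon = k))
  sel <- lapply(c(5, 15, 40, 60), function(k) {
    t <- screen_at(k)
    t$compound_id[t$selected]
  })
  for (i in 1:3) expect_true(all(sel[[i]] %in% sel[[i + 1]]))
  expect_length(sel[[4]], 60) # top_k = library size selects everything
  expect_error(screen_at(0), "top_k")
  expect_error(screen_at(61), "top_k")
})

test_that("scores and ranks are invariant to library row order", {
  genes <- sprintf("g%04d", 1:150)
  sigs <- make_sigs(genes)
  sim <- simulate_ctp_library(genes, sigs$stem, sigs$tendon,
                              n_compounds = 50, n_dual_hits = 3,
                              reversal_strength = 3, seed = 19)
  tab1 <- suppressWarnings(dual_score_screen(sim$library, sigs$stem,
                                             sigs$tendon, 10, 10))
  set.seed(2)
  perm <- sample(50)
  lib2 <- compound_library(sim$library$delta[perm, ])
  tab2 <- suppressWarnings(dual_score_screen(lib2, sigs$stem,
                                             sigs$tendon, 10, 10))
  m <- match(tab1$compound_id, tab2$compound_id)
  expect_equal(tab1$stemness_score, tab2$stemness_score[m])
  expect_equal(tab1$tendon_score, tab2$tendon_score[m])
  expect_identical(tab1$stemness_rank, tab2$stemness_rank[m])
  expect_identical(tab1$tendon_rank, tab2$tendon_rank[m])
})

test_that("ranks are a permutation of 1..n with lexicographic tie-break", {
  genes <- sprintf("g%04d", 1:80)
  sigs <- make_sigs(genes)
  set.seed(3)
  delta <- matrix(rnorm(30 * 80), 30, 80,
                  dimnames = list(sprintf("c%02d", 1:30), genes))
  tab <- suppressWarnings(dual_score_screen(compound_library(delta),
                                            sigs$stem, sigs$tendon, 5, 5))
  expect_setequal(tab$stemness_rank, 1:30)
  expect_setequal(tab$tendon_rank, 1:30)
  # ties (many up-only stemness scores coincide at 0-width grids) must be
  # ordered by compound id
  for (s in unique(tab$stemness_score)) {
    sub <- tab[tab$stemness_score == s, ]
    if (nrow(sub) > 1)
      expect_identical(sub$compound_id[order(sub$stemness_rank)],
                       sort(sub$compound_id))
  }
})

test_that("universe mismatch and metadata misuse raise errors", {
  m <- matrix(1, 2, 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(compound_library(m, metadata = data.frame(x = 1)),
               "compound_id")
  m2 <- m
  m2[1, 1] <- NA
  expect_error(compound_library(m2), "non-finite")
  rownames(m2) <- c("c1", "c1")
  expect_error(compound_library(m2), "unique rownames")
})

test_that("screen table round-trips through TSV with fixed columns", {
  genes <- sprintf("g%04d", 1:100)
  sigs <- make_sigs(genes)
  sim <- simulate_ctp_library(genes, sigs$stem, sigs$tendon,
                              n_compounds = 25, n_dual_hits = 2,
                              reversal_strength = 3, seed = 5)
  tab <- suppressWarnings(dual_score_screen(sim$library, sigs$stem,
                                            sigs$tendon, 5, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_table(tab, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header, c("compound_id", "name", "stemness_score",
                             "tendon_score", "stemness_rank",
                             "tendon_rank", "selected"))
  back <- read_screen_table(path)
  expect_identical(back$compound_id, tab$compound_id)
  expect_identical(back$selected, tab$selected)
  expect_type(back$selected, "logical")
  expect_equal(back$stemness_score, tab$stemness_score, tolerance = 1e-10)
})
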