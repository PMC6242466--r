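test_that("dataset compilation follows the per-category rules", {
  # deletion fitness: simple addition of -1/0/+1 calls
  del <- data.frame(gene_id = rep(c("g1", "g2"), each = 4),
                    value = c(1, 1, -1, 0, -1, -1, -1, 0),
                    source_id = rep(paste0("s", 1:4), 2))
  d <- compile_dataset(del, "deletion_fitness")
  expect_equal(unname(d$scores[c("g1", "g2")]), c(1, -3))

  # mrna: mean over the sources a gene appears in
  mr <- data.frame(gene_id = c("g1", "g1", "g2"), value = c(2, 4, 5),
                   source_id = c("s1", "s2", "s1"))
  expect_equal(unname(compile_dataset(mr, "mrna")$scores[c("g1", "g2")]),
               c(3, 5))

  # abundance: SD-normalize each source, then add
  ab <- data.frame(gene_id = c("g1", "g2", "g1", "g2"),
                   value = c(2, -2, 4, -4),
                   source_id = c("s1", "s1", "s2", "s2"))
  sc <- compile_dataset(ab, "protein_abundance")$scores
  expect_equal(unname(sc["g1"]), 2 / sd(c(2, -2)) + 4 / sd(c(4, -4)))

  # flux: sum of |Z| over top lists; absentees in the universe score 0
  fl <- data.frame(gene_id = c("g1", "g1", "g1"), value = c(2.0, -1.5, 3.0),
                   compartment = c("C1", "C2", "C3"), timepoint = 1)
  f <- compile_dataset(fl, "flux", universe = c("g1", "g2"))
  expect_equal(unname(f$scores[c("g1", "g2")]), c(6.5, 0))
  fl_na <- fl; fl_na$value[2] <- NA
  expect_error(compile_dataset(fl_na, "flux"), "Z-scores")

  # flux compilation is invariant to record order
  f2 <- compile_dataset(fl[c(3, 1, 2), ], "flux", universe = c("g1", "g2"))
  expect_equal(f$scores, f2$scores)

  # phospho: qualitative calls pass through, quantitative are SD-normalized
  ph <- data.frame(gene_id = c("g1", "g1", "g2"), value = c(1, 6, -6),
                   source_id = c("q1", "s1", "s1"),
                   source_type = c("qualitative", "quantitative",
                                   "quantitative"))
  psc <- compile_dataset(ph, "phospho")$scores
  expect_equal(unname(psc["g1"]), 1 + 6 / sd(c(6, -6)))

  expect_error(compile_dataset(del, "proteomics"), "unknown category")
})

test_that("top-fraction overlap scan matches exact hypergeometric values", {
  # universe of 10, top sets of sizes 5 and 4 sharing 4 genes
  uni <- paste0("g", 1:10)
  dsA <- ranked_dataset(setNames(10:1, uni), ranking = uni)
  dsB <- ranked_dataset(setNames(10:1, uni),
                        ranking = c("g1", "g2", "g3", "g4", "g6", "g5",
                                    paste0("g", 7:10)))
  r <- suppressWarnings(overlap_significance(dsA, dsB, fractions = 0.45))
  expect_equal(r$grid$size_a, 4)
  expect_equal(r$grid$overlap, 4)
  expect_equal(r$grid$p, choose(4, 4) * choose(6, 0) / choose(10, 4))
  # cross-check the 5-vs-4 worked case directly
  expect_equal(hypergeom_overrep(paste0("g", 1:5), paste0("g", 1:4), uni),
               5 / 210, tolerance = 1e-12)

  # identical rankings: overlap saturates and min_p is attained
  set.seed(3)
  sc <- setNames(rnorm(200), paste0("g", 1:200))
  ds <- ranked_dataset(sc)
  ident <- overlap_significance(ds, ds)
  expect_equal(ident$grid$overlap, ident$grid$size_a)
  expect_equal(ident$min_p, min(ident$grid$p))
  expect_equal(ident$neg_log10_min_p, -log10(ident$min_p))
  expect_equal(ident$min_p_corrected, min(1, ident$min_p * 6))

  # symmetry in the two arguments
  sc2 <- setNames(rnorm(200), paste0("g", 1:200))
  ds2 <- ranked_dataset(sc2)
  ab <- overlap_significance(ds, ds2)
  ba <- overlap_significance(ds2, ds)
  expect_equal(ab$min_p, ba$min_p)
  expect_equal(ab$universe_size, ba$universe_size)

  expect_error(overlap_significance(
    ranked_dataset(c(a = 1)), ranked_dataset(c(b = 1))), "empty shared")
})

test_that("correlated external datasets overlap more than independent ones", {
  p <- screen_sim_params(n_strains = 1000, days = 1:3, spike_fraction = 0.1,
                         seed = 17)
  truth <- simulate_screen(p)$truth
  truth_ranking <- ranked_dataset(
    setNames(truth$true_effect_log2 +
               1e-9 * seq_along(truth$strain_id), truth$strain_id))
  wins <- vapply(1:20, function(s) {
    hi <- simulate_external_dataset(truth, "mrna", corr = 0.7, seed = s)
    lo <- simulate_external_dataset(truth, "mrna", corr = 0, seed = s + 500)
    overlap_significance(truth_ranking, hi)$neg_log10_min_p >
      overlap_significance(truth_ranking, lo)$neg_log10_min_p
  }, TRUE)
  expect_gt(mean(wins), 0.8)
})

test_that("running overlap curves reflect rank enrichment", {
  ranking <- paste0("g", 1:1000)

  top <- ranking[1:200]
  cv <- running_overlap_curve(ranking, top)
  expect_gt(mean(cv$fraction[1:100]), 0.8)
  expect_lt(mean(cv$fraction[901:1000]), 0.1)
  expect_true(all(cv$fraction >= 0 & cv$fraction <= 1))

  set.seed(11)
  rnd <- sample(ranking, 200)
  cr <- running_overlap_curve(ranking, rnd)
  mid <- cr$fraction[100:900]   # ends have one-sided smoothing windows
  expect_lt(max(abs(mid - 0.2)), 0.05)

  expect_error(running_overlap_curve(ranking, character(0)), "empty")
  expect_error(running_overlap_curve(ranking, "nope"), "contained")
})

test_that("signed screen ranking puts directions at opposite ends", {
  eff <- c(rep(0, 40), rep(1.5, 5), rep(-1.5, 5))
  tab <- tiny_table(50, days = 1:3, n_rep = 4, effect = eff)
  set.seed(8)
  tab$density <- tab$density * 2^rnorm(nrow(tab), 0, 0.05)
  attr(tab, "stage") <- "raw"
  res <- test_screen(quantile_normalize_table(log_transform(tab)),
                     test_params(window = 11))
  rk <- rank_screen_results(res, mode = "signed")
  strains <- sprintf("S%02d", 1:50)
  dec <- strains[eff < 0]; inc <- strains[eff > 0]
  pos <- match(c(dec, inc), rk$ranking)
  expect_true(all(match(dec, rk$ranking) <= 10))
  expect_true(all(match(inc, rk$ranking) >= 41))
  # p-value mode: both effect groups at the top
  rp <- rank_screen_results(res, mode = "pvalue")
  expect_true(all(match(c(dec, inc), rp$ranking) <= 15))
})

test_that("pairwise overlap matrix is symmetric", {
  set.seed(2)
  dss <- lapply(1:3, function(i)
    ranked_dataset(setNames(rnorm(100), paste0("g", 1:100))))
  names(dss) <- c("a", "b", "c")
  m <- overlap_matrix(dss)
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
})
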