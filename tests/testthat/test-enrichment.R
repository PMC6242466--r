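test_that("hypergeometric over-representation handles the boundary cases", {
  uni <- paste0("g", 1:10)
  expect_equal(hypergeom_overrep(uni[1:5], uni[6:9], uni), 1)  # P(X >= 0)
  expect_equal(hypergeom_overrep(uni, uni, uni), 1)
  expect_equal(hypergeom_overrep(uni[1:5], uni[1:4], uni), 5 / 210,
               tolerance = 1e-12)
  expect_error(hypergeom_overrep(c("zz"), uni[1:2], uni), "contained")
})

test_that("hypergeometric p matches exhaustive draw enumeration", {
  set.seed(13)
  for (rep in 1:60) {
    N <- sample(2:12, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    uni <- paste0("g", 1:N)
    p_impl <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_impl, oracle_hyper_enum(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("conditional enrichment on a flat ontology is unconditional", {
  genes <- paste0("g", 1:60)
  terms <- list(T1 = genes[1:15], T2 = genes[10:30], T3 = genes[40:60])
  edges <- data.frame(child = names(terms), parent = "root")
  ann <- data.frame(term_id = rep(names(terms), lengths(terms)),
                    gene_id = unlist(terms))
  dag <- ontology_dag(edges, ann)
  hits <- genes[c(1:10, 55:58)]
  res <- conditional_enrichment(hits, genes, dag, alpha = 0.05)
  leaf <- res[res$term_id != "root", ]
  for (i in seq_len(nrow(leaf))) {
    expect_equal(leaf$p[i],
                 hypergeom_overrep(hits, terms[[leaf$term_id[i]]], genes))
  }
})

test_that("a significant child is excluded from its parent's test", {
  # root annotated g1-g10 via two children; universe of 20; hits g1-g4
  genes <- paste0("g", sprintf("%02d", 1:20))
  edges <- data.frame(child = c("C1", "C2"), parent = "root")
  ann <- data.frame(term_id = c(rep("C1", 5), rep("C2", 5)),
                    gene_id = genes[1:10])
  dag <- ontology_dag(edges, ann)
  hits <- genes[1:4]
  res <- conditional_enrichment(hits, genes, dag, alpha = 0.05)
  res <- res[match(c("C1", "C2", "root"), res$term_id), ]
  expect_equal(res$p[1], phyper(3, 5, 15, 4, lower.tail = FALSE))
  expect_true(res$enriched[1])
  expect_false(res$enriched[2])
  # root is tested on g6-g10 only: zero overlap, not significant
  expect_equal(res$size_annotated[3], 5)
  expect_equal(res$overlap[3], 0)
  expect_false(res$enriched[3])
  # without conditioning the root would have been significant
  expect_lt(hypergeom_overrep(hits, genes[1:10], genes), 0.05)

  # alpha = 0: nothing significant, conditioning never fires
  res0 <- conditional_enrichment(hits, genes, dag, alpha = 0)
  expect_false(any(res0$enriched))
  expect_equal(res0$size_annotated[res0$term_id == "root"], 10)

  expect_error(
    ontology_dag(data.frame(child = c("a", "b"), parent = c("b", "a")),
                 data.frame(term_id = "a", gene_id = "g1")),
    "cyclic")
})

test_that("uniform null hit sets keep per-term significance near alpha", {
  dag <- simulate_ontology(20, n_genes = 200, seed = 44, extra_edges = 3)
  genes <- dag$genes
  set.seed(45)
  n_draw <- 300
  sig <- replicate(n_draw, {
    hits <- sample(genes, 25)
    mean(conditional_enrichment(hits, genes, dag, alpha = 0.05)$enriched)
  })
  expect_lte(mean(sig), 0.05 + 2 * sd(sig) / sqrt(n_draw) + 0.01)
})

test_that("enrichment map links term pairs strictly above the threshold", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"),
               C = c("x", "y"), D = c("a", "b", "c", "d", "e", "f", "g",
                                      "h"))
  em <- enrichment_map(sets, threshold = 0.25)
  edge_ab <- em[em$term_a == "A" & em$term_b == "B", ]
  expect_equal(edge_ab$jaccard, 0.5)
  expect_false(any(em$term_a == "C" | em$term_b == "C"))
  # Jaccard exactly at the threshold is excluded: |A n D| = 3, |A u D| = 8
  expect_equal(length(intersect(sets$A, sets$D)) /
                 length(union(sets$A, sets$D)), 0.375)
  em2 <- enrichment_map(sets, threshold = 0.375)
  expect_false(any(em2$term_a == "A" & em2$term_b == "D"))
  # invariance under reordering of the term list
  em_r <- enrichment_map(sets[c(3, 1, 4, 2)], threshold = 0.25)
  expect_equal(em[order(em$term_a, em$term_b), ],
               em_r[order(em_r$term_a, em_r$term_b), ],
               ignore_attr = TRUE)
  expect_warning(enrichment_map(c(sets, list(E = character(0)))), "empty")
})

test_that("chi-square independence matches hand computation", {
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  m <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  r <- chi_square_independence(m)
  expect_equal(r$statistic, 18)
  expect_equal(r$df, 1)
  r10 <- chi_square_independence(10 * m)
  expect_equal(r10$statistic, 180)

  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "marginal")
})

test_that("GWAS overlap applies both filters then composes the test", {
  uni <- paste0("y", 1:50)
  hits <- uni[1:10]
  snps <- data.frame(
    snp_id = paste0("rs", 1:6),
    disease = c("t2d", "t2d", "t2d", "t2d", "cancer", "cancer"),
    study_design = c("case_control", "case_control", "cohort",
                     "case_control", "case_control", "case_control"),
    assoc_p = c(1e-8, 1e-6, 1e-9, 1e-4, 1e-7, 1e-6),
    human_gene = paste0("H", 1:6),
    yeast_homolog = c("y1", "y2", "y3", "y4", "y20", "y21"))
  res <- gwas_overlap(snps, hits, uni)
  t2d <- res[res$disease == "t2d", ]
  # rs3 fails the design filter, rs4 fails the p filter: y1, y2 remain
  expect_equal(t2d$n_genes, 2)
  expect_equal(t2d$p, hypergeom_overrep(hits, c("y1", "y2"), uni))
  ca <- res[res$disease == "cancer", ]
  expect_equal(ca$p, hypergeom_overrep(hits, c("y20", "y21"), uni))
  expect_error(gwas_overlap(snps[, -6], hits, uni), "missing mapping")
})
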