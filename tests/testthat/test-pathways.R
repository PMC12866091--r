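test_that("pathway alteration matrix flags any member-gene hit", {
  cat1 <- pathway_catalog(list(PW1 = "G1", PW2 = "G9"))
  v <- qc_record()                              # somatic tumor hit in G1
  tri <- toy_triplet(qc_record()[0, ], qc_record()[0, ], v)
  tri0 <- toy_triplet(qc_record()[0, ], qc_record()[0, ], qc_record()[0, ])
  m <- pathway_alteration_matrix(list(PT = classify_origin(tri),
                                      P0 = classify_origin(tri0)), cat1)
  expect_equal(m["PT", "PW1"], 1L)
  expect_equal(m["PT", "PW2"], 0L)
  expect_equal(unname(m["P0", ]), c(0L, 0L))     # zero-variant patient
})

test_that("pathway column sums recover seeded somatic hits", {
  sim <- noiseless_sim()
  origins <- classify_cohort(sim$cohort, level = "variant")
  genes <- sort(unique(sim$truth$gene))
  catalog <- make_pathway_partition(genes, 7)
  m <- pathway_alteration_matrix(origins, catalog,
                                 classes = "tumor_private")
  tr <- sim$truth[sim$truth$class == "tumor_private", ]
  for (pw in names(catalog)) {
    hit_patients <- unique(tr$patient_id[toupper(tr$gene) %in%
                                           catalog[[pw]]])
    expect_equal(unname(sum(m[, pw])), length(hit_patients))
  }
})

test_that("germline/somatic contribution percentages follow the definitions", {
  # pathway of 10 genes; patient with germline hits in 4, tumor-private in 1
  genes <- sprintf("G%02d", 1:10)
  germ <- do.call(rbind, lapply(1:4, function(i)
    qc_record(pos = i * 10L, gene = genes[i])))
  tum <- qc_record(pos = 100L, gene = genes[5])
  tri <- toy_triplet(germ, germ, rbind(germ, tum))
  ot <- list(PT = classify_origin(tri))
  cat1 <- pathway_catalog(list(PW = genes))
  contrib <- germline_somatic_contribution(ot, cat1, definition = "A",
                                           universe = genes)
  expect_equal(contrib$germline_pct, 40)
  expect_equal(contrib$somatic_pct, 10)

  # all-germline cohort: somatic percent 0 everywhere
  tri_g <- toy_triplet(germ, germ, germ)
  c2 <- germline_somatic_contribution(list(PT = classify_origin(tri_g)),
                                      cat1, definition = "A",
                                      universe = genes)
  expect_equal(c2$somatic_pct, 0)

  # definition B counts normal-private and shared-somatic as somatic
  norm_priv <- qc_record(pos = 200L, gene = genes[6])
  shared <- qc_record(pos = 300L, gene = genes[7])
  tri_b <- toy_triplet(germ, rbind(germ, norm_priv, shared),
                       rbind(germ, shared))
  cb <- germline_somatic_contribution(list(PT = classify_origin(tri_b)),
                                      cat1, definition = "B",
                                      universe = genes)
  expect_equal(cb$somatic_pct, 20)   # genes 6 and 7 of 10
  expect_equal(cb$germline_pct, 40)

  # a pathway outside the universe is flagged and excluded
  cat2 <- pathway_catalog(list(PW = genes, OUT = c("NOPE1", "NOPE2")))
  c3 <- germline_somatic_contribution(ot, cat2, definition = "A",
                                      universe = genes)
  expect_false(c3$in_universe[c3$pathway == "OUT"])
  expect_true(is.na(c3$germline_pct[c3$pathway == "OUT"]))
})

test_that("disjoint origin classes keep contribution sums below 100", {
  sim <- small_sim()
  origins <- classify_cohort(sim$cohort, level = "variant")
  catalog <- make_pathway_partition(unique(sim$truth$gene), 10)
  contrib <- germline_somatic_contribution(origins, catalog,
                                           definition = "A")
  ok <- contrib$in_universe
  expect_true(all(contrib$germline_pct[ok] + contrib$somatic_pct[ok] <=
                    100 + 1e-9))
})

test_that("log-OR gene ranking uses exact cells unless a cell is zero", {
  mk <- function(counts, n, genes) {
    m <- matrix(0L, nrow = n, ncol = length(genes),
                dimnames = list(NULL, genes))
    for (j in seq_along(counts)) if (counts[j] > 0) m[1:counts[j], j] <- 1L
    m
  }
  ma <- mk(c(20, 3, 6), 24, c("GA", "GB", "GC"))
  mb <- mk(c(5, 3, 0), 24, c("GA", "GB", "GC"))
  r <- rank_genes_log_or(ma, mb)
  expect_equal(unname(r["GA"]), log((20 * 19) / (4 * 5)))
  expect_equal(unname(r["GB"]), 0)
  # only-in-A gene gets the maximal finite score via +0.5
  expect_equal(unname(r["GC"]), log((6.5 * 24.5) / (0.5 * 18.5)))
  expect_true(all(diff(unname(r)) <= 0))        # sorted descending
})

test_that("enrichment scores match hand-computed running sums", {
  ranked <- setNames(c(5, 4, 3, 2, 1), c("A", "B", "C", "D", "E"))
  # set = top 2, weight 1: hits 5/9 and 4/9, misses 1/3 -> max at rank 2
  r <- gsea_preranked(ranked, c("A", "B"), weight_p = 1, n_perm = 100,
                      seed = 1)
  expect_equal(r$es, 1.0)
  # set at the exact bottom -> negative ES
  r2 <- gsea_preranked(ranked, c("D", "E"), weight_p = 1, n_perm = 100,
                       seed = 1)
  expect_lt(r2$es, 0)
  # set = entire list: no misses, running sum peaks at 1
  r3 <- gsea_preranked(ranked, names(ranked), n_perm = 100, seed = 1)
  expect_equal(r3$es, 1)
  expect_false(r3$testable)
  # empty intersection: explicit not-testable
  r4 <- gsea_preranked(ranked, c("ZZ"), n_perm = 100, seed = 1)
  expect_false(r4$testable)
  expect_true(is.na(r4$es))
})

test_that("ES is scale-invariant and flips sign on list reversal at p=0", {
  set.seed(4)
  scores <- sort(rnorm(30), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:30)
  inset <- names(scores) %in% sample(names(scores), 8)
  es <- tripletmut:::gsea_es
  expect_equal(es(scores, inset, 1), es(scores * 7.3, inset, 1),
               tolerance = 1e-12)
  # reversal at weight 0 mirrors the running sum
  expect_equal(es(rev(scores), rev(inset), 0), -es(scores, inset, 0),
               tolerance = 1e-12)
})

test_that("gsea ES agrees with fgsea's statistic", {
  set.seed(12)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:50)
  for (i in 1:10) {
    set_genes <- sample(names(scores), sample(3:12, 1))
    mine <- tripletmut:::gsea_es(scores, names(scores) %in% set_genes, 1)
    ref <- fgsea::calcGseaStat(scores,
                               which(names(scores) %in% set_genes),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("catalog-level GSEA adds BH q-values over testable sets", {
  set.seed(9)
  scores <- sort(rnorm(60), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:60)
  catalog <- pathway_catalog(list(S1 = names(scores)[1:8],
                                  S2 = sample(names(scores), 10),
                                  S3 = c("NOPE")))
  res <- gsea_catalog(scores, catalog, n_perm = 200, seed = 3)
  expect_equal(nrow(res), 3)
  expect_true(is.na(res$p[res$pathway == "S3"]))
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], bh_adjust(res$p[ok]))
  # the front-loaded set is strongly enriched
  expect_gt(res$es[res$pathway == "S1"], 0.5)
})
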