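cosine_sim_test <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

test_that("trinucleotide contexts are pyrimidine-centred", {
  refseq <- c(sim1 = "AACGTTGAC")
  # positions:           123456789  (ACG at 2-4; TGA at 6-8)
  expect_equal(trinucleotide_context(refseq, "sim1", 3, "C", "T"),
               "A[C>T]G")
  # purine centre: revcomp of TGA is TCA; G>A on the minus strand is C>T
  expect_equal(trinucleotide_context(refseq, "sim1", 7, "G", "A"),
               "T[C>T]A")
  expect_error(trinucleotide_context(refseq, "sim1", 3, "CA", "C"),
               "SNVs only")
  expect_error(trinucleotide_context(refseq, "sim1", 3, "G", "A"),
               "mismatch")
  expect_warning(res <- trinucleotide_context(refseq, "sim1", 1, "A", "G"),
                 "edge")
  expect_true(is.na(res))
})

test_that("SBS matrices count SNVs per channel and exclude non-SNVs", {
  # 10 distinct A[C>T]G contexts in a repeated ACGTT motif
  refseq <- c(sim1 = strrep("ACGTT", 12))
  pos <- 2L + 5L * (0:9)
  v <- do.call(rbind, lapply(pos, function(p)
    qc_record(chrom = "sim1", pos = p, ref = "C", alt = "T")))
  v <- rbind(v, qc_record(chrom = "sim1", pos = 52L, ref = "CG",
                          alt = "C"))                    # indel, excluded
  s <- tissue_sample("p", "tumor", v)
  m <- build_sbs_matrix(list(p_tumor = s), refseq)
  expect_equal(unname(m["A[C>T]G", 1]), 10L)
  expect_equal(sum(m), 10)
  expect_equal(unname(attr(m, "n_excluded")["p_tumor"]), 1L)
  # zero-SNV sample -> all-zero column
  m0 <- build_sbs_matrix(list(x = tissue_sample("p", "blood")), refseq)
  expect_true(all(m0 == 0))
})

test_that("the SBS matrix is invariant to the reference strand", {
  sim <- small_sim()
  s <- sim$cohort[[1]]$tumor
  seqs <- sim$reference$sequences
  m1 <- build_sbs_matrix(list(a = s), seqs)
  # flip the genome to the minus strand and re-express every variant there
  L <- nchar(seqs[[1]])
  flipped <- c(sim1 = tripletmut:::revcomp(seqs[[1]]))
  v <- s$variants
  v$pos <- L - v$pos + 1L
  v$ref <- chartr("ACGT", "TGCA", v$ref)
  v$alt <- chartr("ACGT", "TGCA", v$alt)
  m2 <- build_sbs_matrix(list(a = tissue_sample("p", "tumor", v)), flipped)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("simulated spectra match the generating signature mixture", {
  sim <- small_sim()
  catalog <- sim$config$signature_catalog
  mix <- sim$config$signature_mix
  m <- build_sbs_matrix(sim$cohort, sim$reference)
  # pool the tumor columns: each emitted variant counted exactly once, so
  # the pooled counts are a multinomial draw from the mixture spectrum
  pooled <- rowSums(m[, grepl("_tumor$", colnames(m)), drop = FALSE])
  expected <- as.vector(catalog[, names(mix)] %*% mix)
  obs_cos <- cosine_sim_test(pooled, expected)
  # multinomial oracle: the observed cosine should sit inside the spread of
  # cosines that exact multinomial draws of the same size produce
  set.seed(71)
  band <- replicate(500, cosine_sim_test(
    as.vector(rmultinom(1, sum(pooled), expected)), expected))
  expect_gt(obs_cos, quantile(band, 0.002))
})

test_that("NNLS refitting recovers exposures", {
  catalog <- demo_signature_catalog()
  # single-source sample
  y1 <- round(1000 * catalog[, "SBSsim5"])
  m <- cbind(s1 = y1)
  rownames(m) <- sbs_channels()
  et <- refit_signatures(m, catalog)
  expect_gte(et$fractions["s1", "SBSsim5"], 0.999)
  expect_gte(et$cosine["s1"], 0.999)

  # noiseless 60/40 mixture recovered within 1e-6
  y2 <- 10000 * (0.6 * catalog[, 1] + 0.4 * catalog[, 2])
  m2 <- cbind(mix = y2); rownames(m2) <- sbs_channels()
  et2 <- refit_signatures(m2, catalog)
  expect_equal(unname(et2$fractions["mix", 1:2]), c(0.6, 0.4),
               tolerance = 1e-6)

  # multinomial noise at n = 10,000 within +/- 0.03
  set.seed(31)
  y3 <- as.vector(rmultinom(1, 10000, 0.6 * catalog[, 1] +
                              0.4 * catalog[, 2]))
  m3 <- cbind(noisy = y3); rownames(m3) <- sbs_channels()
  et3 <- refit_signatures(m3, catalog)
  expect_lt(max(abs(unname(et3$fractions["noisy", 1:2]) - c(0.6, 0.4))),
            0.03)

  # all-zero sample: zero exposures, similarity undefined
  m0 <- cbind(z = rep(0L, 96)); rownames(m0) <- sbs_channels()
  et0 <- refit_signatures(m0, catalog)
  expect_true(all(et0$fractions == 0))
  expect_true(is.na(et0$cosine["z"]))
  expect_error(refit_signatures(m0, catalog, "NOT_A_SIG"), "unknown")
})

test_that("refitting a reconstructed spectrum returns the same exposures", {
  catalog <- demo_signature_catalog()
  y <- 5000 * (0.5 * catalog[, 1] + 0.3 * catalog[, 2] + 0.2 * catalog[, 3])
  m <- cbind(s = y); rownames(m) <- sbs_channels()
  e1 <- refit_signatures(m, catalog)
  recon <- 5000 * as.vector(catalog %*% e1$fractions["s", ])
  m2 <- cbind(s = recon); rownames(m2) <- sbs_channels()
  e2 <- refit_signatures(m2, catalog)
  expect_equal(e1$fractions, e2$fractions, tolerance = 1e-9)
})

test_that("de novo NMF factorises exactly at the true rank", {
  catalog <- demo_signature_catalog()
  V1 <- outer(catalog[, 1], c(100, 200, 300))
  dn <- extract_denovo(V1, 1, n_restarts = 3, seed = 2)
  expect_lt(dn$frobenius_error, 1e-8)
  expect_gt(cosine_sim_test(dn$signatures[, 1], catalog[, 1]), 0.9999)

  # two-signature mixture with separable (disjoint) supports, the regime
  # where NMF is identifiable: recovered signatures match after best
  # assignment
  parts <- tripletmut:::parse_channel(sbs_channels())
  sub <- paste0(parts$ref, ">", parts$alt)
  s_a <- as.numeric(sub == "C>A"); s_a <- s_a / sum(s_a)
  s_b <- as.numeric(sub == "T>C") * rep(c(1, 2), 48); s_b <- s_b / sum(s_b)
  truth2 <- cbind(s_a, s_b)
  E <- matrix(c(800, 200, 300, 700, 500, 500, 900, 100), nrow = 2)
  V2 <- truth2 %*% E
  dn2 <- extract_denovo(V2, 2, n_restarts = 8, seed = 5)
  cos_mat <- vapply(1:2, function(j) vapply(1:2, function(k)
    cosine_sim_test(dn2$signatures[, j], truth2[, k]), 0), numeric(2))
  best <- max(min(diag(cos_mat)), min(cos_mat[1, 2], cos_mat[2, 1]))
  expect_gt(best, 0.95)

  # determinism for a fixed seed
  dn3 <- extract_denovo(V2, 2, n_restarts = 8, seed = 5)
  expect_identical(dn2$signatures, dn3$signatures)
  expect_error(extract_denovo(V2, 10), "k must lie")
})

test_that("per-group contributions count and round consistently", {
  catalog <- demo_signature_catalog()
  m <- cbind(a = round(100 * catalog[, 1]),
             b = round(as.vector(200 * (0.5 * catalog[, 1] +
                                          0.5 * catalog[, 2]))))
  rownames(m) <- sbs_channels()
  et <- refit_signatures(m, catalog)
  contrib <- signature_percent_contribution(et, c("g1", "g2"))
  # single signature at full exposure: ~100%
  g1 <- contrib[contrib$group == "g1", ]
  expect_gt(g1$percent[g1$signature == "SBSsim1"], 99)
  # counts per group sum to the group's SNV totals
  expect_equal(sum(contrib$count[contrib$group == "g1"]), sum(m[, "a"]))
  expect_equal(sum(contrib$count[contrib$group == "g2"]), sum(m[, "b"]))
  # largest-remainder rounding: exact totals for awkward fractions
  expect_equal(sum(largest_remainder(c(1, 1, 1) / 3, 100)), 100L)
  expect_equal(largest_remainder(c(0.5, 0.5), 5), c(3L, 2L))
})

test_that("wilcoxon signed-rank handles exact, tied and degenerate input", {
  x <- c(1, 2, 3, 4, 5, 6)
  nt <- wilcoxon_signed_rank(x, x)
  expect_false(nt$testable)
  # all-positive differences, n = 6: exact two-sided p = 2/64
  w <- wilcoxon_signed_rank(x + c(1, 2, 3, 4, 5, 6) * 0.1, x)
  expect_true(w$exact)
  expect_equal(w$p, 2 / 64)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0)), "at least 5")
  # agreement with a direct wilcox.test call on untied data
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})

test_that("the exact signed-rank test is calibrated under a symmetric null", {
  set.seed(44)
  reps <- 1000
  rejections <- sum(vapply(seq_len(reps), function(i) {
    x <- rnorm(20); y <- rnorm(20)
    wilcoxon_signed_rank(x, y)$p <= 0.05
  }, TRUE))
  # discrete exact test is conservative at 0.05; allow the binomial band
  expect_gte(rejections, qbinom(0.005, reps, 0.03))
  expect_lte(rejections, qbinom(0.995, reps, 0.06))
})
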