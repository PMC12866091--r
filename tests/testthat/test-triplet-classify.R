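test_that("presence bits map to the seven origin classes", {
  b <- qc_record(pos = 1L)                       # in all three
  n <- qc_record(pos = 2L)                       # normal+tumor
  t3 <- qc_record(pos = 3L)                      # tumor only
  n4 <- qc_record(pos = 4L)                      # normal only
  b5 <- qc_record(pos = 5L)                      # blood only
  bn <- qc_record(pos = 6L)                      # blood+normal
  bt <- qc_record(pos = 7L)                      # blood+tumor
  tri <- toy_triplet(blood = rbind(b, b5, bn, bt),
                     normal = rbind(b, n, n4, bn),
                     tumor = rbind(b, n, t3, bt))
  ot <- classify_origin(tri, level = "variant")
  cls <- setNames(ot$class, sub("^.*:(\\d+):.*$", "\\1", ot$item))
  expect_equal(unname(cls[c("1", "2", "3", "4", "5", "6", "7")]),
               c("germline_all", "shared_somatic", "tumor_private",
                 "normal_private", "blood_private", "blood_normal",
                 "blood_tumor"))
  # partition: every item in exactly one class
  expect_equal(sum(venn_counts(ot)), nrow(ot))
  expect_false(anyNA(ot$class))
  # VAFs carried per tissue where present
  expect_equal(ot$vaf_tumor[ot$class == "tumor_private"], 0.5)
  expect_true(is.na(ot$vaf_blood[ot$class == "tumor_private"]))
})

test_that("venn counts match the configured cohort structure", {
  sim <- noiseless_sim()          # high VAFs: no detection censoring
  cfg <- sim$config
  origins <- classify_cohort(sim$cohort, level = "variant")
  for (p in names(origins)) {
    vc <- venn_counts(origins[[p]])
    expect_equal(unname(vc["germline_all"]), cfg$n_germline_per_patient)
    expect_equal(unname(vc["shared_somatic"]), cfg$n_shared_somatic)
    expect_equal(unname(vc["tumor_private"]), cfg$n_tumor_private)
    expect_equal(unname(vc["normal_private"]), cfg$n_normal_private)
    expect_equal(unname(vc["blood_private"] + vc["blood_normal"] +
                          vc["blood_tumor"]), 0L)
  }
  # empty triplet: all regions zero
  tri0 <- toy_triplet(qc_record()[0, ], qc_record()[0, ], qc_record()[0, ])
  expect_equal(sum(venn_counts(classify_origin(tri0))), 0L)
})

test_that("classification agrees with the generating truth", {
  sim <- noiseless_sim()
  origins <- classify_cohort(sim$cohort, level = "variant")
  for (p in names(origins)) {
    ot <- origins[[p]]
    tr <- sim$truth[sim$truth$patient_id == p, ]
    key <- paste0("sim1:", tr$pos, ":", tr$ref, ">", tr$alt)
    m <- match(key, ot$item)
    expect_false(anyNA(m))
    expect_equal(ot$class[m], tr$class)
  }
})

test_that("with censoring, classes follow the emitted presence bits exactly", {
  sim <- small_sim()              # realistic VAFs: dropout occurs
  origins <- classify_cohort(sim$cohort, level = "variant")
  tr <- sim$truth
  key <- paste0(tr$patient_id, "|sim1:", tr$pos, ":", tr$ref, ">", tr$alt)
  observed <- unlist(lapply(names(origins), function(p)
    setNames(origins[[p]]$class, paste0(p, "|", origins[[p]]$item))))
  derived <- tripletmut:::origin_class(tr$emitted_blood, tr$emitted_normal,
                                       tr$emitted_tumor)
  seen <- !is.na(derived)
  expect_equal(unname(observed[key[seen]]), derived[seen])
  # fully censored variants never appear
  expect_false(any(key[!seen] %in% names(observed)))
  # dropout only moves variants to subset classes; germline can never be
  # observed as shared_somatic (blood het VAF is far above the limit)
  expect_false(any(tr$class == "germline_all" & seen &
                     derived == "shared_somatic"))
})

test_that("jaccard index behaves as a set overlap measure", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard(c("a"), c("b")), 0.0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)
  # symmetry over random sets
  set.seed(1)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
  }
})

test_that("VAF summaries use type-7 order statistics", {
  mk <- function(vafs) {
    v <- do.call(rbind, lapply(seq_along(vafs), function(i)
      qc_record(pos = i * 10L, dp = 1000L, ad_alt = as.integer(1000 * vafs[i]))))
    toy_triplet(qc_record()[0, ], v, v)   # shared somatic in normal+tumor
  }
  s1 <- vaf_summary(classify_origin(mk(0.2)), "shared_somatic", "normal")
  expect_equal(c(s1$min, s1$median, s1$max, s1$iqr), c(0.2, 0.2, 0.2, 0))
  s2 <- vaf_summary(classify_origin(mk(c(0.1, 0.2, 0.3, 0.4))),
                    "shared_somatic", "normal")
  expect_equal(s2$median, 0.25)
  expect_equal(s2$iqr, 0.15)
  # empty selection: explicit empty summary
  s0 <- vaf_summary(classify_origin(mk(0.2)), "tumor_private", "tumor")
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median))
})

test_that("the generating somatic VAF distribution hits its target median", {
  set.seed(99)
  ab <- beta_params_from_median_iqr(0.216, 0.117)
  draws <- rbeta(20000, ab[1], ab[2])
  se <- 1.2533 * sd(draws) / sqrt(length(draws))   # se of a sample median
  expect_lt(abs(median(draws) - 0.216), 4 * se)
})

test_that("tumor-to-normal VAF ratios divide the observed VAFs", {
  mk_shared <- function(vn, vt, pos) {
    list(normal = qc_record(pos = pos, dp = 100L,
                            ad_alt = as.integer(100 * vn)),
         tumor = qc_record(pos = pos, dp = 100L,
                           ad_alt = as.integer(100 * vt)))
  }
  a <- mk_shared(0.69, 0.83, 10L)   # SUSD2-like pair
  b <- mk_shared(0.47, 0.72, 20L)   # SVIL-like pair
  c0 <- mk_shared(0.30, 0.30, 30L)
  tri <- toy_triplet(qc_record()[0, ],
                     rbind(a$normal, b$normal, c0$normal),
                     rbind(a$tumor, b$tumor, c0$tumor))
  r <- shared_somatic_vaf_ratio(classify_origin(tri))
  expect_equal(sort(r$ratios), sort(c(0.83 / 0.69, 0.72 / 0.47, 1.0)),
               tolerance = 1e-12)
  expect_equal(r$ratios[order(r$ratios)][2], 1.2029, tolerance = 1e-4)
  expect_equal(max(r$ratios), 1.5319, tolerance = 1e-4)
})

test_that("minimal detectable VAF is the read rule over coverage", {
  expect_identical(min_detectable_vaf(10, 100), 0.10)
  expect_identical(min_detectable_vaf(10, 200), 0.05)
  expect_identical(min_detectable_vaf(0, 100), 0)
  expect_error(min_detectable_vaf(10, 0), "coverage")
  # homogeneity: scaling both leaves the limit unchanged
  for (s in c(2, 5, 10))
    expect_equal(min_detectable_vaf(10 * s, 100 * s),
                 min_detectable_vaf(10, 100))
})

test_that("binomial presence revalidation matches the exact tail", {
  r0 <- revalidate_presence(0, 100)
  expect_equal(r0$call, "absent")
  expect_equal(r0$p_value, 1)
  expect_equal(revalidate_presence(50, 50)$call, "present")
  expect_lt(revalidate_presence(50, 50)$p_value, 1e-15)
  # exact enumeration oracle for the tail probability
  oracle <- sum(vapply(5:100, function(k)
    choose(100, k) * 0.01^k * 0.99^(100 - k), 0))
  expect_equal(revalidate_presence(5, 100, 0.01)$p_value, oracle,
               tolerance = 1e-12)
  nc <- revalidate_presence(0, 0)
  expect_equal(nc$call, "no-call")
  expect_true(is.na(nc$p_value))
  expect_error(revalidate_presence(5, 100, error_rate = 0.7), "error_rate")
})
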