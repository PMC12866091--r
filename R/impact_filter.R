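#' Hard-filter and impact-filter policy
#'
#' Thresholds follow the GATK-style hard filters used for the triplet
#' analysis, exactly as printed: an SNV fails on `DP < 4`, `QD < 2`,
#' `FS > 60`, `MQ < 35`, `MQRankSum < -12.5` or `ReadPosRankSum < -8`;
#' an indel on `DP < 4`, `QD < 2`, `FS > 200`, `MQ < 35` or
#' `ReadPosRankSum < -20`; genotypes with `GQ < 20` are removed. Boundary
#' values pass (strict inequalities). Records missing a QC field skip that
#' rule rather than fail.
#'
#' @param gq_min genotype-quality cutoff (fail when `GQ < gq_min`).
#' @param include_splicing count splicing variants as exonic non-silent.
#' @param clinvar_qualifying ClinVar classes that qualify as high impact.
#' @return `filter_policy` list.
#' @export
filter_policy <- function(gq_min = 20, include_splicing = TRUE,
                          clinvar_qualifying = c("pathogenic",
                                                 "likely_pathogenic")) {
  nonsilent <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                 "frameshift_insertion", "frameshift_deletion",
                 "nonframeshift_insertion", "nonframeshift_deletion")
  if (include_splicing) nonsilent <- c(nonsilent, "splicing")
  structure(list(
    snv = list(dp_min = 4, qd_min = 2, fs_max = 60, mq_min = 35,
               mqrs_min = -12.5, rprs_min = -8),
    indel = list(dp_min = 4, qd_min = 2, fs_max = 200, mq_min = 35,
                 rprs_min = -20),
    gq_min = gq_min,
    nonsilent_classes = nonsilent,
    clinvar_qualifying = clinvar_qualifying),
    class = "filter_policy")
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv", "indel")
}

#' Apply quality hard filters to variant records
#'
#' Evaluates the per-kind threshold rules in a fixed order and reports the
#' first violated rule; a record passes when no rule is violated. Missing QC
#' fields skip their rule.
#'
#' @param records data.frame of variant records (columns `dp, qd, fs, mq,
#'   mq_rank_sum, read_pos_rank_sum, gq`).
#' @param kind `"snv"`, `"indel"`, or `NULL` to infer per record from the
#'   allele lengths.
#' @param policy a [filter_policy()].
#' @return character vector: `"pass"` or `"fail(<rule>)"` per record.
#' @export
apply_hard_filters <- function(records, kind = NULL,
                               policy = filter_policy()) {
  n <- nrow(records)
  if (is.null(kind)) kind <- variant_kind(records$ref, records$alt)
  else kind <- rep(match.arg(kind, c("snv", "indel")), n)
  viol <- function(x, op, thr) !is.na(x) & op(x, thr)
  out <- character(n)
  for (k in c("snv", "indel")) {
    i <- which(kind == k)
    if (!length(i)) next
    th <- policy[[k]]
    rules <- list(
      `DP<4` = viol(records$dp[i], `<`, th$dp_min),
      `QD<2` = viol(records$qd[i], `<`, th$qd_min),
      `FS>60` = viol(records$fs[i], `>`, th$fs_max),
      `MQ<35` = viol(records$mq[i], `<`, th$mq_min))
    if (k == "snv")
      rules$`MQRankSum<-12.5` <- viol(records$mq_rank_sum[i], `<`,
                                      th$mqrs_min)
    rules$`ReadPosRankSum<threshold` <- viol(records$read_pos_rank_sum[i],
                                             `<`, th$rprs_min)
    rules$`GQ<20` <- viol(records$gq[i], `<`, policy$gq_min)
    names(rules)[3] <- if (k == "snv") "FS>60" else "FS>200"
    names(rules)[names(rules) == "ReadPosRankSum<threshold"] <-
      if (k == "snv") "ReadPosRankSum<-8" else "ReadPosRankSum<-20"
    names(rules)[names(rules) == "GQ<20"] <-
      paste0("GQ<", format(policy$gq_min))
    res <- rep("pass", length(i))
    hit <- rep(FALSE, length(i))
    for (r in names(rules)) {
      new <- rules[[r]] & !hit
      res[new] <- paste0("fail(", r, ")")
      hit <- hit | rules[[r]]
    }
    out[i] <- res
  }
  out
}

#' Is a record exonic and non-silent?
#'
#' `TRUE` for the protein-altering functional categories (nonsynonymous,
#' stopgain/stoploss, frameshift and non-frameshift indels and, by default,
#' splicing). Synonymous, intronic, UTR and unknown categories are `FALSE`;
#' unknown categories additionally raise a warning.
#'
#' @param records data.frame with an `exonic_func` column.
#' @param policy a [filter_policy()].
#' @return logical vector.
#' @export
is_exonic_nonsilent <- function(records, policy = filter_policy()) {
  func <- gsub(" ", "_", records$exonic_func)
  known <- c(policy$nonsilent_classes, "splicing", "synonymous_SNV",
             "intronic", "UTR3", "UTR5", "intergenic", "ncRNA", "upstream",
             "downstream", "missing", "unknown")
  if (any(!func %in% known))
    warning("unknown exonic function categories treated as silent: ",
            paste(unique(func[!func %in% known]), collapse = ", "))
  func %in% policy$nonsilent_classes
}

#' Is a record of high functional impact?
#'
#' The disjunctive high-impact rule: predicted deleterious by MetaSVM
#' (`D`) OR classified pathogenic / likely pathogenic by ClinVar. Missing
#' annotations never qualify.
#'
#' @param records data.frame with `metasvm` and `clinvar` columns.
#' @param policy a [filter_policy()].
#' @return logical vector.
#' @export
is_high_impact <- function(records, policy = filter_policy()) {
  metasvm <- records$metasvm
  clin <- records$clinvar
  (!is.na(metasvm) & metasvm == "D") |
    (!is.na(clin) & clin %in% policy$clinvar_qualifying)
}

#' Filter a tissue sample to analysis-ready variants
#'
#' Conjunction of the three stages: quality hard filters, the
#' exonic-non-silent requirement, and the high-functional-impact rule.
#' Each dropped record is attributed to exactly one rule (the first stage,
#' and within the hard filters the first rule, that rejects it), so the
#' report counts are additive: input = output + sum of drops.
#'
#' @param sample a [tissue_sample()].
#' @param policy a [filter_policy()].
#' @return list with `sample` (the filtered [tissue_sample()]) and `report`
#'   (data.frame `rule, n_dropped` plus `n_input`/`n_passed` attributes).
#' @export
filter_sample <- function(sample, policy = filter_policy()) {
  stopifnot(inherits(sample, "tissue_sample"))
  v <- sample$variants
  n <- nrow(v)
  if (n == 0) {
    report <- data.frame(rule = character(0), n_dropped = integer(0))
    attr(report, "n_input") <- 0L; attr(report, "n_passed") <- 0L
    return(list(sample = sample, report = report))
  }
  hard <- apply_hard_filters(v, kind = NULL, policy = policy)
  nonsilent <- is_exonic_nonsilent(v, policy)
  impact <- is_high_impact(v, policy)

  reason <- rep(NA_character_, n)
  reason[hard != "pass"] <- sub("^fail\\((.*)\\)$", "\\1",
                                hard[hard != "pass"])
  drop_ns <- is.na(reason) & !nonsilent
  reason[drop_ns] <- "not_exonic_nonsilent"
  drop_hi <- is.na(reason) & !impact
  reason[drop_hi] <- "not_high_impact"
  keep <- is.na(reason)

  tab <- table(factor(reason[!keep]))
  report <- data.frame(rule = names(tab), n_dropped = as.integer(tab),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n
  attr(report, "n_passed") <- sum(keep)
  list(sample = tissue_sample(sample$patient_id, sample$tissue,
                              v[keep, , drop = FALSE]),
       report = report)
}

#' Filter every sample of a cohort
#'
#' @param cohort a [triplet_cohort()].
#' @param policy a [filter_policy()].
#' @return a filtered [triplet_cohort()] (reports attached as attribute
#'   `reports`, a named list by `patient/tissue`).
#' @export
filter_cohort <- function(cohort, policy = filter_policy()) {
  stopifnot(inherits(cohort, "triplet_cohort"))
  reports <- list()
  out <- lapply(cohort, function(tri) {
    smp <- lapply(c("blood", "normal", "tumor"), function(t) {
      fr <- filter_sample(tri[[t]], policy)
      reports[[paste0(tri$patient_id, "/", t)]] <<- fr$report
      fr$sample
    })
    patient_triplet(tri$patient_id, smp[[1]], smp[[2]], smp[[3]],
                    age = tri$age, cohort = tri$cohort)
  })
  res <- triplet_cohort(out, label = attr(cohort, "label"))
  attr(res, "reports") <- reports
  res
}
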