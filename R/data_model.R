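# Internal data model: a variant collection is a plain data.frame with the
# columns below; tissue samples and patient triplets are light S3 wrappers.

variant_columns <- c("chrom", "pos", "ref", "alt", "gene", "exonic_func",
                     "metasvm", "clinvar", "cadd", "dp", "ad_alt", "gq",
                     "qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum",
                     "vaf")

empty_variants <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   gene = character(0), exonic_func = character(0),
                   metasvm = character(0), clinvar = character(0),
                   cadd = numeric(0), dp = integer(0), ad_alt = integer(0),
                   gq = numeric(0), qd = numeric(0), fs = numeric(0),
                   mq = numeric(0), mq_rank_sum = numeric(0),
                   read_pos_rank_sum = numeric(0), vaf = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Construct a tissue sample
#'
#' @param patient_id patient identifier.
#' @param tissue one of `"blood"`, `"normal"`, `"tumor"`.
#' @param variants data.frame of variant records (one row per bi-allelic
#'   call) with at least `chrom, pos, ref, alt`; missing annotation columns
#'   are filled with `"missing"`/`NA`.
#' @return object of class `tissue_sample`.
#' @export
tissue_sample <- function(patient_id, tissue, variants = empty_variants()) {
  tissue <- match.arg(tissue, c("blood", "normal", "tumor"))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in variant_columns) {
    if (!col %in% names(variants)) {
      variants[[col]] <- if (col %in% c("gene", "exonic_func", "metasvm",
                                        "clinvar"))
        rep("missing", nrow(variants)) else rep(NA_real_, nrow(variants))
    }
  }
  variants <- variants[variant_columns]
  rownames(variants) <- NULL
  if (nrow(variants)) {
    if (any(variants$ref == variants$alt))
      stop("ref and alt alleles must differ")
    if (any(variants$pos < 1)) stop("positions must be >= 1")
    keys <- variant_key(variants)$key
    if (anyDuplicated(keys))
      stop("duplicate variant keys within sample ", patient_id, "/", tissue)
    dp_ok <- is.na(variants$dp) | is.na(variants$ad_alt) |
      (variants$ad_alt >= 0 & variants$ad_alt <= variants$dp)
    if (!all(dp_ok)) stop("ad_alt must lie in [0, dp]")
    variants$vaf <- ifelse(!is.na(variants$dp) & variants$dp > 0,
                           variants$ad_alt / variants$dp, NA_real_)
  }
  structure(list(patient_id = patient_id, tissue = tissue,
                 variants = variants),
            class = "tissue_sample")
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat("<tissue_sample>", x$patient_id, x$tissue, "-", nrow(x$variants),
      "variants\n")
  invisible(x)
}

#' Construct a patient triplet
#'
#' A complete set of matched blood, cancer-adjacent normal and tumor samples
#' for one patient. Incomplete triplets are rejected: the origin analysis is
#' only defined when all three tissues are present.
#'
#' @param patient_id identifier shared by the three samples.
#' @param blood,normal,tumor `tissue_sample` objects.
#' @param age patient age in years (optional, used for burden/age analyses).
#' @param cohort cohort label.
#' @return object of class `patient_triplet`.
#' @export
patient_triplet <- function(patient_id, blood, normal, tumor,
                            age = NA_real_, cohort = NA_character_) {
  for (s in list(blood, normal, tumor))
    if (!inherits(s, "tissue_sample"))
      stop("blood, normal and tumor must be tissue_sample objects; ",
           "incomplete triplets are not allowed")
  ids <- c(blood$patient_id, normal$patient_id, tumor$patient_id)
  if (!all(ids == patient_id))
    stop("all three tissues must share patient_id ", patient_id)
  if (blood$tissue != "blood" || normal$tissue != "normal" ||
      tumor$tissue != "tumor")
    stop("tissue labels do not match their slots")
  structure(list(patient_id = patient_id, age = age, cohort = cohort,
                 blood = blood, normal = normal, tumor = tumor),
            class = "patient_triplet")
}

#' @export
print.patient_triplet <- function(x, ...) {
  cat("<patient_triplet>", x$patient_id,
      sprintf("(age %s): B=%d A=%d T=%d variants\n",
              format(x$age), nrow(x$blood$variants),
              nrow(x$normal$variants), nrow(x$tumor$variants)))
  invisible(x)
}

#' Construct a triplet cohort
#'
#' @param triplets list of `patient_triplet` objects with unique patient ids.
#' @param label cohort label.
#' @return object of class `triplet_cohort` (a named list of triplets).
#' @export
triplet_cohort <- function(triplets, label = "cohort") {
  stopifnot(all(vapply(triplets, inherits, TRUE, "patient_triplet")))
  ids <- vapply(triplets, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort")
  names(triplets) <- ids
  structure(triplets, class = "triplet_cohort", label = label)
}

#' @export
print.triplet_cohort <- function(x, ...) {
  cat("<triplet_cohort>", attr(x, "label"), "-", length(x), "patients\n")
  invisible(x)
}
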