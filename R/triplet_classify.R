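#' Classify a patient's variants by tissue presence
#'
#' Partitions items into the seven presence classes over blood (B),
#' adjacent-normal (A) and tumor (T): `germline_all` (B+A+T),
#' `blood_normal` (B+A), `blood_tumor` (B+T), `shared_somatic` (A+T),
#' `tumor_private` (T), `normal_private` (A) and `blood_private` (B).
#' Somatic mutations are the classes absent from blood (`shared_somatic`,
#' `tumor_private`, `normal_private`); germline variants are those shared by
#' all three tissues. Matching is by canonical variant key at the variant
#' level and by gene symbol at the gene level.
#'
#' @param triplet a complete [patient_triplet()].
#' @param level `"variant"` (allele-exact, default) or `"gene"`.
#' @return `origin_table` data.frame: `item` (key or gene), `gene`,
#'   presence bits `in_blood/in_normal/in_tumor`, `class`, and (variant
#'   level) per-tissue observed VAFs.
#' @export
classify_origin <- function(triplet, level = c("variant", "gene")) {
  stopifnot(inherits(triplet, "patient_triplet"))
  level <- match.arg(level)
  per_tissue <- lapply(c(blood = "blood", normal = "normal",
                         tumor = "tumor"), function(t) {
    v <- triplet[[t]]$variants
    if (level == "variant") {
      k <- if (nrow(v)) variant_key(v)$key else character(0)
      data.frame(item = k, gene = v$gene, vaf = v$vaf,
                 stringsAsFactors = FALSE)
    } else {
      g <- unique(v$gene[v$gene != "missing"])
      data.frame(item = g, gene = g, vaf = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  items <- unique(unlist(lapply(per_tissue, `[[`, "item")))
  inb <- items %in% per_tissue$blood$item
  ina <- items %in% per_tissue$normal$item
  int <- items %in% per_tissue$tumor$item
  cls <- origin_class(inb, ina, int)
  gene <- per_tissue$blood$gene[match(items, per_tissue$blood$item)]
  gene[is.na(gene)] <- per_tissue$normal$gene[
    match(items[is.na(gene)], per_tissue$normal$item)]
  gene[is.na(gene)] <- per_tissue$tumor$gene[
    match(items[is.na(gene)], per_tissue$tumor$item)]
  out <- data.frame(item = items, gene = gene, in_blood = inb,
                    in_normal = ina, in_tumor = int, class = cls,
                    stringsAsFactors = FALSE)
  if (level == "variant") {
    out$vaf_blood <- per_tissue$blood$vaf[match(items, per_tissue$blood$item)]
    out$vaf_normal <- per_tissue$normal$vaf[match(items,
                                                  per_tissue$normal$item)]
    out$vaf_tumor <- per_tissue$tumor$vaf[match(items,
                                                per_tissue$tumor$item)]
  }
  structure(out, class = c("origin_table", "data.frame"),
            patient_id = triplet$patient_id, level = level)
}

# presence bits -> class; pure function, mutually exclusive and exhaustive
origin_class <- function(in_blood, in_normal, in_tumor) {
  cls <- rep(NA_character_, length(in_blood))
  cls[in_blood & in_normal & in_tumor] <- "germline_all"
  cls[in_blood & in_normal & !in_tumor] <- "blood_normal"
  cls[in_blood & !in_normal & in_tumor] <- "blood_tumor"
  cls[!in_blood & in_normal & in_tumor] <- "shared_somatic"
  cls[!in_blood & !in_normal & in_tumor] <- "tumor_private"
  cls[!in_blood & in_normal & !in_tumor] <- "normal_private"
  cls[in_blood & !in_normal & !in_tumor] <- "blood_private"
  cls
}

SOMATIC_CLASSES <- c("shared_somatic", "tumor_private", "normal_private")

#' Classify every patient of a cohort
#'
#' @param cohort a [triplet_cohort()] (usually post-filter).
#' @param level passed to [classify_origin()].
#' @return named list of `origin_table`s, one per patient.
#' @export
classify_cohort <- function(cohort, level = "variant") {
  stopifnot(inherits(cohort, "triplet_cohort"))
  lapply(cohort, classify_origin, level = level)
}

#' Venn region counts of an origin table
#'
#' @param origin_table a [classify_origin()] result.
#' @return named integer vector over the seven presence regions; sums to
#'   the number of distinct items.
#' @export
venn_counts <- function(origin_table) {
  tab <- table(factor(origin_table$class, levels = ORIGIN_CLASSES))
  setNames(as.integer(tab), ORIGIN_CLASSES)
}

#' Jaccard index of two sets
#'
#' `|A n B| / |A u B|`; by convention 0 when both sets are empty.
#'
#' @param set_a,set_b vectors treated as sets.
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' VAF summary for one origin class in one tissue
#'
#' Order-statistic summary (type-7 quantiles: linear interpolation) of the
#' observed VAFs of a class, e.g. somatic variants in the adjacent-normal
#' tissue.
#'
#' @param origin_table a variant-level [classify_origin()] result, or a
#'   list of them (patients pooled).
#' @param class origin class(es) to select (default: the somatic classes
#'   present in the tissue).
#' @param tissue `"blood"`, `"normal"` or `"tumor"`.
#' @return list of class `vaf_summary`: `n, min, max, median, iqr`.
#' @export
vaf_summary <- function(origin_table, class = SOMATIC_CLASSES,
                        tissue = "normal") {
  tissue <- match.arg(tissue, c("blood", "normal", "tumor"))
  if (inherits(origin_table, "origin_table")) origin_table <-
      list(origin_table)
  vafs <- unlist(lapply(origin_table, function(ot) {
    stopifnot(identical(attr(ot, "level"), "variant"))
    ot[[paste0("vaf_", tissue)]][ot$class %in% class]
  }))
  vafs <- vafs[!is.na(vafs)]
  if (!length(vafs))
    return(structure(list(n = 0L, min = NA_real_, max = NA_real_,
                          median = NA_real_, iqr = NA_real_),
                     class = "vaf_summary"))
  q <- quantile(vafs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(n = length(vafs), min = min(vafs), max = max(vafs),
                 median = q[2], iqr = q[3] - q[1]),
            class = "vaf_summary")
}

#' @export
print.vaf_summary <- function(x, ...) {
  cat(sprintf("<vaf_summary> n=%d min=%.3f median=%.3f max=%.3f IQR=%.3f\n",
              x$n, x$min, x$median, x$max, x$iqr))
  invisible(x)
}

#' Tumor-to-normal VAF ratios of shared somatic variants
#'
#' For every shared-somatic variant with defined VAFs in both tissues,
#' the ratio tumor VAF / normal VAF; a ratio near 1 indicates comparable
#' allelic representation in both tissues (early clonal seeding).
#'
#' @param origin_table a variant-level origin table or list of them.
#' @return list: `ratios` (per-variant), `mean`, `range`, and
#'   `n_excluded_zero_normal`.
#' @export
shared_somatic_vaf_ratio <- function(origin_table) {
  if (inherits(origin_table, "origin_table")) origin_table <-
      list(origin_table)
  tum <- unlist(lapply(origin_table, function(ot)
    ot$vaf_tumor[ot$class == "shared_somatic"]))
  nor <- unlist(lapply(origin_table, function(ot)
    ot$vaf_normal[ot$class == "shared_somatic"]))
  ok <- !is.na(tum) & !is.na(nor)
  tum <- tum[ok]; nor <- nor[ok]
  zero <- nor == 0
  ratios <- tum[!zero] / nor[!zero]
  list(ratios = ratios,
       mean = if (length(ratios)) mean(ratios) else NA_real_,
       range = if (length(ratios)) range(ratios) else c(NA_real_, NA_real_),
       n_excluded_zero_normal = sum(zero))
}

#' Minimal detectable VAF under a read-support rule
#'
#' With a requirement of at least `min_reads` supporting reads at a mean
#' coverage, the smallest detectable allele fraction is roughly
#' `min_reads / coverage`: 0.10 at 100x and 0.05 at 200x for a 10-read
#' rule.
#'
#' @param min_reads minimum supporting reads (>= 0).
#' @param coverage mean depth (> 0).
#' @return fraction.
#' @export
min_detectable_vaf <- function(min_reads, coverage) {
  if (any(coverage <= 0)) stop("coverage must be > 0")
  if (any(min_reads < 0)) stop("min_reads must be >= 0")
  min_reads / coverage
}

#' Binomial presence re-validation
#'
#' A coverage-aware second look at a locus: tests whether the observed
#' alt-read count exceeds what a sequencing-error process would produce,
#' via a one-sided exact binomial tail `P[X >= alt | depth, error_rate]`.
#' Zero-depth loci are "no-call", never "absent".
#'
#' @param alt_count,depth observed alt reads and total depth (vectorised).
#' @param error_rate per-read error probability in (0, 0.5).
#' @param alpha presence threshold on the p-value.
#' @return data.frame: `call` (`"present"`, `"absent"`, `"no-call"`) and
#'   `p_value`.
#' @export
revalidate_presence <- function(alt_count, depth, error_rate = 0.01,
                                alpha = 0.05) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie strictly between 0 and 0.5")
  if (any(alt_count < 0 | alt_count > depth))
    stop("alt_count must lie in [0, depth]")
  p <- pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
  call <- ifelse(depth == 0, "no-call",
                 ifelse(p < alpha, "present", "absent"))
  p[depth == 0] <- NA_real_
  data.frame(call = call, p_value = p, stringsAsFactors = FALSE)
}
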