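#' Demonstration SBS signature catalog (synthetic)
#'
#' Three synthetic, well-separated SBS-96 signatures used as the default
#' generating processes for simulated cohorts and as test fixtures. They are
#' loosely shaped after the clock-like / flat / artifact-like trio commonly
#' reported in breast tissue (a CpG C>T-concentrated signature, a nearly flat
#' signature with a T>C tilt, and a C>A-heavy signature), but the numeric
#' values are constructed here and are NOT the COSMIC reference signatures.
#'
#' @return numeric 96 x 3 matrix, columns `SBSsim1`, `SBSsim5`, `SBSsim54`;
#'   each column sums to 1; rownames are [sbs_channels()].
#' @export
demo_signature_catalog <- function() {
  ch <- sbs_channels()
  parts <- parse_channel(ch)
  sub <- paste0(parts$ref, ">", parts$alt)

  # CpG-deamination-like: mass on N[C>T]G
  s1 <- rep(0.1 / 92, 96)
  cpg <- sub == "C>T" & parts$three == "G"
  s1[cpg] <- 0.9 / sum(cpg)

  # flat-like with a T>C tilt
  s5 <- ifelse(sub == "T>C", 2, 1)
  s5 <- s5 / sum(s5)

  # artifact-like: C>A heavy, some T>A
  s54 <- ifelse(sub == "C>A", 4, ifelse(sub == "T>A", 2, 0.25))
  s54 <- s54 / sum(s54)

  m <- cbind(SBSsim1 = s1, SBSsim5 = s5, SBSsim54 = s54)
  rownames(m) <- ch
  m
}

#' Simulation configuration for a synthetic triplet cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults describe the study conditions the pipeline is designed for: 24
#' patients, ~100x coverage in blood and adjacent normal, ~200x in tumor, a
#' 10-read detection limit, a dominant shared-germline fraction, and somatic
#' VAFs drawn from a Beta distribution re-parameterised to the observed
#' normal-tissue median 0.216 and IQR 0.117.
#'
#' @param n_patients number of triplet patients.
#' @param n_genes,gene_length_bp gene model size: count and mean length.
#' @param n_germline_per_patient,n_shared_somatic,n_tumor_private,n_normal_private
#'   per-patient true variant counts by origin class (before detection
#'   censoring).
#' @param coverage_blood,coverage_normal,coverage_tumor mean sequencing
#'   depths (x).
#' @param depth_distribution `"poisson"` (default; depth ~ Poisson(mean)) or
#'   `"fixed"` (every site at exactly the mean depth; useful for
#'   detection-limit diagnostics).
#' @param min_supporting_reads detection limit: a variant is emitted in a
#'   tissue only if it gathers at least this many alt reads there.
#' @param germline_vaf_levels,germline_vaf_weights true germline VAF levels
#'   (default heterozygous 0.5 / homozygous 1.0 at 85/15).
#' @param somatic_vaf somatic true-VAF distribution: either
#'   `list(dist = "beta", median =, iqr =)` or `list(dist = "fixed", value =)`.
#' @param signature_catalog 96 x K column-stochastic matrix of generating
#'   signatures (default [demo_signature_catalog()]).
#' @param signature_mix named nonnegative fractions over catalog columns,
#'   summing to 1 (default 0.19/0.59/0.22).
#' @param impact_pass_fraction fraction of variants annotated so that they
#'   pass the exonic-nonsilent + high-impact filter.
#' @param age_range patient ages are drawn uniformly from this range (years).
#' @param seed global RNG seed; per-patient streams are fanned out from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 24,
                       n_genes = 500,
                       gene_length_bp = 1500,
                       n_germline_per_patient = 150,
                       n_shared_somatic = 15,
                       n_tumor_private = 25,
                       n_normal_private = 10,
                       coverage_blood = 100,
                       coverage_normal = 100,
                       coverage_tumor = 200,
                       depth_distribution = c("poisson", "fixed"),
                       min_supporting_reads = 10,
                       germline_vaf_levels = c(0.5, 1.0),
                       germline_vaf_weights = c(0.85, 0.15),
                       somatic_vaf = list(dist = "beta", median = 0.216,
                                          iqr = 0.117),
                       signature_catalog = demo_signature_catalog(),
                       signature_mix = c(SBSsim1 = 0.19, SBSsim5 = 0.59,
                                         SBSsim54 = 0.22),
                       impact_pass_fraction = 0.5,
                       age_range = c(23, 49),
                       seed = 1L) {
  depth_distribution <- match.arg(depth_distribution)
  cfg <- list(n_patients = n_patients, n_genes = n_genes,
              gene_length_bp = gene_length_bp,
              n_germline_per_patient = n_germline_per_patient,
              n_shared_somatic = n_shared_somatic,
              n_tumor_private = n_tumor_private,
              n_normal_private = n_normal_private,
              coverage_blood = coverage_blood,
              coverage_normal = coverage_normal,
              coverage_tumor = coverage_tumor,
              depth_distribution = depth_distribution,
              min_supporting_reads = min_supporting_reads,
              germline_vaf_levels = germline_vaf_levels,
              germline_vaf_weights = germline_vaf_weights,
              somatic_vaf = somatic_vaf,
              signature_catalog = signature_catalog,
              signature_mix = signature_mix,
              impact_pass_fraction = impact_pass_fraction,
              age_range = age_range, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- character(0)
  pos_counts <- c("n_patients", "n_genes", "gene_length_bp",
                  "n_germline_per_patient")
  for (f in pos_counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      bad <- c(bad, paste0(f, " must be a positive count"))
  for (f in c("n_shared_somatic", "n_tumor_private", "n_normal_private",
              "min_supporting_reads"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      bad <- c(bad, paste0(f, " must be a nonnegative count"))
  for (f in c("coverage_blood", "coverage_normal", "coverage_tumor"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      bad <- c(bad, paste0(f, " must be > 0"))
  if (length(cfg$germline_vaf_levels) != length(cfg$germline_vaf_weights) ||
      any(cfg$germline_vaf_levels < 0 | cfg$germline_vaf_levels > 1) ||
      any(cfg$germline_vaf_weights < 0) ||
      abs(sum(cfg$germline_vaf_weights) - 1) > 1e-9)
    bad <- c(bad, "germline VAF levels/weights must pair up, lie in [0,1], and weights sum to 1")
  sv <- cfg$somatic_vaf
  if (!is.list(sv) || is.null(sv$dist) ||
      !(identical(sv$dist, "beta") || identical(sv$dist, "fixed")))
    bad <- c(bad, "somatic_vaf$dist must be 'beta' or 'fixed'")
  else if (sv$dist == "fixed" &&
           (is.null(sv$value) || sv$value < 0 || sv$value > 1))
    bad <- c(bad, "somatic_vaf$value must lie in [0,1]")
  else if (sv$dist == "beta" &&
           (is.null(sv$median) || is.null(sv$iqr) ||
            sv$median <= 0 || sv$median >= 1 || sv$iqr <= 0))
    bad <- c(bad, "somatic_vaf beta spec needs median in (0,1) and iqr > 0")
  cat_ok <- is.matrix(cfg$signature_catalog) &&
    nrow(cfg$signature_catalog) == 96 &&
    all(cfg$signature_catalog >= 0) &&
    all(abs(colSums(cfg$signature_catalog) - 1) < 1e-6)
  if (!cat_ok)
    bad <- c(bad, "signature_catalog must be a 96-row column-stochastic matrix")
  mix <- cfg$signature_mix
  if (is.null(names(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-9 ||
      (cat_ok && !all(names(mix) %in% colnames(cfg$signature_catalog))))
    bad <- c(bad, "signature_mix must be named, nonnegative, sum to 1, and match catalog columns")
  if (cfg$impact_pass_fraction < 0 || cfg$impact_pass_fraction > 1)
    bad <- c(bad, "impact_pass_fraction must lie in [0,1]")
  if (length(bad))
    stop("invalid sim_config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

#' Beta shape parameters matching a target median and IQR
#'
#' Numerically inverts the Beta quantile function so that
#' `qbeta(0.5, a, b)` hits the target median and
#' `qbeta(0.75) - qbeta(0.25)` the target IQR. Used to re-parameterise the
#' somatic-VAF distribution by the two summary statistics reported for
#' normal-tissue somatic variants (median 0.216, IQR 0.117).
#'
#' @param median,iqr targets; `0 < median < 1`, `iqr > 0`.
#' @return named numeric vector `c(shape1, shape2)`.
#' @export
beta_params_from_median_iqr <- function(median = 0.216, iqr = 0.117) {
  stopifnot(median > 0, median < 1, iqr > 0)
  obj <- function(logab) {
    a <- exp(logab[1]); b <- exp(logab[2])
    (qbeta(0.5, a, b) - median)^2 +
      (qbeta(0.75, a, b) - qbeta(0.25, a, b) - iqr)^2
  }
  fit <- optim(c(log(2), log(6)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  out <- exp(fit$par)
  names(out) <- c("shape1", "shape2")
  out
}

draw_somatic_vaf <- function(n, spec) {
  if (spec$dist == "fixed") return(rep(spec$value, n))
  ab <- spec$shapes %||% beta_params_from_median_iqr(spec$median, spec$iqr)
  rbeta(n, ab[1], ab[2])
}
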