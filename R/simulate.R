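#' Simulate a reference sequence and gene model
#'
#' Draws a random DNA sequence with a given GC fraction and lays
#' non-overlapping gene intervals across it. A single contig (`sim1`) is
#' used; genes occupy the central part of equal-width slots so that every
#' gene has flanking intergenic sequence.
#'
#' @param length_bp total contig length; must be at least `100 * n_genes`.
#' @param gc_fraction target GC content in (0, 1).
#' @param n_genes number of gene intervals.
#' @param seed RNG seed; the result is deterministic for a fixed seed.
#' @return object of class `sim_reference`: `sequences` (named character,
#'   one contig) and `genes` (data.frame `gene, chrom, start, end`, 1-based
#'   inclusive coordinates).
#' @export
simulate_reference <- function(length_bp, gc_fraction, n_genes, seed = 1L) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie strictly between 0 and 1")
  if (length_bp < n_genes * 100)
    stop("length_bp (", length_bp, ") too small for ", n_genes,
         " genes; need at least ", n_genes * 100, " bp")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- paste(sample(names(p), length_bp, replace = TRUE, prob = p),
               collapse = "")
  slot <- floor(length_bp / n_genes)
  gap <- max(10L, floor(slot * 0.1))
  start <- (seq_len(n_genes) - 1L) * slot + gap + 1L
  end <- seq_len(n_genes) * slot - gap
  genes <- data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                      chrom = "sim1", start = as.integer(start),
                      end = as.integer(end), stringsAsFactors = FALSE)
  structure(list(sequences = c(sim1 = seq), genes = genes,
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference>", nchar(x$sequences[[1]]), "bp,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Sample read support for a variant
#'
#' Emulates exome read sampling at a mean depth: total depth is drawn from a
#' Poisson with the given mean (or held fixed), and the alt-supporting count
#' is Binomial(depth, true VAF).
#'
#' @param true_vaf true variant allele fraction(s) in `[0, 1]`; vectorised.
#' @param mean_depth mean sequencing depth (> 0).
#' @param depth_distribution `"poisson"` or `"fixed"`.
#' @param seed optional seed for a self-contained draw.
#' @return data.frame with columns `ad_alt` and `dp`.
#' @export
sample_read_support <- function(true_vaf, mean_depth,
                                depth_distribution = c("poisson", "fixed"),
                                seed = NULL) {
  depth_distribution <- match.arg(depth_distribution)
  if (any(true_vaf < 0 | true_vaf > 1))
    stop("true_vaf must lie in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_vaf)
  dp <- if (depth_distribution == "poisson") rpois(n, mean_depth)
        else rep(as.integer(round(mean_depth)), n)
  ad <- rbinom(n, dp, true_vaf)
  data.frame(ad_alt = as.integer(ad), dp = as.integer(dp))
}

# Index genic positions of a sim_reference by their pyrimidine-normalised
# trinucleotide context ("ACA" = 5'A, centre C, 3'A on the pyrimidine strand).
context_pools <- function(reference) {
  seq <- reference$sequences[[1]]
  chars <- strsplit(seq, "")[[1]]
  genes <- reference$genes
  pos <- unlist(mapply(seq.int, pmax(genes$start, 2L),
                       pmin(genes$end, length(chars) - 1L),
                       SIMPLIFY = FALSE))
  tri <- paste0(chars[pos - 1L], chars[pos], chars[pos + 1L])
  pur <- chars[pos] %in% c("A", "G")
  tri[pur] <- revcomp(tri[pur])
  list(pools = split(pos, tri), chars = chars)
}

gene_at <- function(genes, pos) {
  i <- findInterval(pos, genes$start)
  ok <- i >= 1 & pos <= genes$end[pmax(i, 1L)]
  out <- rep(NA_character_, length(pos))
  out[ok] <- genes$gene[i[ok]]
  out
}

ORIGIN_CLASSES <- c("germline_all", "blood_normal", "blood_tumor",
                    "shared_somatic", "tumor_private", "normal_private",
                    "blood_private")

# which tissues carry each generated origin class
class_tissues <- list(germline_all = c("blood", "normal", "tumor"),
                      shared_somatic = c("normal", "tumor"),
                      tumor_private = "tumor",
                      normal_private = "normal")

NONSILENT_CLASSES <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                       "frameshift_insertion", "frameshift_deletion",
                       "nonframeshift_insertion", "nonframeshift_deletion",
                       "splicing")

#' Simulate a triplet cohort with known ground truth
#'
#' Generates per-patient germline, shared-somatic, tumor-private and
#' normal-private variants over a simulated reference, draws per-tissue read
#' support at the configured coverages, censors variants below the
#' minimum-supporting-reads detection limit, and annotates each variant so a
#' configured fraction passes the high-impact filter. Substitution types are
#' drawn from the configured signature mixture, placed at genomic positions
#' whose trinucleotide context matches the drawn SBS-96 channel (on either
#' strand).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort` with elements `cohort`
#'   (a [triplet_cohort()] of emitted, i.e. detected, variants), `truth`
#'   (data.frame: one row per generated variant with origin class, true
#'   per-tissue VAFs, generating signature and channel, and per-tissue
#'   emitted AD/DP), `reference`, and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  ref <- simulate_reference(length_bp = config$n_genes *
                              as.integer(ceiling(config$gene_length_bp * 1.25)),
                            gc_fraction = 0.41, n_genes = config$n_genes,
                            seed = fanout_seed(config$seed, 0L))
  ctx <- context_pools(ref)
  catalog <- config$signature_catalog
  rownames(catalog) <- rownames(catalog) %||% sbs_channels()
  mix <- config$signature_mix
  sv <- config$somatic_vaf
  if (sv$dist == "beta" && is.null(sv$shapes))
    sv$shapes <- beta_params_from_median_iqr(sv$median, sv$iqr)
  channel_parts <- parse_channel(sbs_channels())
  channel_key <- paste0(channel_parts$five, channel_parts$ref,
                        channel_parts$three)

  counts <- c(germline_all = config$n_germline_per_patient,
              shared_somatic = config$n_shared_somatic,
              tumor_private = config$n_tumor_private,
              normal_private = config$n_normal_private)
  coverages <- c(blood = config$coverage_blood,
                 normal = config$coverage_normal,
                 tumor = config$coverage_tumor)
  triplets <- vector("list", config$n_patients)
  truth_rows <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    set.seed(fanout_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    m <- sum(counts)
    cls <- rep(names(counts), counts)

    # substitution type from the signature mixture
    sig <- sample(names(mix), m, replace = TRUE, prob = mix)
    chan_idx <- integer(m)
    for (s in unique(sig)) {
      sel <- sig == s
      chan_idx[sel] <- sample.int(96, sum(sel), replace = TRUE,
                                  prob = catalog[, s])
    }
    channel <- sbs_channels()[chan_idx]

    # place each variant at a context-matching genic position (no reuse
    # of a position within a patient)
    pos <- integer(m)
    for (key in unique(channel_key[chan_idx])) {
      sel <- channel_key[chan_idx] == key
      pool <- ctx$pools[[key]]
      if (is.null(pool) || length(pool) < sum(sel))
        stop("reference too small: context ", key, " has ",
             length(pool %||% integer(0)), " genic positions but ",
             sum(sel), " are needed; increase n_genes or gene_length_bp")
      pos[sel] <- sample(pool, sum(sel))
    }
    ref_allele <- ctx$chars[pos]
    pyr <- ref_allele %in% c("C", "T")
    alt_allele <- ifelse(pyr, channel_parts$alt[chan_idx],
                         chartr("ACGT", "TGCA", channel_parts$alt[chan_idx]))
    gene <- gene_at(ref$genes, pos)

    # true VAFs: germline het/hom levels, somatic from the Beta spec
    is_germ <- cls == "germline_all"
    vaf <- numeric(m)
    vaf[is_germ] <- sample(config$germline_vaf_levels, sum(is_germ),
                           replace = TRUE, prob = config$germline_vaf_weights)
    vaf[!is_germ] <- draw_somatic_vaf(sum(!is_germ), sv)

    # annotations (constant across tissues of a patient)
    ann <- simulate_annotations(m, config$impact_pass_fraction)

    # per-tissue read support + detection censoring
    tiss <- list()
    truth <- data.frame(patient_id = pid, chrom = "sim1", pos = pos,
                        ref = ref_allele, alt = alt_allele, gene = gene,
                        class = cls, signature = sig, channel = channel,
                        stringsAsFactors = FALSE)
    for (t in c("blood", "normal", "tumor")) {
      present <- vapply(cls, function(cl) t %in% class_tissues[[cl]], TRUE)
      rs <- sample_read_support(vaf[present], coverages[[t]],
                                config$depth_distribution)
      emitted <- rs$ad_alt >= config$min_supporting_reads
      truth[[paste0("vaf_", t)]] <- ifelse(present, vaf, NA_real_)
      ad <- dp <- rep(NA_integer_, m)
      ad[present] <- ifelse(emitted, rs$ad_alt, NA_integer_)
      dp[present] <- ifelse(emitted, rs$dp, NA_integer_)
      truth[[paste0("ad_", t)]] <- ad
      truth[[paste0("dp_", t)]] <- dp
      emit_full <- rep(FALSE, m)
      emit_full[present] <- emitted
      truth[[paste0("emitted_", t)]] <- emit_full
      keep <- which(emit_full)
      v <- data.frame(chrom = "sim1", pos = pos[keep],
                      ref = ref_allele[keep], alt = alt_allele[keep],
                      gene = gene[keep],
                      exonic_func = ann$exonic_func[keep],
                      metasvm = ann$metasvm[keep],
                      clinvar = ann$clinvar[keep], cadd = ann$cadd[keep],
                      dp = dp[keep], ad_alt = ad[keep], gq = 99,
                      qd = 25, fs = 1, mq = 60, mq_rank_sum = 0,
                      read_pos_rank_sum = 0, stringsAsFactors = FALSE)
      v <- v[order(v$pos), , drop = FALSE]
      tiss[[t]] <- tissue_sample(pid, t, v)
    }
    age <- sample(seq(config$age_range[1], config$age_range[2]), 1)
    triplets[[i]] <- patient_triplet(pid, tiss$blood, tiss$normal,
                                     tiss$tumor, age = age,
                                     cohort = "synthetic")
    truth_rows[[i]] <- truth
  }
  structure(list(cohort = triplet_cohort(triplets, label = "synthetic"),
                 truth = do.call(rbind, truth_rows),
                 reference = ref, config = config),
            class = "sim_cohort")
}

# Annotation fields such that a `pass_fraction` of variants survive the
# exonic-nonsilent + high-impact filter; the remainder fail via a silent
# functional class or via benign/tolerated predictions.
simulate_annotations <- function(m, pass_fraction) {
  passes <- runif(m) < pass_fraction
  exonic_func <- character(m)
  metasvm <- character(m)
  clinvar <- character(m)
  cadd <- numeric(m)

  n_pass <- sum(passes)
  exonic_func[passes] <- sample(c("nonsynonymous_SNV", "stopgain",
                                  "splicing"), n_pass, replace = TRUE,
                                prob = c(0.8, 0.15, 0.05))
  via_metasvm <- runif(n_pass) < 0.7
  metasvm[passes] <- ifelse(via_metasvm, "D", "T")
  clinvar[passes] <- ifelse(via_metasvm,
                            sample(c("benign", "VUS", "missing"), n_pass,
                                   replace = TRUE),
                            sample(c("pathogenic", "likely_pathogenic"),
                                   n_pass, replace = TRUE))
  cadd[passes] <- round(runif(n_pass, 20, 40), 1)

  n_fail <- m - n_pass
  silent <- runif(n_fail) < 0.5
  exonic_func[!passes] <- ifelse(silent,
                                 sample(c("synonymous_SNV", "intronic"),
                                        n_fail, replace = TRUE),
                                 "nonsynonymous_SNV")
  metasvm[!passes] <- "T"
  clinvar[!passes] <- sample(c("benign", "VUS", "missing"), n_fail,
                             replace = TRUE)
  cadd[!passes] <- round(runif(n_fail, 0, 20), 1)
  list(exonic_func = exonic_func, metasvm = metasvm, clinvar = clinvar,
       cadd = cadd)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF 4.2 file per patient-tissue, the reference FASTA with a
#' `.fai` index, the gene model as BED (0-based half-open), the ground-truth
#' table and patient metadata as TSV, and the configuration as JSON (the
#' signature catalog goes to its own TSV).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_indexed(sim$reference$sequences, file.path(dir, "reference.fa"))
  genes <- sim$reference$genes
  write.table(data.frame(genes$chrom, genes$start - 1L, genes$end,
                         genes$gene),
              file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  contig_len <- nchar(sim$reference$sequences)
  for (tri in sim$cohort) {
    for (t in c("blood", "normal", "tumor")) {
      write_tissue_vcf(tri[[t]],
                       file.path(dir, paste0(tri$patient_id, "_", t, ".vcf")),
                       contig_lengths = contig_len)
    }
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(patient_id = names(sim$cohort),
                     age = vapply(sim$cohort, `[[`, 0, "age"),
                     cohort = vapply(sim$cohort, `[[`, "", "cohort"))
  write.table(meta, file.path(dir, "patients.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  catalog <- sim$config$signature_catalog
  write_signature_catalog(catalog, file.path(dir, "signature_catalog.tsv"))
  cfg <- sim$config
  cfg$signature_catalog <- "signature_catalog.tsv"
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# FASTA (80-column) plus a samtools-style .fai index computed from the
# layout we just wrote.
write_fasta_indexed <- function(sequences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  offsets <- numeric(length(sequences))
  offset <- 0
  for (i in seq_along(sequences)) {
    header <- paste0(">", names(sequences)[i], "\n")
    writeChar(header, con, eos = NULL)
    offset <- offset + nchar(header)
    offsets[i] <- offset
    s <- sequences[[i]]
    n <- nchar(s)
    starts <- seq(1, n, by = 80)
    lines <- paste0(substring(s, starts, pmin(starts + 79, n)), "\n")
    writeChar(paste(lines, collapse = ""), con, eos = NULL)
    offset <- offset + sum(nchar(lines))
  }
  fai <- data.frame(names(sequences), nchar(sequences), format(offsets,
                    scientific = FALSE, trim = TRUE), 80L, 81L)
  write.table(fai, paste0(path, ".fai"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
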