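#' Partition genes into a synthetic pathway catalog
#'
#' Deterministic stand-in for a curated pathway collection when none is
#' supplied: sorts the gene universe and deals it round-robin into `n_sets`
#' named sets.
#'
#' @param genes character vector of gene symbols.
#' @param n_sets number of sets (default 21, the size of a curated
#'   hallmark-pathway collection).
#' @return a [pathway_catalog()].
#' @export
make_pathway_partition <- function(genes, n_sets = 21) {
  genes <- sort(unique(toupper(genes)))
  n_sets <- min(n_sets, length(genes))
  idx <- rep_len(seq_len(n_sets), length(genes))
  sets <- split(genes, idx)
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
  pathway_catalog(sets, label = "synthetic-partition")
}

#' Run the triplet analysis pipeline end to end
#'
#' Orchestrates simulate/load -> filter -> classify -> gene stats ->
#' pathways -> signatures, writing every stage's tables as TSV plus a JSON
#' summary and a per-stage log. A run is fully determined by
#' (config, seed): rerunning with the same configuration yields
#' byte-identical outputs.
#'
#' @param config a list, or path to a JSON/YAML file, with elements:
#'   `seed`; either `simulate` (a list of [sim_config()] overrides) or
#'   `vcf_dir` (+ `reference` FASTA for the signature stage); optional
#'   `gene_sets` (GMT path; default: a synthetic 21-way partition of the
#'   observed genes); optional `signature_catalog` (TSV path; default
#'   [demo_signature_catalog()]); `stages` (default all of `"filter"`,
#'   `"classify"`, `"genestats"`, `"pathways"`, `"signatures"`);
#'   `gsea` (`weight_p`, `n_perm`).
#' @param outdir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("filter", "classify", "genestats",
                                 "pathways", "signatures")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  tsv <- function(df, name) write.table(df, file.path(outdir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  jsonlite::write_json(config, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # ---- stage: input (simulate or load) ----
  reference <- NULL; gene_model <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    cohort <- sim$cohort
    reference <- sim$reference
    gene_model <- sim$reference$genes
    truth <- sim$truth
    write_cohort(sim, file.path(outdir, "cohort"))
    note("input: simulated cohort with ", length(cohort), " patients, ",
         nrow(truth), " true variants")
  } else if (!is.null(config$vcf_dir)) {
    cohort <- read_cohort_dir(config$vcf_dir)
    if (!is.null(config$reference)) reference <- config$reference
    if (!is.null(config$genes_bed)) {
      bed <- read.delim(config$genes_bed, header = FALSE,
                        stringsAsFactors = FALSE)
      gene_model <- data.frame(gene = bed[[4]], chrom = bed[[1]],
                               start = bed[[2]] + 1L, end = bed[[3]])
    }
    note("input: loaded ", length(cohort), " patients from ",
         config$vcf_dir)
  } else stop("config must provide either 'simulate' or 'vcf_dir'")
  n_per_tissue <- function(co, t)
    vapply(co, function(tri) nrow(tri[[t]]$variants), 0L)
  summary_counts <- lapply(c(blood = "blood", normal = "normal",
                             tumor = "tumor"), function(t) {
    n <- n_per_tissue(cohort, t)
    list(mean = mean(n), min = min(n), max = max(n))
  })

  results <- list(cohort = cohort, truth = truth)

  # ---- stage: filter ----
  if ("filter" %in% stages) {
    policy <- filter_policy()
    filtered <- filter_cohort(cohort, policy)
    reports <- attr(filtered, "reports")
    rep_df <- do.call(rbind, lapply(names(reports), function(nm) {
      r <- reports[[nm]]
      if (!nrow(r)) return(NULL)
      data.frame(sample = nm, rule = r$rule, n_dropped = r$n_dropped)
    }))
    tsv(rep_df %||% data.frame(sample = character(0), rule = character(0),
                               n_dropped = integer(0)),
        "filter_report.tsv")
    summary_counts_hfi <- lapply(c(blood = "blood", normal = "normal",
                                   tumor = "tumor"), function(t) {
      n <- n_per_tissue(filtered, t)
      list(mean = mean(n), min = min(n), max = max(n))
    })
    note("filter: mean high-impact variants per tissue: ",
         paste(sprintf("%s=%.1f", names(summary_counts_hfi),
                       vapply(summary_counts_hfi, `[[`, 0, "mean")),
               collapse = " "))
    results$filtered <- filtered
    analysis_cohort <- filtered
  } else {
    summary_counts_hfi <- NULL
    analysis_cohort <- cohort
  }

  # ---- stage: classify ----
  if ("classify" %in% stages) {
    origins <- classify_cohort(analysis_cohort, level = "variant")
    origins_gene <- classify_cohort(analysis_cohort, level = "gene")
    otab <- do.call(rbind, lapply(names(origins), function(p)
      cbind(patient_id = p, as.data.frame(origins[[p]]))))
    tsv(otab, "origin_variants.tsv")
    venn <- lapply(origins_gene, function(ot) as.list(venn_counts(ot)))
    jsonlite::write_json(venn, file.path(outdir, "venn_gene_counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jac <- do.call(rbind, lapply(names(origins_gene), function(p) {
      ot <- origins_gene[[p]]
      g <- function(bit) ot$item[ot[[bit]]]
      data.frame(patient_id = p,
                 jaccard_blood_normal = jaccard(g("in_blood"),
                                                g("in_normal")),
                 jaccard_blood_tumor = jaccard(g("in_blood"),
                                               g("in_tumor")),
                 jaccard_normal_tumor = jaccard(g("in_normal"),
                                                g("in_tumor")))
    }))
    tsv(jac, "jaccard_gene.tsv")
    vs <- vaf_summary(origins, class = SOMATIC_CLASSES, tissue = "normal")
    ratio <- shared_somatic_vaf_ratio(origins)
    tsv(data.frame(n = vs$n, min = vs$min, median = vs$median,
                   max = vs$max, iqr = vs$iqr), "vaf_summary_normal.tsv")
    tsv(data.frame(mean_ratio = ratio$mean, min_ratio = ratio$range[1],
                   max_ratio = ratio$range[2],
                   n = length(ratio$ratios),
                   n_excluded_zero_normal = ratio$n_excluded_zero_normal),
        "vaf_ratio_shared_somatic.tsv")
    note("classify: pooled somatic VAF (normal) median ",
         format(vs$median, digits = 3), " over ", vs$n, " variants")
    results$origins <- origins
  }

  # ---- stage: gene stats ----
  if ("genestats" %in% stages && !is.null(results$origins)) {
    origins <- results$origins
    all_classes <- ORIGIN_CLASSES
    mats <- lapply(c(blood = "blood", normal = "normal", tumor = "tumor"),
                   function(t) build_gene_matrix(origins, t,
                                                 classes = all_classes))
    soma_mats <- lapply(c(normal = "normal", tumor = "tumor"),
                        function(t) build_gene_matrix(origins, t))
    for (t in names(mats))
      tsv(data.frame(patient_id = rownames(mats[[t]]), mats[[t]],
                     check.names = FALSE),
          paste0("gene_matrix_", t, ".tsv"))
    pairs <- list(c("blood", "normal"), c("blood", "tumor"),
                  c("normal", "tumor"))
    for (pr in pairs) {
      dm <- fisher_gene_test(mats[[pr[1]]], mats[[pr[2]]])
      tsv(dm, paste0("diffmut_", pr[1], "_vs_", pr[2], ".tsv"))
      note("genestats: ", pr[1], " vs ", pr[2], ": ",
           sum(dm$q < 0.05, na.rm = TRUE),
           " genes at BH q < 0.05 of ", nrow(dm))
    }
    for (t in names(soma_mats)) {
      if (ncol(soma_mats[[t]]) > 0)
        tsv(top_frequent_genes(soma_mats[[t]], 10),
            paste0("top_somatic_genes_", t, ".tsv"))
    }
    if (!is.null(gene_model)) {
      glen <- sum(gene_model$end - gene_model$start + 1)
      burden <- vapply(names(origins), function(p)
        mutation_burden(sum(origins[[p]]$class %in% SOMATIC_CLASSES &
                              origins[[p]]$in_tumor), glen), 0)
      ages <- vapply(analysis_cohort, `[[`, 0, "age")[names(origins)]
      if (sum(!is.na(ages)) >= 3 && stats::sd(burden) > 0 &&
          stats::sd(ages, na.rm = TRUE) > 0) {
        ba <- burden_age_correlation(burden, ages)
        tsv(data.frame(r = ba$r, p = ba$p, n = ba$n), "burden_age.tsv")
        note("genestats: burden/age Pearson r = ",
             format(ba$r, digits = 3))
      }
    }
    results$gene_matrices <- mats
  }

  # ---- stage: pathways ----
  if ("pathways" %in% stages && !is.null(results$origins)) {
    origins <- results$origins
    catalog <- if (!is.null(config$gene_sets))
      read_gene_sets(config$gene_sets)
    else make_pathway_partition(unlist(lapply(origins, function(ot)
      ot$gene[ot$gene != "missing"])))
    pam <- pathway_alteration_matrix(origins, catalog)
    tsv(data.frame(patient_id = rownames(pam), pam, check.names = FALSE),
        "pathway_alteration.tsv")
    for (def in c("A", "B")) {
      contrib <- germline_somatic_contribution(origins, catalog,
                                               definition = def)
      tsv(contrib, paste0("contribution_", def, ".tsv"))
    }
    gs <- config$gsea %||% list()
    weight_p <- gs$weight_p %||% 1
    n_perm <- gs$n_perm %||% 500
    mats <- results$gene_matrices %||%
      lapply(c(blood = "blood", normal = "normal", tumor = "tumor"),
             function(t) build_gene_matrix(origins, t,
                                           classes = ORIGIN_CLASSES))
    pairs <- list(c("blood", "normal"), c("blood", "tumor"),
                  c("normal", "tumor"))
    for (pr in pairs) {
      ranked <- rank_genes_log_or(mats[[pr[1]]], mats[[pr[2]]])
      res <- gsea_catalog(ranked, catalog, weight_p = weight_p,
                          n_perm = n_perm, seed = seed)
      tsv(res, paste0("gsea_", pr[1], "_vs_", pr[2], ".tsv"))
      note("pathways: GSEA ", pr[1], " vs ", pr[2], ": ",
           sum(res$q < 0.05, na.rm = TRUE), " sets at FDR q < 0.05")
    }
    results$pathway_catalog <- catalog
  }

  # ---- stage: signatures ----
  if ("signatures" %in% stages) {
    if (is.null(reference)) {
      note("signatures: skipped (no reference sequence provided)")
    } else {
      sig_catalog <- if (!is.null(config$signature_catalog))
        read_signature_catalog(config$signature_catalog)
      else demo_signature_catalog()
      sbs <- build_sbs_matrix(cohort, reference)
      tsv(data.frame(Type = rownames(sbs), sbs, check.names = FALSE),
          "sbs_matrix.tsv")
      exp_tab <- refit_signatures(sbs, sig_catalog)
      tsv(data.frame(sample = rownames(exp_tab$fractions),
                     exp_tab$fractions, total = exp_tab$totals,
                     cosine = exp_tab$cosine, check.names = FALSE),
          "exposures.tsv")
      tissue_of <- sub("^.*_", "", colnames(sbs))
      contrib <- signature_percent_contribution(exp_tab, tissue_of)
      tsv(contrib, "signature_contribution.tsv")
      note("signatures: mean reconstruction cosine ",
           format(mean(exp_tab$cosine, na.rm = TRUE), digits = 4))
      results$exposures <- exp_tab
    }
  }

  summary <- list(n_patients = length(cohort),
                  variants_per_tissue = summary_counts,
                  high_impact_per_tissue = summary_counts_hfi,
                  stages_run = stages, seed = seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "log.txt"))
  invisible(results)
}
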