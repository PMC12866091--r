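#' Binary patient-by-pathway alteration matrix
#'
#' Cell (patient, pathway) is 1 iff at least one member gene of the pathway
#' carries at least one variant of the selected origin classes in that
#' patient.
#'
#' @param origins named list of variant-level origin tables.
#' @param catalog a [pathway_catalog()].
#' @param classes origin classes that qualify (default: somatic).
#' @param tissues presence in any of these tissues qualifies (default: the
#'   tissues implied by the classes — all three).
#' @return binary integer matrix, patients x pathways.
#' @export
pathway_alteration_matrix <- function(origins, catalog,
                                      classes = SOMATIC_CLASSES,
                                      tissues = c("blood", "normal",
                                                  "tumor")) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  hit_genes <- lapply(origins, function(ot) {
    inside <- Reduce(`|`, lapply(paste0("in_", tissues),
                                 function(b) ot[[b]]))
    unique(toupper(ot$gene[ot$class %in% classes & inside &
                             !is.na(ot$gene) & ot$gene != "missing"]))
  })
  m <- matrix(0L, nrow = length(origins), ncol = length(catalog),
              dimnames = list(names(origins), names(catalog)))
  for (i in seq_along(hit_genes))
    m[i, ] <- as.integer(vapply(catalog, function(g)
      any(g %in% hit_genes[[i]]), TRUE))
  m
}

# origin-class groupings behind the two published germline/somatic
# attribution definitions
contribution_classes <- function(definition) {
  switch(definition,
         A = list(germline = "germline_all", somatic = "tumor_private"),
         B = list(germline = c("germline_all", "blood_normal"),
                  somatic = c("normal_private", "shared_somatic")),
         stop("definition must be 'A' or 'B'"))
}

#' Germline versus somatic pathway contribution
#'
#' For each pathway, the per-patient percentage of member genes altered by
#' germline variants and by somatic mutations, averaged across patients.
#' Two definitions are supported: under `A`, somatic = tumor-only variants
#' and germline = variants shared by all three tissues; under `B`, somatic
#' = normal-only plus normal+tumor-shared variants and germline = shared by
#' all tissues plus blood+normal-shared. Pathways with no member gene in
#' the cohort's annotation universe are flagged and excluded from averages.
#'
#' @param origins named list of variant-level origin tables.
#' @param catalog a [pathway_catalog()].
#' @param definition `"A"` or `"B"`.
#' @param universe optional gene universe; defaults to all genes seen in
#'   the origin tables.
#' @return data.frame per pathway: `pathway, size, germline_pct,
#'   somatic_pct, in_universe`.
#' @export
germline_somatic_contribution <- function(origins, catalog,
                                          definition = c("A", "B"),
                                          universe = NULL) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  definition <- match.arg(definition)
  grp <- contribution_classes(definition)
  if (is.null(universe))
    universe <- unique(toupper(unlist(lapply(origins, function(ot)
      ot$gene[!is.na(ot$gene) & ot$gene != "missing"]))))
  per_origin_genes <- function(ot, classes)
    unique(toupper(ot$gene[ot$class %in% classes & !is.na(ot$gene) &
                             ot$gene != "missing"]))
  germ <- lapply(origins, per_origin_genes, classes = grp$germline)
  soma <- lapply(origins, per_origin_genes, classes = grp$somatic)
  res <- lapply(names(catalog), function(pw) {
    members <- catalog[[pw]]
    present <- any(members %in% universe)
    if (!present)
      return(data.frame(pathway = pw, size = length(members),
                        germline_pct = NA_real_, somatic_pct = NA_real_,
                        in_universe = FALSE, stringsAsFactors = FALSE))
    gp <- vapply(germ, function(g) 100 * sum(members %in% g) /
                   length(members), 0)
    sp <- vapply(soma, function(g) 100 * sum(members %in% g) /
                   length(members), 0)
    data.frame(pathway = pw, size = length(members),
               germline_pct = mean(gp), somatic_pct = mean(sp),
               in_universe = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "definition") <- definition
  out
}

#' Rank genes by log odds ratio between two tissues
#'
#' Per gene, the log OR of the 2x2 mutated / non-mutated patient table of
#' tissue A over reference tissue B, with the +0.5 correction applied only
#' when a cell is zero. Genes are returned sorted by score descending with
#' alphabetical tie order — the preranked input for GSEA.
#'
#' @param matrix_a,matrix_b binary patient x gene matrices.
#' @return named numeric vector of scores, sorted descending.
#' @export
rank_genes_log_or <- function(matrix_a, matrix_b) {
  genes <- sort(union(colnames(matrix_a), colnames(matrix_b)))
  a <- b <- setNames(integer(length(genes)), genes)
  a[colnames(matrix_a)] <- colSums(matrix_a)
  b[colnames(matrix_b)] <- colSums(matrix_b)
  score <- log_odds_ratio(a, nrow(matrix_a) - a, b, nrow(matrix_b) - b)
  names(score) <- genes
  score[order(-score, genes)]
}

# Weighted Kolmogorov-Smirnov-style running-sum enrichment score.
# scores must be sorted descending; inset is logical over the same order.
gsea_es <- function(scores, inset, weight_p = 1) {
  n <- length(scores)
  n_set <- sum(inset)
  if (n_set == 0 || n_set == n) {
    # degenerate: no misses (or no hits) - running sum peaks at 1 (or 0)
    if (n_set == n) return(1)
    return(NA_real_)
  }
  w <- abs(scores)^weight_p
  hit <- ifelse(inset, w, 0)
  sh <- sum(hit)
  if (sh == 0) hit[inset] <- 1 / n_set else hit <- hit / sh
  miss <- ifelse(inset, 0, 1 / (n - n_set))
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

#' Preranked gene set enrichment of a single set
#'
#' Classic weighted running-sum GSEA on a preranked list: hit increments
#' proportional to `|score|^weight_p` (normalised over in-set genes), miss
#' decrements `1/(N - n_set)`; ES is the maximum deviation of the running
#' sum. Significance by gene-label permutation: NES is ES divided by the
#' mean of same-sign permutation ESs, and the p-value is the same-sign
#' permutation tail fraction with +1 smoothing.
#'
#' @param ranked_list named numeric vector (scores, sorted descending — it
#'   is re-sorted defensively).
#' @param gene_set character vector of gene symbols.
#' @param weight_p score weighting exponent (default 1, classic GSEA).
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return list `es, nes, p, n_set_used`; `not-testable` error if the set
#'   does not intersect the list.
#' @export
gsea_preranked <- function(ranked_list, gene_set, weight_p = 1,
                           n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  ord <- order(-ranked_list, names(ranked_list))
  scores <- ranked_list[ord]
  inset <- toupper(names(scores)) %in% toupper(gene_set)
  n_set <- sum(inset)
  if (n_set == 0)
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                n_set_used = 0L, testable = FALSE))
  es <- gsea_es(scores, inset, weight_p)
  if (n_set == length(scores))
    return(list(es = es, nes = NA_real_, p = NA_real_,
                n_set_used = n_set, testable = FALSE))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    gsea_es(scores, sample(inset), weight_p)
  }, 0)
  if (es >= 0) {
    same <- perm[perm >= 0]
    nes <- if (length(same) && mean(same) > 0) es / mean(same) else NA_real_
    p <- (1 + sum(same >= es)) / (1 + length(same))
  } else {
    same <- perm[perm < 0]
    nes <- if (length(same)) es / abs(mean(same)) else NA_real_
    p <- (1 + sum(same <= es)) / (1 + length(same))
  }
  list(es = es, nes = nes, p = p, n_set_used = as.integer(n_set),
       testable = TRUE)
}

#' Preranked GSEA over a pathway catalog
#'
#' Runs [gsea_preranked()] for every set and adds BH-adjusted FDR q-values
#' across the testable sets.
#'
#' @param ranked_list named numeric score vector.
#' @param catalog a [pathway_catalog()].
#' @param weight_p,n_perm,seed passed through; each set uses a seed derived
#'   deterministically from `seed`.
#' @return data.frame `pathway, size, es, nes, p, q`.
#' @export
gsea_catalog <- function(ranked_list, catalog, weight_p = 1, n_perm = 1000,
                         seed = 1L) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  rows <- lapply(seq_along(catalog), function(i) {
    r <- gsea_preranked(ranked_list, catalog[[i]], weight_p = weight_p,
                        n_perm = n_perm, seed = fanout_seed(seed, i))
    data.frame(pathway = names(catalog)[i], size = length(catalog[[i]]),
               es = r$es, nes = r$nes, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out
}
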