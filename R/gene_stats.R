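#' Binary patient-by-gene mutation matrix
#'
#' Cell (patient, gene) is 1 iff that patient carries at least one variant
#' of the requested origin class(es) in that gene in the given tissue.
#'
#' @param origins named list of variant-level origin tables
#'   (see [classify_cohort()]).
#' @param tissue which tissue's presence to require.
#' @param classes origin classes that qualify (default: all somatic
#'   classes).
#' @param genes optional fixed gene universe for the columns.
#' @return binary integer matrix, patients x genes.
#' @export
build_gene_matrix <- function(origins, tissue = "tumor",
                              classes = SOMATIC_CLASSES, genes = NULL) {
  tissue <- match.arg(tissue, c("blood", "normal", "tumor"))
  bit <- paste0("in_", tissue)
  hits <- lapply(origins, function(ot) {
    sel <- ot$class %in% classes & ot[[bit]] & !is.na(ot$gene) &
      ot$gene != "missing"
    unique(ot$gene[sel])
  })
  if (is.null(genes)) genes <- sort(unique(unlist(hits)))
  m <- matrix(0L, nrow = length(origins), ncol = length(genes),
              dimnames = list(names(origins), genes))
  for (i in seq_along(hits)) m[i, intersect(hits[[i]], genes)] <- 1L
  m
}

# Two-sided Fisher exact p for 2x2 tables [a, n_a - a; b, n_b - b] by the
# conventional "minlike" rule: sum of all hypergeometric outcomes no more
# likely than the observed one (relative tolerance 1e-7). Vectorised.
fisher_2x2_p <- function(a, b, n_a, n_b) {
  stopifnot(all(a >= 0 & a <= n_a), all(b >= 0 & b <= n_b))
  mapply(function(a, b, n_a, n_b) {
    m <- a + b
    k <- max(0, m - n_b):min(m, n_a)
    probs <- stats::dhyper(k, n_a, n_b, m)
    pobs <- probs[match(a, k)]
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }, a, b, n_a, n_b)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate control; input order is preserved.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Cramer's V for a 2x2 table
#'
#' `sqrt(chi^2 / n)` with the uncorrected chi-square statistic (for a 2x2
#' table `min(r, c) - 1 = 1`, so V is the phi coefficient's magnitude).
#' Tables with a zero margin carry no association and return 0.
#'
#' @param table_2x2 2x2 matrix of nonnegative counts (grand total > 0).
#' @return effect size in `[0, 1]`.
#' @export
cramers_v <- function(table_2x2) {
  stopifnot(identical(dim(table_2x2), c(2L, 2L)), all(table_2x2 >= 0),
            sum(table_2x2) > 0)
  cramers_v_cells(table_2x2[1, 1], table_2x2[1, 2], table_2x2[2, 1],
                  table_2x2[2, 2])
}

cramers_v_cells <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- ifelse(denom == 0, 0, abs(a * d - b * c) / sqrt(denom))
  out
}

#' Differential mutation test between two tissues
#'
#' Per gene, builds the 2x2 table of mutated / non-mutated patient counts
#' in the two tissues and reports the two-sided Fisher exact p (exact
#' hypergeometric "minlike" enumeration), the BH-adjusted q across genes,
#' the sample odds ratio, the log odds ratio (Haldane-Anscombe +0.5 applied
#' to all cells only when a cell is zero, and only for the log scale — the
#' exact p is never modified), and Cramer's V. A gene absent from one
#' matrix counts as unmutated in that tissue.
#'
#' @param matrix_a,matrix_b binary patient x gene matrices from
#'   [build_gene_matrix()] (patient universes may differ in size).
#' @return data.frame per gene: `gene, mutated_a, n_a, mutated_b, n_b,
#'   odds_ratio, log_or, p, q, cramers_v`, ordered alphabetically by gene.
#' @export
fisher_gene_test <- function(matrix_a, matrix_b) {
  genes <- sort(union(colnames(matrix_a), colnames(matrix_b)))
  n_a <- nrow(matrix_a); n_b <- nrow(matrix_b)
  a <- b <- setNames(integer(length(genes)), genes)
  a[colnames(matrix_a)] <- colSums(matrix_a)
  b[colnames(matrix_b)] <- colSums(matrix_b)
  or <- (a * (n_b - b)) / (b * (n_a - a))
  log_or <- log_odds_ratio(a, n_a - a, b, n_b - b)
  p <- fisher_2x2_p(a, b, n_a, n_b)
  v <- cramers_v_cells(a, n_a - a, b, n_b - b)
  data.frame(gene = genes, mutated_a = as.integer(a), n_a = n_a,
             mutated_b = as.integer(b), n_b = n_b, odds_ratio = or,
             log_or = log_or, p = p, q = bh_adjust(p), cramers_v = v,
             row.names = NULL, stringsAsFactors = FALSE)
}

# log OR of [a, c; b, d]; +0.5 on every cell only when some cell is zero,
# keeping scores finite for ranking.
log_odds_ratio <- function(a, c, b, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  log((a * d) / (b * c))
}

#' Mutation burden in variants per megabase
#'
#' Total number of variants in a gene divided by the gene length in
#' megabases.
#'
#' @param n_variants variant count(s).
#' @param gene_length_bp gene length(s) in base pairs (> 0).
#' @return variants per Mb.
#' @export
mutation_burden <- function(n_variants, gene_length_bp) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  n_variants / (gene_length_bp / 1e6)
}

#' Pearson correlation between mutation burden and age
#'
#' @param per_patient_burden,ages paired numeric vectors, n >= 3.
#' @return list `r`, `p` (two-sided t-test), `n`; when either vector has
#'   zero variance the correlation is reported as undefined (`NA` with a
#'   `reason`) rather than propagating NaN.
#' @export
burden_age_correlation <- function(per_patient_burden, ages) {
  ok <- !is.na(per_patient_burden) & !is.na(ages)
  x <- per_patient_burden[ok]; y <- ages[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                reason = "zero variance"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Most frequently mutated genes
#'
#' Genes ranked by the fraction of patients mutated, descending; ties are
#' broken alphabetically so the ranking is deterministic.
#'
#' @param matrix binary patient x gene matrix.
#' @param k number of genes to return (default 10).
#' @return data.frame `gene, n_mutated, n_patients, frequency` (percent).
#' @export
top_frequent_genes <- function(matrix, k = 10) {
  if (ncol(matrix) == 0) stop("matrix has no genes")
  cnt <- colSums(matrix)
  ord <- order(-cnt, colnames(matrix))
  top <- head(ord, k)
  data.frame(gene = colnames(matrix)[top], n_mutated = as.integer(cnt[top]),
             n_patients = nrow(matrix),
             frequency = 100 * cnt[top] / nrow(matrix),
             row.names = NULL, stringsAsFactors = FALSE)
}
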