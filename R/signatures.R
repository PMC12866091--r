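#' Build an SBS-96 context count matrix
#'
#' Counts every SNV of every sample into its pyrimidine-centred
#' trinucleotide channel. Non-SNV records (indels, MNVs) are excluded and
#' tallied.
#'
#' @param samples a [triplet_cohort()], a list of [tissue_sample()]s, or a
#'   single one; cohort samples are labelled `<patient>_<tissue>`.
#' @param reference contig sequences (see [trinucleotide_context()]).
#' @return integer 96 x samples matrix with channel rownames; attribute
#'   `n_excluded` counts non-SNV records per sample.
#' @export
build_sbs_matrix <- function(samples, reference) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  if (inherits(samples, "triplet_cohort")) {
    flat <- list()
    for (tri in samples)
      for (t in c("blood", "normal", "tumor"))
        flat[[paste0(tri$patient_id, "_", t)]] <- tri[[t]]
    samples <- flat
  }
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, function(s)
      paste0(s$patient_id, "_", s$tissue), "")
  ch <- sbs_channels()
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(ch, names(samples)))
  excluded <- setNames(integer(length(samples)), names(samples))
  for (j in seq_along(samples)) {
    v <- samples[[j]]$variants
    if (!nrow(v)) next
    snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1
    excluded[j] <- sum(!snv)
    if (!any(snv)) next
    lab <- trinucleotide_context(reference, v$chrom[snv], v$pos[snv],
                                 v$ref[snv], v$alt[snv])
    lab <- lab[!is.na(lab)]
    tab <- table(factor(lab, levels = ch))
    m[, j] <- as.integer(tab)
  }
  attr(m, "n_excluded") <- excluded
  m
}

#' Refit SBS spectra onto a known signature catalog
#'
#' Per sample, solves the nonnegative least-squares problem of expressing
#' the 96-channel spectrum as a mixture of the selected catalog signatures,
#' normalises the solution to exposure fractions, and reports the cosine
#' similarity between the observed and reconstructed spectra.
#'
#' @param sbs_matrix 96 x samples count matrix.
#' @param catalog 96 x K column-stochastic signature matrix.
#' @param signature_subset columns of the catalog to fit against (default
#'   all).
#' @return `exposure_table`: list with `fractions` (samples x signatures,
#'   rows sum to 1 for non-empty samples), `totals` (SNVs per sample) and
#'   `cosine` (reconstruction similarity; `NA` for all-zero samples).
#' @export
refit_signatures <- function(sbs_matrix, catalog,
                             signature_subset = colnames(catalog)) {
  stopifnot(nrow(sbs_matrix) == 96, nrow(catalog) == 96,
            length(signature_subset) >= 1)
  if (!all(signature_subset %in% colnames(catalog)))
    stop("unknown signature(s): ",
         paste(setdiff(signature_subset, colnames(catalog)), collapse = ", "))
  cat_sub <- catalog[, signature_subset, drop = FALSE]
  if (!is.null(rownames(sbs_matrix)))
    cat_sub <- cat_sub[rownames(sbs_matrix), , drop = FALSE]
  ns <- ncol(sbs_matrix)
  fractions <- matrix(0, nrow = ns, ncol = ncol(cat_sub),
                      dimnames = list(colnames(sbs_matrix),
                                      colnames(cat_sub)))
  cosine <- setNames(rep(NA_real_, ns), colnames(sbs_matrix))
  totals <- colSums(sbs_matrix)
  for (j in seq_len(ns)) {
    y <- sbs_matrix[, j]
    if (sum(y) == 0) next
    fit <- pracma::lsqnonneg(cat_sub, y)
    x <- fit$x
    if (sum(x) > 0) fractions[j, ] <- x / sum(x)
    cosine[j] <- cosine_sim(y, as.vector(cat_sub %*% x))
  }
  structure(list(fractions = fractions, totals = totals, cosine = cosine),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat("<exposure_table>", nrow(x$fractions), "samples x",
      ncol(x$fractions), "signatures; mean reconstruction cosine",
      format(mean(x$cosine, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' De novo signature extraction by nonnegative matrix factorisation
#'
#' Rank-k NMF of the SBS count matrix minimising Frobenius reconstruction
#' error (multiplicative updates), over several random restarts; the best
#' restart is kept. Signature columns are normalised to sum to 1. Intended
#' for desk-scale exploration at a fixed k; no model selection across k is
#' performed.
#'
#' @param sbs_matrix 96 x samples nonnegative matrix (not all zero).
#' @param k factorisation rank, `1 <= k <= min(96, n_samples)`.
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed; output is deterministic for a fixed seed.
#' @param max_iter,tol update iterations per restart and relative
#'   convergence tolerance.
#' @return list `signatures` (96 x k, columns sum to 1), `exposures`
#'   (k x samples), `frobenius_error`.
#' @export
extract_denovo <- function(sbs_matrix, k, n_restarts = 10, seed = 1L,
                           max_iter = 2000, tol = 1e-10) {
  V <- as.matrix(sbs_matrix)
  if (any(V < 0)) stop("sbs_matrix must be nonnegative")
  if (sum(V) == 0) stop("sbs_matrix is all zero")
  if (k < 1 || k > min(nrow(V), ncol(V)))
    stop("k must lie in [1, min(96, n_samples)]")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(fanout_seed(seed, r))
    W <- matrix(runif(nrow(V) * k, 0.1, 1), ncol = k)
    H <- matrix(runif(k * ncol(V), 0.1, 1), nrow = k)
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
      if (it %% 25 == 0) {
        err <- sum((V - W %*% H)^2)
        if (is.finite(err_prev) &&
            abs(err_prev - err) <= tol * max(err_prev, eps)) break
        err_prev <- err
      }
    }
    err <- sum((V - W %*% H)^2)
    if (is.null(best) || err < best$err) best <- list(W = W, H = H,
                                                      err = err)
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  dimnames(W) <- list(rownames(V) %||% sbs_channels(),
                      paste0("DN", seq_len(k)))
  dimnames(H) <- list(paste0("DN", seq_len(k)), colnames(V))
  list(signatures = W, exposures = H, frobenius_error = sqrt(best$err))
}

#' Per-group signature contribution counts and percentages
#'
#' Attributes each sample's SNV total to signatures in proportion to its
#' exposure fractions (largest-remainder rounding, so counts per sample sum
#' exactly to the sample total), then aggregates over sample groups — e.g.
#' the mutation counts and percentages per signature per tissue type.
#'
#' @param exposure_table a [refit_signatures()] result.
#' @param sample_groups factor/character of group labels, one per sample
#'   (default: one group).
#' @return data.frame `group, signature, count, percent`.
#' @export
signature_percent_contribution <- function(exposure_table,
                                           sample_groups = NULL) {
  fr <- exposure_table$fractions
  totals <- exposure_table$totals
  if (is.null(sample_groups)) sample_groups <- rep("all", nrow(fr))
  stopifnot(length(sample_groups) == nrow(fr))
  counts <- t(vapply(seq_len(nrow(fr)), function(i)
    largest_remainder(fr[i, ], totals[i]), integer(ncol(fr))))
  if (ncol(fr) == 1) counts <- matrix(counts, ncol = 1)
  rows <- lapply(unique(sample_groups), function(g) {
    sel <- sample_groups == g
    cnt <- colSums(counts[sel, , drop = FALSE])
    tot <- sum(cnt)
    data.frame(group = g, signature = colnames(fr), count = as.integer(cnt),
               percent = if (tot > 0) 100 * cnt / tot else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank test for paired vectors
#'
#' Two-sided paired test of the differences `x - y`; zero differences are
#' dropped first. The exact null distribution is used for n <= 25 when
#' there are no rank ties; otherwise the normal approximation with tie
#' correction (and continuity correction) applies.
#'
#' @param x,y paired numeric vectors; at least 5 nonzero differences.
#' @return list `statistic, p, n_used, exact`; when every difference is
#'   zero the result is flagged not testable.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n_used = 0L,
                exact = NA, testable = FALSE))
  if (length(nz) < 5)
    stop("need at least 5 nonzero differences")
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(nz, alternative = "two.sided",
                                     mu = 0, exact = exact,
                                     correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(nz), exact = exact, testable = TRUE)
}
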