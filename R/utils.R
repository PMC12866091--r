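`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a DNA string
#'
#' Plain-character helper used throughout the simulator and the SBS-96
#' context code. Vectorised over its input.
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  flipped <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(flipped, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Cosine similarity between two nonnegative vectors
#' @keywords internal
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

#' Largest-remainder rounding
#'
#' Rounds a nonnegative vector to integers that sum exactly to `total`
#' (Hamilton apportionment). Used so per-signature attributed mutation
#' counts add up to each sample's SNV total.
#'
#' @param x nonnegative numeric vector of ideal (real-valued) shares.
#' @param total integer the rounded values must sum to.
#' @return integer vector, `sum(result) == total`.
#' @export
largest_remainder <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0)
  if (length(x) == 0) return(integer(0))
  if (sum(x) == 0) {
    out <- integer(length(x))
    if (total > 0) out[1] <- total
    return(out)
  }
  ideal <- x / sum(x) * total
  base <- floor(ideal)
  short <- total - sum(base)
  if (short > 0) {
    # break remainder ties by index so the result is deterministic
    ord <- order(ideal - base, -seq_along(x), decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Derive a per-patient RNG seed from the global one (MINSTD-style multiplier,
# kept in exact double arithmetic, result < 2^31 - 1).
fanout_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((48271 * ((seed %% m) + index)) %% m)
}

# first-fail reporting helper: returns index of first TRUE or 0L
first_true <- function(...) {
  flags <- c(...)
  idx <- which(flags)
  if (length(idx)) idx[1] else 0L
}
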