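#' Canonical SBS-96 channel labels
#'
#' The 96 single-base-substitution classes: six pyrimidine-centred
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) in blocks, each with its 16
#' flanking-base contexts in alphabetical order (5' base varying slowest).
#' This is the row layout of COSMIC-style signature files, so catalogs load
#' without remapping.
#'
#' @return character vector of 96 labels such as `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t)
      paste0(f, "[", s, "]", t))))))
}

# Split "A[C>T]G" into its parts.
parse_channel <- function(channel) {
  m <- regmatches(channel,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", channel))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) stop("malformed SBS channel label: ", channel[bad][1])
  data.frame(five = vapply(m, `[`, "", 2), ref = vapply(m, `[`, "", 3),
             alt = vapply(m, `[`, "", 4), three = vapply(m, `[`, "", 5))
}

#' SBS-96 channel of a single-nucleotide variant
#'
#' Maps an SNV plus its reference trinucleotide context to one of the 96
#' pyrimidine-centred channels. When the reference base is a purine the
#' substitution is projected onto the opposite strand (reverse complement of
#' the context, complement of the alternate base), so the two strand
#' representations of the same event share a channel.
#'
#' @param reference named character vector (or `DNAStringSet`-coercible) of
#'   contig sequences, or a `sim_reference`.
#' @param chrom,pos,ref,alt SNV coordinates (1-based) and alleles; vectorised.
#' @return character vector of channel labels; `NA` (with a warning count)
#'   for variants at a contig edge.
#' @export
trinucleotide_context <- function(reference, chrom, pos, ref, alt) {
  seqs <- reference_sequences(reference)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (any(nchar(ref) != 1 | nchar(alt) != 1))
    stop("trinucleotide_context() is defined for SNVs only")
  out <- rep(NA_character_, n)
  edge <- 0L
  for (ctg in unique(chrom)) {
    s <- seqs[[ctg]]
    if (is.null(s)) stop("contig not in reference: ", ctg)
    i <- which(chrom == ctg)
    len <- nchar(s)
    ok <- pos[i] >= 2 & pos[i] <= len - 1
    edge <- edge + sum(!ok)
    i <- i[ok]
    if (!length(i)) next
    ctx <- substring(s, pos[i] - 1, pos[i] + 1)
    centre <- substring(ctx, 2, 2)
    if (any(centre != ref[i]))
      stop("reference mismatch at ", ctg, ":", pos[i][centre != ref[i]][1],
           " (reference has ", centre[centre != ref[i]][1], ")")
    pur <- ref[i] %in% c("A", "G")
    ctx[pur] <- revcomp(ctx[pur])
    a <- alt[i]
    a[pur] <- chartr("ACGT", "TGCA", a[pur])
    out[i] <- paste0(substring(ctx, 1, 1), "[", substring(ctx, 2, 2), ">",
                     a, "]", substring(ctx, 3, 3))
  }
  if (edge > 0)
    warning(edge, " variant(s) at contig edges skipped (no full context)")
  out
}

# Accept a sim_reference, a named character vector, or a file path to FASTA.
reference_sequences <- function(reference) {
  if (inherits(reference, "sim_reference")) return(as.list(reference$sequences))
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    out <- as.list(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference)))
    return(as.list(reference))
  stop("reference must be a sim_reference, a named character vector of ",
       "contig sequences, or a FASTA path")
}
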