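#' Canonical variant keys
#'
#' Normalises alleles so that identical biological events map to identical
#' keys: shared trailing bases are trimmed first, then shared leading bases
#' (advancing the position), always leaving at least one base per allele.
#' E.g. `(chr1, 100, AT, GT)` becomes `(chr1, 100, A, G)`.
#'
#' @param x data.frame with columns `chrom, pos, ref, alt` (extra columns
#'   ignored).
#' @return data.frame with normalised `chrom, pos, ref, alt` and a `key`
#'   string `"chrom:pos:ref>alt"`.
#' @export
variant_key <- function(x) {
  chrom <- as.character(x$chrom); pos <- as.integer(x$pos)
  ref <- as.character(x$ref); alt <- as.character(x$alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  nr <- nchar(ref); na <- nchar(alt)
  # trim shared suffix
  repeat {
    can <- nr > 1 & na > 1 &
      substring(ref, nr, nr) == substring(alt, na, na)
    if (!any(can)) break
    ref[can] <- substring(ref[can], 1, nr[can] - 1)
    alt[can] <- substring(alt[can], 1, na[can] - 1)
    nr[can] <- nr[can] - 1L; na[can] <- na[can] - 1L
  }
  # trim shared prefix, advancing pos
  repeat {
    can <- nr > 1 & na > 1 &
      substring(ref, 1, 1) == substring(alt, 1, 1)
    if (!any(can)) break
    ref[can] <- substring(ref[can], 2)
    alt[can] <- substring(alt[can], 2)
    pos[can] <- pos[can] + 1L
    nr[can] <- nr[can] - 1L; na[can] <- na[can] - 1L
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste0(chrom, ":", pos, ":", ref, ">", alt),
             stringsAsFactors = FALSE)
}

# Map "chr1" / "1" to the single convention without the prefix; purely
# cosmetic contigs like "sim1" are left alone.
normalize_chrom <- function(chrom) sub("^chr", "", chrom)

CLNSIG_LEVELS <- c("pathogenic", "likely_pathogenic", "benign", "VUS",
                   "missing")

normalize_clnsig <- function(x) {
  x <- tolower(x)
  out <- rep("missing", length(x))
  out[x %in% c("pathogenic")] <- "pathogenic"
  out[x %in% c("likely_pathogenic", "likely pathogenic")] <- "likely_pathogenic"
  out[x %in% c("benign", "likely_benign", "likely benign")] <- "benign"
  out[x %in% c("uncertain_significance", "vus")] <- "VUS"
  out
}

#' Read an annotated VCF into a tissue sample
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) carrying ANNOVAR-style annotation
#' INFO keys (`Gene`, `ExonicFunc`, `MetaSVM`, `CLNSIG`, `CADD`), GATK site
#' QC metrics (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`) and
#' `GT:AD:DP:GQ` sample fields. Multi-allelic sites are split into one
#' bi-allelic record per ALT allele before any set logic. Missing annotation
#' keys become `"missing"`, missing QC metrics `NA`. Records without usable
#' AD/DP keep an undefined VAF.
#'
#' @param path VCF file path.
#' @param patient_id,tissue sample identity; defaults parsed from a
#'   `<patient>_<tissue>.vcf` filename.
#' @return a [tissue_sample()].
#' @export
read_annotated_vcf <- function(path, patient_id = NULL, tissue = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  m <- regmatches(base, regexec("^(.*)_(blood|normal|tumor)$", base))[[1]]
  if (is.null(patient_id))
    patient_id <- if (length(m)) m[2] else base
  if (is.null(tissue)) {
    if (!length(m))
      stop("cannot infer tissue from filename '", basename(path),
           "'; pass tissue= explicitly")
    tissue <- m[3]
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse VCF ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0)
    return(tissue_sample(patient_id, tissue))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_str <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else v
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_str(key)))
  ad_str <- gq_str <- dp_str <- rep(NA_character_, n)
  if (ncol(vcf@gt) >= 2) {
    ad_str <- vcfR::extract.gt(vcf, element = "AD")[, 1]
    dp_str <- vcfR::extract.gt(vcf, element = "DP")[, 1]
    gq_str <- vcfR::extract.gt(vcf, element = "GQ")[, 1]
  }
  site <- data.frame(chrom = normalize_chrom(fix$CHROM),
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT,
                     gene = info_str("Gene"),
                     exonic_func = info_str("ExonicFunc"),
                     metasvm = info_str("MetaSVM"),
                     clnsig = info_str("CLNSIG"),
                     cadd = info_num("CADD"),
                     qd = info_num("QD"), fs = info_num("FS"),
                     mq = info_num("MQ"),
                     mq_rank_sum = info_num("MQRankSum"),
                     read_pos_rank_sum = info_num("ReadPosRankSum"),
                     ad = ad_str, dp = suppressWarnings(as.integer(dp_str)),
                     gq = suppressWarnings(as.numeric(gq_str)),
                     stringsAsFactors = FALSE)
  # split multi-allelic sites into bi-allelic records
  alts <- strsplit(site$alt, ",", fixed = TRUE)
  k <- lengths(alts)
  idx <- rep(seq_len(n), k)
  which_alt <- unlist(lapply(k, seq_len))
  rec <- site[idx, ]
  rec$alt <- unlist(alts)
  ad_parts <- strsplit(rec$ad, ",", fixed = TRUE)
  rec$ad_alt <- suppressWarnings(as.integer(mapply(
    function(p, i) if (length(p) >= i + 1) p[i + 1] else NA_character_,
    ad_parts, which_alt)))
  fix_missing <- function(x) {
    x[is.na(x) | x == "." | x == ""] <- "missing"
    x
  }
  out <- data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                    alt = rec$alt, gene = fix_missing(rec$gene),
                    exonic_func = fix_missing(rec$exonic_func),
                    metasvm = fix_missing(rec$metasvm),
                    clinvar = normalize_clnsig(rec$clnsig),
                    cadd = rec$cadd, dp = rec$dp, ad_alt = rec$ad_alt,
                    gq = rec$gq, qd = rec$qd, fs = rec$fs, mq = rec$mq,
                    mq_rank_sum = rec$mq_rank_sum,
                    read_pos_rank_sum = rec$read_pos_rank_sum,
                    stringsAsFactors = FALSE)
  tissue_sample(patient_id, tissue, out)
}

#' Write a tissue sample as VCF 4.2
#'
#' Inverse of [read_annotated_vcf()]: annotation fields go to INFO, read
#' support to `GT:AD:DP:GQ`. `"missing"` annotations are written as `.`.
#'
#' @param sample a [tissue_sample()].
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_tissue_vcf <- function(sample, path, contig_lengths = NULL) {
  stopifnot(inherits(sample, "tissue_sample"))
  v <- sample$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tripletmut")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr,
    '##INFO=<ID=Gene,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=ExonicFunc,Number=1,Type=String,Description="Exonic function">',
    '##INFO=<ID=MetaSVM,Number=1,Type=String,Description="MetaSVM call (D/T)">',
    '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar significance">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample$patient_id), collapse = "\t"))
  lines <- hdr
  if (nrow(v)) {
    fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                  format(x, scientific = FALSE, trim = TRUE))
    info_field <- function(key, val, missing_ok = TRUE) {
      out <- ifelse(is.na(val) | val == "missing", NA_character_,
                    paste0(key, "=", val))
      out
    }
    parts <- cbind(info_field("Gene", v$gene),
                   info_field("ExonicFunc", v$exonic_func),
                   info_field("MetaSVM", v$metasvm),
                   info_field("CLNSIG", ifelse(v$clinvar == "missing",
                                               NA_character_, v$clinvar)),
                   info_field("CADD", fmt_num(v$cadd)),
                   info_field("QD", fmt_num(v$qd)),
                   info_field("FS", fmt_num(v$fs)),
                   info_field("MQ", fmt_num(v$mq)),
                   info_field("MQRankSum", fmt_num(v$mq_rank_sum)),
                   info_field("ReadPosRankSum", fmt_num(v$read_pos_rank_sum)))
    info <- apply(parts, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) paste(r, collapse = ";") else "."
    })
    gt <- ifelse(!is.na(v$vaf) & v$vaf >= 0.999, "1/1", "0/1")
    ad <- ifelse(is.na(v$dp) | is.na(v$ad_alt), ".",
                 paste0(v$dp - v$ad_alt, ",", v$ad_alt))
    dp <- ifelse(is.na(v$dp), ".", as.character(v$dp))
    gq <- ifelse(is.na(v$gq), ".", fmt_num(v$gq))
    lines <- c(lines, paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                            info, "GT:AD:DP:GQ",
                            paste(gt, ad, dp, gq, sep = ":"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort of triplet VCFs from a directory
#'
#' Expects files named `<patient>_<tissue>.vcf` with tissues `blood`,
#' `normal`, `tumor`, and optionally a `patients.tsv` with columns
#' `patient_id, age, cohort`. Patients lacking any of the three tissues are
#' rejected.
#'
#' @param dir directory path.
#' @param label cohort label when `patients.tsv` is absent.
#' @return a [triplet_cohort()].
#' @export
read_cohort_dir <- function(dir, label = "cohort") {
  files <- list.files(dir, pattern = "_(blood|normal|tumor)\\.vcf$")
  if (!length(files)) stop("no <patient>_<tissue>.vcf files in ", dir)
  pid <- sub("_(blood|normal|tumor)\\.vcf$", "", files)
  meta <- NULL
  meta_path <- file.path(dir, "patients.tsv")
  if (file.exists(meta_path))
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  triplets <- lapply(unique(pid), function(p) {
    smp <- lapply(c("blood", "normal", "tumor"), function(t) {
      f <- file.path(dir, paste0(p, "_", t, ".vcf"))
      if (!file.exists(f))
        stop("patient ", p, " is missing its ", t,
             " sample; incomplete triplets are excluded")
      read_annotated_vcf(f, patient_id = p, tissue = t)
    })
    age <- NA_real_; coh <- label
    if (!is.null(meta) && p %in% meta$patient_id) {
      row <- meta[meta$patient_id == p, ]
      age <- row$age[1] %||% NA_real_
      if ("cohort" %in% names(row)) coh <- row$cohort[1]
    }
    patient_triplet(p, smp[[1]], smp[[2]], smp[[3]], age = age, cohort = coh)
  })
  triplet_cohort(triplets, label = label)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB interchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are uppercased and
#' deduplicated; empty sets are skipped with a warning.
#'
#' @param gmt_path path to a GMT file.
#' @param label collection label (`"Hallmark"`, `"KEGG"`, ...).
#' @return a named list of character vectors with attribute `label`
#'   (class `pathway_catalog`).
#' @export
read_gene_sets <- function(gmt_path, label = "custom") {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT parse error: line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  names(sets) <- vapply(fields, `[`, "", 1)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  pathway_catalog(sets, label)
}

#' Construct a pathway catalog
#'
#' @param sets named list of character gene-symbol vectors.
#' @param label collection label.
#' @return `pathway_catalog` object.
#' @export
pathway_catalog <- function(sets, label = "custom") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene set names must be present and unique")
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, label = label, class = c("pathway_catalog", "list"))
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat("<pathway_catalog>", attr(x, "label"), "-", length(x), "sets,",
      length(unique(unlist(x))), "distinct genes\n")
  invisible(x)
}

#' Read an SBS signature catalog
#'
#' Tab-delimited, COSMIC-style layout: first column channel labels
#' (`A[C>A]A`, ...), one column per signature, 96 data rows. Rows are
#' reordered to the canonical channel order; columns whose sums are within
#' `1e-3` of 1 are renormalised to sum exactly to 1; anything else is
#' rejected.
#'
#' @param path file path.
#' @return numeric 96 x K matrix with channel rownames.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != 96)
    stop("signature catalog must have exactly 96 data rows, got ", nrow(df))
  labels <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(is.na(mat))) stop("non-numeric entries in signature catalog")
  if (any(mat < 0)) stop("negative entries in signature catalog")
  if (!setequal(labels, sbs_channels()) || anyDuplicated(labels))
    stop("first column must contain the 96 SBS channel labels")
  rownames(mat) <- labels
  mat <- mat[sbs_channels(), , drop = FALSE]
  cs <- colSums(mat)
  off <- abs(cs - 1) > 1e-3
  if (any(off))
    stop("signature column(s) not normalised (sum off by > 1e-3): ",
         paste(colnames(mat)[off], collapse = ", "))
  sweep(mat, 2, cs, "/")
}

#' Write an SBS signature catalog
#' @param catalog 96 x K matrix with channel rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  stopifnot(nrow(catalog) == 96)
  df <- data.frame(Type = rownames(catalog) %||% sbs_channels(), catalog,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
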