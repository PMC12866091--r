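# Shared fixtures, built in code. small_sim() is memoised per session so the
# many tests that need a cohort pay the simulation cost once.

small_config <- function(...) {
  sim_config(n_patients = 4, n_genes = 120, gene_length_bp = 900,
             n_germline_per_patient = 50, n_shared_somatic = 8,
             n_tumor_private = 10, n_normal_private = 5,
             impact_pass_fraction = 0.6, seed = 11L, ...)
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_cohort(small_config())
  .sim_cache$sim
}

# high-VAF cohort: somatic VAF fixed well above the detection limit so no
# variant is censored
noiseless_config <- function(...) {
  sim_config(n_patients = 4, n_genes = 120, gene_length_bp = 900,
             n_germline_per_patient = 50, n_shared_somatic = 8,
             n_tumor_private = 10, n_normal_private = 5,
             somatic_vaf = list(dist = "fixed", value = 0.45),
             impact_pass_fraction = 0.6, seed = 13L, ...)
}

noiseless_sim <- function() {
  if (is.null(.sim_cache$noiseless))
    .sim_cache$noiseless <- simulate_cohort(noiseless_config())
  .sim_cache$noiseless
}

# a hand-built variant record row with comfortable QC values
qc_record <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                      gene = "G1", exonic_func = "nonsynonymous_SNV",
                      metasvm = "D", clinvar = "missing", cadd = 25,
                      dp = 100L, ad_alt = 50L, gq = 99, qd = 20, fs = 1,
                      mq = 60, mq_rank_sum = 0, read_pos_rank_sum = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             exonic_func = exonic_func, metasvm = metasvm,
             clinvar = clinvar, cadd = cadd, dp = dp, ad_alt = ad_alt,
             gq = gq, qd = qd, fs = fs, mq = mq,
             mq_rank_sum = mq_rank_sum,
             read_pos_rank_sum = read_pos_rank_sum,
             stringsAsFactors = FALSE)
}

# build a triplet from three small variant tables (keyed rows)
toy_triplet <- function(blood, normal, tumor, pid = "PT") {
  patient_triplet(pid,
                  tissue_sample(pid, "blood", blood),
                  tissue_sample(pid, "normal", normal),
                  tissue_sample(pid, "tumor", tumor),
                  age = 40, cohort = "toy")
}
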