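# Shared seeded cohorts, generated once per test run and cached.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

# small two-tissue cohort for fast structural tests
tiny_cohort <- function() {
  cached_cohort("tiny", simulation_config(
    n_donors = 120, tissues = c(tissueA = 1, tissueB = 0.8),
    n_genes = 500, n_shared_age_genes = 50, seed = 101))
}

prep_log2 <- function(m) log2_transform(quantile_normalize(m))

# samples-x-genes design + ages for one tissue of a cohort
design_for <- function(cohort, tissue) {
  sub <- subset_by_tissue(cohort$matrices[[tissue]], cohort$samples, tissue)
  m <- prep_log2(sub$matrix)
  list(x = t(m$values), ages = sub$table$age, table = sub$table)
}

causal_genes <- function(cohort, tissue) {
  unique(cohort$truth$gene_id[cohort$truth$tissue == tissue &
                              cohort$truth$beta != 0])
}

table1_path <- function() {
  system.file("extdata", "gtex_v6_cohort_summary.tsv", package = "txclock")
}

table4_path <- function() {
  system.file("extdata", "pituitary_muscle_model.tsv", package = "txclock")
}
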