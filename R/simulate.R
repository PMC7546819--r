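#' Configuration for the synthetic multi-tissue cohort generator
#'
#' Describes a GTEx-like cohort: donors aged 20-70 (integer years by
#' default), several tissues sampled per donor with partial overlap, a
#' minority of genes carrying linear age effects on the log2 scale (shared
#' across tissues or tissue-specific), Gaussian per-gene residual noise, and
#' a donor-by-tissue "transcriptomic age" deviation that makes each tissue
#' report a noisy version of chronological age — the component that limits
#' single-tissue accuracy and that combining tissues can average away.
#'
#' Generative model for gene g, donor s, tissue t:
#' \deqn{\log_2 x = \mu_g + \delta_{g,t} + \beta_{g,t} \cdot a_{s,t} + \varepsilon,}
#' where \eqn{a_{s,t} = (age_s + \eta_{s,t} - mid)/halfrange} is the
#' standardized transcriptomic age of the tissue
#' (\eqn{\eta_{s,t} \sim N(0, tissue\_age\_sd^2)}, years),
#' \eqn{\varepsilon \sim N(0, noise\_sd^2)} (log2 units), and raw expression
#' is \eqn{2^{\log_2 x}}. Slopes \eqn{\beta} of causal genes are drawn
#' \eqn{N(0, effect\_size\_sd^2)} with magnitudes below
#' `effect_floor * effect_size_sd` redrawn, so configured causal genes are never
#' effectively null.
#'
#' @param n_donors number of donors.
#' @param tissues named numeric vector: per-tissue donor-inclusion
#'   probability in (0, 1].
#' @param n_genes total genes per tissue.
#' @param n_shared_age_genes genes with the same age slope in every tissue.
#' @param n_specific_age_genes integer (recycled) or named vector: causal
#'   genes private to each tissue.
#' @param effect_size_sd sd of causal slopes (log2 units per standardized age).
#' @param effect_floor relative magnitude floor for causal slopes in `[0, 1)`:
#'   draws with `|beta| < effect_floor * effect_size_sd` are redrawn, so a
#'   configured causal gene is never effectively null. Raise it (e.g. 0.5)
#'   for stress tests that need every causal gene unambiguously detectable.
#' @param noise_sd per-gene Gaussian residual sd (log2 units).
#' @param baseline_mean_sd sd of per-gene baselines \eqn{\mu_g} (log2 units).
#' @param tissue_age_sd sd (years) of the per-donor, per-tissue deviation
#'   between transcriptomic and chronological age; 3 by default.
#' @param age_range donor ages are uniform on this range (years).
#' @param integer_ages round ages to whole years (default TRUE).
#' @param sex_ratio expected male:female ratio (males drawn with probability
#'   `sex_ratio / (1 + sex_ratio)`).
#' @param seed master seed; the generator is byte-reproducible given it.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_donors = 300,
                              tissues = c(tissueA = 0.8, tissueB = 0.8),
                              n_genes = 2000,
                              n_shared_age_genes = 50,
                              n_specific_age_genes = 0,
                              effect_size_sd = 2,
                              effect_floor = 0.1,
                              noise_sd = 0.5,
                              baseline_mean_sd = 2,
                              tissue_age_sd = 3,
                              age_range = c(20, 70),
                              integer_ages = TRUE,
                              sex_ratio = 1.5,
                              seed = 1) {
  if (is.null(names(tissues)) || any(!nzchar(names(tissues)))) {
    stop("'tissues' must be a named vector of inclusion probabilities")
  }
  if (any(tissues <= 0 | tissues > 1)) stop("inclusion probabilities must be in (0, 1]")
  n_specific <- rep_len(as.integer(n_specific_age_genes), length(tissues))
  names(n_specific) <- names(tissues)
  if (n_shared_age_genes < 0 || any(n_specific < 0)) stop("gene counts must be non-negative")
  if (n_shared_age_genes + sum(n_specific) > n_genes) {
    stop("n_shared_age_genes + sum(n_specific_age_genes) must not exceed n_genes")
  }
  if (age_range[1L] >= age_range[2L]) stop("age_range must satisfy min < max")
  if (n_donors < 2L) stop("need at least 2 donors")
  if (effect_floor < 0 || effect_floor >= 1) stop("effect_floor must lie in [0, 1)")
  structure(list(
    n_donors = as.integer(n_donors), tissues = tissues,
    n_genes = as.integer(n_genes),
    n_shared_age_genes = as.integer(n_shared_age_genes),
    n_specific_age_genes = n_specific,
    effect_size_sd = effect_size_sd, effect_floor = effect_floor,
    noise_sd = noise_sd,
    baseline_mean_sd = baseline_mean_sd, tissue_age_sd = tissue_age_sd,
    age_range = as.numeric(age_range), integer_ages = isTRUE(integer_ages),
    sex_ratio = sex_ratio, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Simulate a multi-tissue expression cohort with known ground truth
#'
#' Draws a cohort according to a [simulation_config()]: donor ages and sexes,
#' per-tissue donor inclusion (every donor is guaranteed at least one
#' tissue), causal slopes, and raw-scale expression matrices. Deterministic
#' given `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [simulation_config()].
#' @return List with `matrices` (named list of raw-scale
#'   [expression_matrix()], one per tissue), `samples` (a [sample_table()]),
#'   `truth` (data frame `gene_id`, `tissue`, `beta`, zero for null genes),
#'   `donors` (data frame `donor_id`, `age`, `sex`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    nd <- config$n_donors
    tissues <- names(config$tissues)
    donor_id <- sprintf("D%04d", seq_len(nd))
    age <- stats::runif(nd, config$age_range[1L], config$age_range[2L])
    if (config$integer_ages) age <- round(age)
    p_male <- config$sex_ratio / (1 + config$sex_ratio)
    sex <- ifelse(stats::runif(nd) < p_male, "male", "female")

    include <- vapply(tissues, function(t) {
      stats::runif(nd) < config$tissues[[t]]
    }, logical(nd))
    if (!is.matrix(include)) include <- matrix(include, nrow = nd)
    none <- rowSums(include) == 0L
    if (any(none)) {           # every donor appears in at least one tissue
      include[cbind(which(none),
                    sample.int(length(tissues), sum(none), replace = TRUE))] <- TRUE
    }
    for (ti in seq_along(tissues)) {
      if (!any(include[, ti])) {
        stop("configuration yields an empty tissue: ", tissues[ti])
      }
    }

    gene_id <- sprintf("G%05d", seq_len(config$n_genes))
    mu <- stats::rnorm(config$n_genes, mean = 5, sd = config$baseline_mean_sd)

    # causal structure: first the shared block, then per-tissue blocks
    draw_slopes <- function(n) {
      b <- stats::rnorm(n, 0, config$effect_size_sd)
      floor_b <- config$effect_floor * config$effect_size_sd
      while (any(small <- abs(b) < floor_b)) {
        b[small] <- stats::rnorm(sum(small), 0, config$effect_size_sd)
      }
      b
    }
    beta <- matrix(0, config$n_genes, length(tissues),
                   dimnames = list(gene_id, tissues))
    n_sh <- config$n_shared_age_genes
    if (n_sh > 0L) {
      shared <- draw_slopes(n_sh)
      beta[seq_len(n_sh), ] <- shared   # same slope in every tissue
    }
    offset <- n_sh
    for (ti in seq_along(tissues)) {
      n_sp <- config$n_specific_age_genes[[ti]]
      if (n_sp > 0L) {
        beta[offset + seq_len(n_sp), ti] <- draw_slopes(n_sp)
        offset <- offset + n_sp
      }
    }

    mid <- mean(config$age_range)
    halfrange <- diff(config$age_range) / 2

    matrices <- list()
    sample_rows <- list()
    for (ti in seq_along(tissues)) {
      t_name <- tissues[ti]
      donors_t <- which(include[, ti])
      eta <- stats::rnorm(length(donors_t), 0, config$tissue_age_sd)
      a_std <- (age[donors_t] + eta - mid) / halfrange
      delta <- stats::rnorm(config$n_genes, 0, 0.5)   # tissue baseline shift
      logx <- mu + delta + outer(beta[, ti], a_std) +
        matrix(stats::rnorm(config$n_genes * length(donors_t), 0, config$noise_sd),
               config$n_genes, length(donors_t))
      values <- 2^logx
      s_ids <- paste(donor_id[donors_t], t_name, sep = "-")
      dimnames(values) <- list(gene_id, s_ids)
      matrices[[t_name]] <- expression_matrix(values, scale = "raw", tissue = t_name)
      sample_rows[[t_name]] <- data.frame(
        sample_id = s_ids, donor_id = donor_id[donors_t], tissue = t_name,
        age = age[donors_t], sex = sex[donors_t], stringsAsFactors = FALSE)
    }

    truth <- data.frame(
      gene_id = rep(gene_id, length(tissues)),
      tissue = rep(tissues, each = config$n_genes),
      beta = as.vector(beta), stringsAsFactors = FALSE)

    list(matrices = matrices,
         samples = sample_table(do.call(rbind, sample_rows)),
         truth = truth,
         donors = data.frame(donor_id = donor_id, age = age, sex = sex,
                             stringsAsFactors = FALSE),
         config = config)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes one GCT 1.2 file per tissue (`<prefix>_<tissue>.gct`), the sample
#' attribute table (`<prefix>_samples.tsv`) and the ground-truth slopes
#' (`<prefix>_truth.tsv`). Files round-trip through [read_expression()] /
#' [read_sample_table()] and are byte-identical across runs with the same
#' config seed.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
export_fixture <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (t_name in names(cohort$matrices)) {
    p <- file.path(dir, paste0(prefix, "_", t_name, ".gct"))
    write_expression(cohort$matrices[[t_name]], p, format = "gct")
    paths <- c(paths, p)
  }
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  write_sample_table(cohort$samples, sp)
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(cohort$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sp, tp))
}
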