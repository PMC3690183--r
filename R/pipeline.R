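#' Simulation settings for a paired-trait cohort study
#'
#' Bundles and validates every generator parameter. The defaults describe the
#' emulated study conditions: a cohort of 2,000 conventionally unrelated
#' genotyped children (organised as one member per twin pair, i.e. 1,000
#' families of 2 before selection is applied downstream), 5,000 unlinked
#' SNPs of which 500 are causal, genetic and residual covariance set to the
#' reference general-ability/language components (true genetic correlation
#' 0.81, heritability ~0.36), and 2,000 MZ + 2,000 DZ twin pairs drawn from
#' the reference ACE components.
#'
#' @param n_individuals,n_snps,n_causal Cohort dimensions.
#' @param maf_range Ancestral allele-frequency range.
#' @param sigma_g,sigma_e 2x2 genetic and residual covariance matrices of the
#'   paired traits.
#' @param fst,subpop_fractions Stratification parameters (see
#'   [sim_genotypes()]).
#' @param n_mz,n_dz Twin-pair counts.
#' @param ace List with 2x2 PSD matrices `sigma_a`, `sigma_c`, `sigma_e` for
#'   the twin generator.
#' @param sex_effect,age_effect Covariate slopes planted on the traits.
#' @param missing_geno_rate,missing_pheno_rate Optional missingness rates.
#' @param family_size Individuals per family id in the genotyped cohort.
#' @param seed Integer seed; the single RNG stream for the whole simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000, n_snps = 5000, n_causal = 500,
                       maf_range = c(0.05, 0.5),
                       sigma_g = matrix(c(0.36, 0.29, 0.29, 0.35), 2),
                       sigma_e = matrix(c(0.63, 0.33, 0.33, 0.65), 2),
                       fst = 0, subpop_fractions = 1,
                       n_mz = 2000, n_dz = 2000,
                       ace = list(
                         sigma_a = matrix(c(0.46, 0.36, 0.36, 0.48), 2),
                         sigma_c = matrix(c(0.21, 0.19, 0.19, 0.20), 2),
                         sigma_e = matrix(c(0.33, 0.07, 0.07, 0.32), 2)
                       ),
                       sex_effect = c(0, 0), age_effect = c(0, 0),
                       missing_geno_rate = 0, missing_pheno_rate = 0,
                       family_size = 2, seed = 1) {
  sigma_g <- check_psd(as_matrix2(sigma_g), "sigma_g")
  sigma_e <- check_psd(as_matrix2(sigma_e), "sigma_e")
  vp <- sigma_g + sigma_e
  if (any(diag(vp) <= 0)) abort("implied phenotypic variances must be positive")
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals", min = 2L),
    n_snps = check_count(n_snps, "n_snps"),
    n_causal = check_count(n_causal, "n_causal"),
    maf_range = maf_range, sigma_g = sigma_g, sigma_e = sigma_e,
    fst = fst, subpop_fractions = subpop_fractions,
    n_mz = check_count(n_mz, "n_mz", min = 0L),
    n_dz = check_count(n_dz, "n_dz", min = 0L),
    ace = lapply(ace, function(m) check_psd(as_matrix2(m), "ace")),
    sex_effect = sex_effect, age_effect = age_effect,
    missing_geno_rate = missing_geno_rate,
    missing_pheno_rate = missing_pheno_rate,
    family_size = check_count(family_size, "family_size"),
    seed = seed
  )
  if (cfg$n_causal > cfg$n_snps) abort("`n_causal` must not exceed `n_snps`")
  structure(cfg, class = "sim_config")
}

as_matrix2 <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(unlist(x), 2, 2, byrow = TRUE)
}

#' Simulate a full cohort from a `sim_config`
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` (genotype_matrix), `phen` (phenotypes +
#'   covariates, family ids grouping `family_size` consecutive individuals)
#'   and `twins` (twin_dataset).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  geno <- sim_genotypes(cfg$n_individuals, cfg$n_snps, cfg$maf_range,
                        cfg$fst, cfg$subpop_fractions, seed = cfg$seed)
  if (cfg$missing_geno_rate > 0) {
    geno <- add_missing_genotypes(geno, cfg$missing_geno_rate,
                                  seed = cfg$seed + 11L)
  }
  phen <- sim_phenotypes(geno, cfg$n_causal, cfg$sigma_g, cfg$sigma_e,
                         seed = cfg$seed + 1L)
  phen <- attach_covariates(phen, cfg$sex_effect, cfg$age_effect,
                            seed = cfg$seed + 2L)
  phen$fid <- sprintf("fam_%04d",
                      (seq_len(nrow(phen)) - 1L) %/% cfg$family_size + 1L)
  if (cfg$missing_pheno_rate > 0) {
    phen <- add_missing_phenotypes(phen, cfg$missing_pheno_rate,
                                   seed = cfg$seed + 12L)
  }
  paths <- ace_paths(cfg$ace$sigma_a, cfg$ace$sigma_c, cfg$ace$sigma_e)
  twins <- sim_twins(cfg$n_mz, cfg$n_dz, paths$a, paths$c, paths$e,
                     seed = cfg$seed + 3L)
  list(geno = geno, phen = phen, twins = twins)
}

#' Full analysis configuration
#'
#' All thresholds of the workflow flow from here; none are hard-coded in the
#' stage code. `sim` may be `NULL` when `input` paths are given instead.
#'
#' @param sim A [sim_config()], or `NULL` to ingest files.
#' @param input Optional list of input paths: `vcf` or `plink` (prefix),
#'   `phen1`, `phen2`, `covar`, `twins`.
#' @param k_sd Outlier SD multiplier.
#' @param quantile_norm Quantile-normalize traits?
#' @param relatedness_threshold GRM pruning cutoff.
#' @param relatedness_noise_z Desk-scale guard: relatedness estimates from m
#'   SNPs carry sampling noise of roughly `1/sqrt(m)` per pair, so a cutoff
#'   below that noise removes individuals at random. The pipeline floors the
#'   effective cutoff at `relatedness_noise_z / sqrt(m)` (with a warning when
#'   the floor binds); set to 0 to apply `relatedness_threshold` verbatim.
#' @param r2_max,ld_window,ld_step LD-pruning parameters.
#' @param pca_k,alpha PCA axis count and Tracy-Widom level.
#' @param add_sex_age Also pass sex/age as GREML fixed effects (traits are
#'   already residualized on them, so the default is principal components
#'   only).
#' @param one_per_family Select one member per family before GREML?
#' @param greml_opts A [greml_control()].
#' @param twin_opts A [twin_control()].
#' @param seed Pipeline seed (family selection and any stage randomness).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input = NULL, k_sd = 3,
                       quantile_norm = TRUE, relatedness_threshold = 0.025,
                       relatedness_noise_z = 4,
                       r2_max = 0.2, ld_window = 50, ld_step = 5,
                       pca_k = 10, alpha = 0.05, add_sex_age = FALSE,
                       one_per_family = TRUE,
                       greml_opts = greml_control(),
                       twin_opts = twin_control(), seed = 1) {
  structure(
    list(sim = sim, input = input, k_sd = k_sd,
         quantile_norm = quantile_norm,
         relatedness_threshold = relatedness_threshold,
         relatedness_noise_z = relatedness_noise_z, r2_max = r2_max,
         ld_window = ld_window, ld_step = ld_step, pca_k = pca_k,
         alpha = alpha, add_sex_age = add_sex_age,
         one_per_family = one_per_family, greml_opts = greml_opts,
         twin_opts = twin_opts, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Nested keys mirror the arguments of [run_config()] and [sim_config()];
#' 2x2 matrices are written as two-row nested lists.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim)
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the end-to-end pleiotropy workflow
#'
#' Simulates (or ingests) a cohort, preprocesses the paired traits, builds
#' the GRM, prunes relatives, LD-prunes, computes ancestry axes with
#' Tracy-Widom selection, fits the bivariate GREML model on one member per
#' family with the selected axes as covariates, fits the bivariate Cholesky
#' ACE model to the twin pairs, and writes report tables:
#' `table1.tsv` (genetic correlation, DNA-based vs twin), `table2.tsv`
#' (full GREML component set), `table3.tsv` (standardized twin components),
#' plus `run.json` metadata and `run.log`.
#'
#' @param config A [run_config()] (or path to its YAML form).
#' @param out_dir Output directory (created if needed).
#' @return A `pleiokit_report`: list with the three tables, both fits, the
#'   PCA result and the metadata, invisibly. Stage failures abort with the
#'   stage name; outputs produced before the failure remain on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = log_path,
        append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      log_line("stage %s: FAILED (%s)", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$input)) {
      inp <- config$input
      geno <- if (!is.null(inp$vcf)) read_vcf(inp$vcf) else read_plink(inp$plink)
      p1 <- read_phen(inp$phen1); p2 <- read_phen(inp$phen2)
      phen <- dplyr::full_join(
        dplyr::rename(p1, trait1 = "value"),
        dplyr::rename(p2, trait2 = "value"), by = c("fid", "iid"))
      if (!is.null(inp$covar)) {
        phen <- dplyr::left_join(phen, read_covar(inp$covar),
                                 by = c("fid", "iid"))
      }
      twins <- if (!is.null(inp$twins)) read_twins(inp$twins)
      list(geno = geno, phen = phen, twins = twins)
    } else {
      simulate_cohort(config$sim)
    }
  })

  phen <- stage("preprocess", {
    covs <- intersect(c("sex", "age"), names(cohort$phen))
    preprocess_phenotypes(cohort$phen, traits = c("trait1", "trait2"),
                          covariates = covs, k_sd = config$k_sd,
                          quantile_norm = config$quantile_norm)
  })

  if (config$one_per_family) {
    phen <- stage("one_per_family",
                  select_one_per_family(phen, "fid", seed = config$seed + 7L))
  }

  grm_all <- stage("grm", {
    g <- compute_grm(geno_subset_individuals(cohort$geno, phen$iid))
    write_grm(g, file.path(out_dir, "cohort"))
    g
  })

  unrelated <- stage("relatedness_pruning", {
    m_snp <- min(grm_all$n_snp)
    thr <- config$relatedness_threshold
    floor_thr <- (config$relatedness_noise_z %||% 0) / sqrt(m_snp)
    if (floor_thr > thr) {
      warn(sprintf(paste0(
        "relatedness cutoff %.3f is below the GRM sampling noise for %d ",
        "SNPs; using %.3f"), thr, m_snp, floor_thr))
      thr <- floor_thr
    }
    prune_related(grm_all, thr)
  })
  log_line("retained %d of %d individuals after relatedness pruning",
           length(unrelated), length(grm_all$ids))
  grm_u <- grm_subset(grm_all, unrelated)
  phen <- phen[phen$iid %in% unrelated, , drop = FALSE]

  pca <- stage("pca", {
    geno_u <- geno_subset_individuals(cohort$geno, unrelated)
    kept_snps <- ld_prune(geno_u, config$r2_max, config$ld_window,
                          config$ld_step)
    log_line("LD pruning kept %d of %d SNPs", length(kept_snps),
             ncol(cohort$geno$dosage))
    pca_axes(geno_subset(geno_u, kept_snps), k = config$pca_k,
             alpha = config$alpha)
  })
  log_line("Tracy-Widom selected %d axes at alpha %.2f",
           length(pca$selected), config$alpha)

  gfit <- stage("greml", {
    covars <- character(0)
    if (length(pca$selected)) {
      pcs <- pca$loadings[, pca$selected, drop = FALSE]
      phen <- dplyr::left_join(
        phen, tibble(iid = rownames(pcs), as_tibble(pcs)), by = "iid")
      covars <- colnames(pcs)
    }
    if (config$add_sex_age) {
      covars <- c(covars, intersect(c("sex", "age"), names(phen)))
    }
    greml(phen, grm_u, traits = c("trait1", "trait2"),
          covariates = covars, control = config$greml_opts)
  })

  tfit <- if (!is.null(cohort$twins)) {
    stage("twin_fit", fit_twin_cholesky(cohort$twins,
                                        control = config$twin_opts))
  }

  report <- stage("report", {
    rg <- genetic_correlation(gfit)
    tw_rg <- if (!is.null(tfit)) component_correlations(tfit)[1, ]
    table1 <- tibble(
      comparison = "trait1 vs trait2",
      rG_dna = rg$estimate, rG_dna_se = rg$std.error,
      rG_twin = if (!is.null(tfit)) tw_rg$estimate else NA_real_,
      rG_twin_se = if (!is.null(tfit)) tw_rg$std.error else NA_real_
    )
    table2 <- tidy(gfit)
    table2$n <- gfit$n
    table3 <- if (!is.null(tfit)) {
      t3 <- tidy(tfit)
      t3$n_pairs <- tfit$n_complete
      t3
    }
    for (nm in c("table1", "table2", "table3")) {
      tb <- get(nm)
      if (!is.null(tb)) {
        write.table(as.data.frame(tb), file.path(out_dir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    meta <- list(
      seed = config$seed,
      config = rapply(unclass(config), unclass, how = "replace"),
      n_greml = gfit$n, pca_axes_selected = pca$selected,
      greml = list(logL = gfit$logL, iterations = gfit$iterations),
      twin = if (!is.null(tfit)) list(minus2lnL = tfit$minus2lnL,
                                      model = tfit$model),
      r_version = as.character(getRversion())
    )
    jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    list(table1 = table1, table2 = table2, table3 = table3)
  })
  log_line("pipeline complete")

  invisible(structure(
    c(report, list(greml_fit = gfit, twin_fit = tfit, pca = pca,
                   out_dir = out_dir)),
    class = "pleiokit_report"
  ))
}

#' Internal-consistency checks on a report
#'
#' Verifies, to a rounding tolerance, the ratio identities among reported
#' columns: `Vp = V(G) + V(e)` per trait, `h2 = V(G)/Vp`,
#' `r_G = C(G)/sqrt(V(G)1 V(G)2)` and `r_E = C(e)/sqrt(V(e)1 V(e)2)` on the
#' DNA-based table, and on the twin table the per-trait standardized
#' components summing to 1 plus the corresponding correlation identities.
#'
#' @param report A `pleiokit_report` (or a list with `table2` / `table3`
#'   tibbles in the same layout).
#' @param tol Tolerance (default 0.02, matching 2-dp rounded reporting).
#' @return Tibble with `check`, `discrepancy`, `pass`.
#' @export
check_table_consistency <- function(report, tol = 0.02) {
  checks <- list()
  add <- function(name, discrepancy) {
    checks[[length(checks) + 1L]] <<- tibble(
      check = name, discrepancy = abs(discrepancy),
      pass = abs(discrepancy) <= tol
    )
  }
  t2 <- report$table2
  if (!is.null(t2)) {
    g <- function(term) t2$estimate[match(term, t2$term)]
    add("gcta: Vp_tr1 = V(G)+V(e)", g("Vp_tr1") - g("V(G)_tr1") - g("V(e)_tr1"))
    add("gcta: Vp_tr2 = V(G)+V(e)", g("Vp_tr2") - g("V(G)_tr2") - g("V(e)_tr2"))
    add("gcta: h2_tr1 ratio", g("V(G)/Vp_tr1") - g("V(G)_tr1") / g("Vp_tr1"))
    add("gcta: h2_tr2 ratio", g("V(G)/Vp_tr2") - g("V(G)_tr2") / g("Vp_tr2"))
    add("gcta: r_G identity",
        g("r_G") - g("C(G)_tr12") / sqrt(g("V(G)_tr1") * g("V(G)_tr2")))
    add("gcta: r_E identity",
        g("r_E") - g("C(e)_tr12") / sqrt(g("V(e)_tr1") * g("V(e)_tr2")))
  }
  t3 <- report$table3
  if (!is.null(t3)) {
    d <- function(term) t3$estimate[match(term, t3$term)]
    add("twin: shares tr1 sum to 1",
        d("VG_tr1") + d("VC_tr1") + d("VE_tr1") - 1)
    add("twin: shares tr2 sum to 1",
        d("VG_tr2") + d("VC_tr2") + d("VE_tr2") - 1)
    add("twin: r_G identity",
        d("r_G") - d("CG_tr12") / sqrt(d("VG_tr1") * d("VG_tr2")))
    add("twin: covariance split sums to r_P",
        d("CG_tr12") + d("CC_tr12") + d("CE_tr12") - d("r_P"))
  }
  dplyr::bind_rows(checks)
}
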