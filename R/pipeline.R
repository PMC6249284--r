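#' Default end-to-end run configuration
#'
#' Desk-scale defaults: a 600-subject behavioral cohort, a 2,000-SNP
#' stratification panel, and a 20-subject imaging arm on a 14 x 16 x 14
#' voxel grid with two 120-volume runs. All stage seeds derive from the one
#' root seed. The configuration round-trips through YAML.
#'
#' @param seed root seed.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_subjects = 600, missing_rate = 0.015),
    snp = list(n_snps = 2000, n_per_population = c(300, 300), fst = 0.1,
               n_x_snps = 50),
    phenotype = list(bands = "default"),
    association = list(m = 15, n_iter = 10,
                       predictors = c("age", "sex", "vocabulary", "ses",
                                      "spanish_home", "bilingual",
                                      "maternal_education",
                                      "carrier_ru2short"),
                       n_pcs = 10),
    imaging = list(n_subjects = 20, grid_shape = c(14, 16, 14),
                   n_volumes_per_run = 120, n_runs = 2,
                   pheno_corr_slope = -0.12,
                   voxel_p = 0.001, cluster_p = 0.05, cluster_iters = 200,
                   network_p = 1e-6, min_sep_mm = 18, sphere_radius_mm = 6,
                   move_thresh = 0.3, outlier_thresh = 0.10,
                   min_retention = 0.60, alpha_select = 0.05)
  ), class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML path.
#' @return `load_run_config` returns the `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the gene-brain-behavior pipeline end-to-end on synthetic data
#'
#' Stages: `simulate` (cohort, genotypes, SNP panel), `phenotype`
#' (residualization and group bands), `genetics` (carrier status,
#' contingency test, stratification PCA and inflation check), `associate`
#' (multinomial model with imputation pooling and sensitivity analyses),
#' `imaging` (BOLD generation, motion QC, nuisance regression, ICD maps,
#' cluster-corrected voxelwise inference, seed network, node regressions).
#' Later stages require the earlier ones; any subset prefix can be run.
#'
#' @param config a [default_run_config()].
#' @param stages character vector of stage names to run (prefix order
#'   enforced).
#' @return List with one entry per executed stage plus `manifest` (config
#'   hash, root seed, per-stage sizes).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "phenotype", "genetics",
                                    "associate", "imaging")) {
  all_stages <- c("simulate", "phenotype", "genetics", "associate",
                  "imaging")
  stages <- all_stages[all_stages %in% stages]
  res <- list()
  manifest <- list(config_hash = object_hash(unclass(config)),
                   seed = config$seed, stages = stages)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    res$simulate <- run_stage("simulate", {
      cs <- cohort_spec(n_subjects = config$cohort$n_subjects,
                        missing_rate = config$cohort$missing_rate,
                        seed = derive_seed(config$seed, "cohort"))
      sim <- generate_cohort(cs)
      ss <- snp_spec(n_snps = config$snp$n_snps,
                     n_per_population = rep(ceiling(
                       cs$n_subjects / length(config$snp$n_per_population)),
                       length(config$snp$n_per_population))[
                         seq_along(config$snp$n_per_population)],
                     fst = config$snp$fst, n_x_snps = config$snp$n_x_snps,
                     seed = derive_seed(config$seed, "snp"))
      # align panel size to the cohort
      ss$n_per_population <- diff(round(seq(0, cs$n_subjects,
                                            length.out =
                                              length(ss$n_per_population) + 1)))
      gm <- generate_snp_matrix(ss)
      gm$sex <- sim$cohort$sex  # reported sex comes from the cohort table
      list(spec = cs, cohort = sim$cohort, genotypes = sim$genotypes,
           snp = gm)
    })
    manifest$n_subjects <- nrow(res$simulate$cohort)
  }

  if ("phenotype" %in% stages) {
    res$phenotype <- run_stage("phenotype", {
      rm_fit <- fit_residual_model(res$simulate$cohort)
      labels <- classify_groups(rm_fit$z, bands = config$phenotype$bands)
      cohort <- res$simulate$cohort
      cohort$resid_z <- rm_fit$z
      cohort$group_fitted <- labels
      list(model = rm_fit, cohort = cohort)
    })
  }

  if ("genetics" %in% stages) {
    res$genetics <- run_stage("genetics", {
      carrier <- carrier_status_table(res$simulate$genotypes)
      cohort <- res$phenotype$cohort
      cohort$carrier_called <- carrier
      ct <- carrier_contingency(cohort$group, carrier)
      chi <- chi_square_independence(ct)
      qc1 <- snp_qc(res$simulate$snp)
      qc2 <- sample_qc(qc1$gm)
      pca <- eigenstrat_pca(qc2$gm, k = config$association$n_pcs)
      pcs <- matrix(NA_real_, nrow(cohort), ncol(pca$components))
      keep_rows <- match(rownames(pca$components),
                         rownames(res$simulate$snp$dosage))
      pcs[keep_rows, ] <- pca$components
      colnames(pcs) <- colnames(pca$components)
      cohort <- cbind(cohort, pcs)
      lambda <- genomic_inflation(
        trend_scan(qc2$gm, cohort$resid_z[keep_rows],
                   covariates = pca$components))
      list(cohort = cohort, contingency = ct, chi_square = chi,
           snp_qc = qc1$report, sample_qc = qc2$report, pca = pca,
           lambda = lambda)
    })
    manifest$chi_square <- res$genetics$chi_square$chisq
    manifest$lambda <- res$genetics$lambda
  }

  if ("associate" %in% stages) {
    res$associate <- run_stage("associate", {
      cohort <- res$genetics$cohort
      preds <- c(config$association$predictors,
                 paste0("PC", seq_len(config$association$n_pcs)))
      dat <- cohort[!is.na(cohort$carrier_called), ]
      dat$carrier_ru2short <- as.numeric(dat$carrier_called)
      dat <- dat[stats::complete.cases(
        dat[, paste0("PC", seq_len(config$association$n_pcs))]), ]
      pooled <- impute_and_pool(dat, outcome = "group", predictors = preds,
                                m = config$association$m,
                                n_iter = config$association$n_iter,
                                seed = derive_seed(config$seed, "impute"))
      sens <- lapply(c("reclassify", "linear", "exclude_bilingual",
                       "exclude_spanish_home"), function(md) {
        cc <- dat[stats::complete.cases(dat[, preds]), ]
        sensitivity_suite(cc, md, predictors = preds)
      })
      names(sens) <- c("reclassify", "linear", "exclude_bilingual",
                       "exclude_spanish_home")
      list(pooled = pooled, sensitivity = sens, data = dat)
    })
    manifest$m_imputations <- res$associate$pooled$m
  }

  if ("imaging" %in% stages) {
    res$imaging <- run_stage("imaging", {
      run_imaging_stage(config, res)
    })
    manifest$n_imaging_retained <- res$imaging$n_retained
  }

  res$manifest <- manifest
  res
}

# imaging arm: subjects are drawn from the cohort, BOLD is generated and
# reduced subject-by-subject, then group inference runs on the stored maps
run_imaging_stage <- function(config, res) {
  ic <- config$imaging
  cohort <- res$genetics$cohort
  eligible <- which(!is.na(cohort$carrier_called) &
                      !is.na(cohort$resid_z) & !is.na(cohort$PC1))
  set.seed(derive_seed(config$seed, "imaging_sample"))
  pick <- sample(eligible, min(ic$n_subjects, length(eligible)))
  sub <- cohort[pick, ]
  spec <- bold_spec(grid_shape = ic$grid_shape,
                    n_volumes_per_run = ic$n_volumes_per_run,
                    n_runs = ic$n_runs,
                    pheno_corr_slope = ic$pheno_corr_slope,
                    seed = derive_seed(config$seed, "bold"))
  grid <- spec$grid
  masks <- bold_masks(spec)
  gm_idx <- which(masks$gm)
  brain <- masks$gm | masks$wm | masks$vent

  alpha_maps <- list(); resid_runs <- list(); qc <- list()
  kept <- logical(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    bold <- generate_bold_subject(
      spec, sub$carrier_called[i], sub$resid_z[i],
      seed = derive_seed(config$seed, paste0("bold_subj", i)))
    outl <- lapply(bold$runs, outlier_fraction, mask = brain)
    cm <- censor(bold$motion, outl, move_thresh = ic$move_thresh,
                 outlier_thresh = ic$outlier_thresh,
                 min_retention = ic$min_retention)
    qc[[i]] <- list(retention = cm$retention, excluded = cm$excluded,
                    n_censored = cm$n_censored)
    if (cm$excluded) next
    resid <- do.call(cbind, lapply(seq_along(bold$runs), function(rr) {
      pd <- bold$runs[[rr]][, -(1:6), drop = FALSE]
      tr_pd <- bold$motion[[rr]][-(1:6), , drop = FALSE]
      nuisance_regress(pd, tr_pd, cm$keep[[rr]], masks$wm, masks$vent,
                       spec$tr_s)
    }))
    icd <- icd_subject(resid, masks$gm)
    am <- icd$alpha
    am[is.na(am) & masks$gm] <- stats::median(am[masks$gm], na.rm = TRUE)
    alpha_maps[[i]] <- smooth_map(am, 6, grid$voxel_mm, masks$gm)
    resid_runs[[i]] <- resid
    kept[i] <- TRUE
  }
  sub_k <- sub[kept, ]
  alpha_maps <- alpha_maps[kept]
  resid_runs <- resid_runs[kept]

  design <- data.frame(resid_z = sub_k$resid_z,
                       sex = as.numeric(sub_k$sex == "female"),
                       medu = sub_k$maternal_education, ses = sub_k$ses,
                       PC1 = sub_k$PC1, PC2 = sub_k$PC2, PC3 = sub_k$PC3)
  design$medu[is.na(design$medu)] <- mean(design$medu, na.rm = TRUE)
  design$ses[is.na(design$ses)] <- 0
  vw <- voxelwise_model(alpha_maps, design, focal = "resid_z",
                        covariates = c("sex", "medu", "ses",
                                       "PC1", "PC2", "PC3"),
                        mask = masks$gm)
  cl <- cluster_correct(vw, grid, voxel_p = ic$voxel_p,
                        cluster_p = ic$cluster_p, iters = ic$cluster_iters)
  seed_voxels <- NULL
  network <- NULL
  node_models <- NULL
  nodes <- NULL
  seed_corrected <- FALSE
  comps <- connected_components(
    !is.na(vw$t) & abs(vw$t) > stats::qt(1 - ic$voxel_p / 2, vw$df) &
      masks$gm)
  if (nrow(cl$clusters) > 0) {
    top <- which.max(abs(cl$clusters$peak_t))
    seed_voxels <- comps[[which(vapply(
      comps, function(ix) cl$clusters$peak_index[top] %in% ix,
      logical(1)))[1]]]
    seed_corrected <- TRUE
  } else if (length(comps) > 0) {
    # no cluster survives correction at desk scale: fall back to the
    # largest supra-threshold cluster, flagged as exploratory
    seed_voxels <- comps[[1]]
  }
  if (!is.null(seed_voxels)) {
    z_maps <- do.call(rbind, lapply(resid_runs, function(rr) {
      seed_corr_map(rr, seed_voxels)$z
    }))
    gn <- group_network(z_maps[, gm_idx, drop = FALSE], ic$network_p,
                        mask = masks$gm)
    pk <- find_peaks(gn$t, gn$network, grid, min_sep_mm = ic$min_sep_mm)
    if (nrow(pk) > 0) {
      nodes <- node_set(pk, grid, radius_mm = ic$sphere_radius_mm)
      nv <- node_values(z_maps, nodes)
      pool <- c("age", "piq", "sex", "medu", "ses", "PC1", "PC2", "PC3")
      covdat <- data.frame(age = sub_k$age, piq = sub_k$piq,
                           sex = design$sex, medu = design$medu,
                           ses = design$ses, PC1 = design$PC1,
                           PC2 = design$PC2, PC3 = design$PC3)
      node_models <- lapply(seq_len(ncol(nv)), function(j) {
        keep_cov <- backward_select(nv[, j], covdat, pool,
                                    alpha = ic$alpha_select)
        node_regression(nv[, j], sub_k$carrier_called, covdat, keep_cov)
      })
      names(node_models) <- nodes$nodes$label
      network <- gn
    }
  }
  list(spec = spec, qc = qc, n_retained = sum(kept), subjects = sub_k,
       voxelwise = vw, clusters = cl, seed_voxels = seed_voxels,
       seed_corrected = seed_corrected, network = network, nodes = nodes,
       node_models = node_models)
}
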