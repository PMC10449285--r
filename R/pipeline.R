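# Config-driven end-to-end orchestration: simulate (or read) ->
# genotype QC -> unconditional/conditional/pairwise lipid models ->
# disease models -> mediation -> cross-cohort meta-analysis, with a
# deterministic output layout and a machine-readable manifest.

#' Pipeline configuration
#'
#' @param sim a [sim_config] used when no input paths are given.
#' @param pheno_paths,geno_paths optional per-cohort file paths (same
#'   length); when supplied, data are read instead of simulated.
#' @param snps SNP ids to analyse (`NULL` = all SNPs in the genotype
#'   data; an empty character vector yields empty result tables).
#' @param coding genotype coding for the lipid/disease models.
#' @param lipids lipid outcomes to model.
#' @param diseases disease suffixes to model (`NULL` = all simulated).
#' @param mediators lipid mediators for the mediation stage.
#' @param covariates_lipid,covariates_disease adjustment sets.
#' @param estimator mediation estimator.
#' @param n_boot bootstrap replicates for mediation.
#' @param alpha,n_tests multiplicity settings; the significance threshold
#'   `alpha/n_tests` is recorded in the manifest.
#' @param seed integer seed governing simulation and bootstrap.
#' @return A classed list (`pipeline_config`).
#' @export
pipeline_config <- function(sim = sim_config(),
                            pheno_paths = NULL, geno_paths = NULL,
                            snps = NULL, coding = "additive",
                            lipids = c("TG", "HDL_C", "LDL_C", "TC"),
                            diseases = NULL,
                            mediators = c("TG", "HDL_C"),
                            covariates_lipid = c("sex", "birth_year",
                                                 "site", "exam_age"),
                            covariates_disease = c("sex", "birth_year",
                                                   "site"),
                            estimator = "product",
                            n_boot = 200, alpha = 0.05, n_tests = 28,
                            seed = 42L) {
  if (xor(is.null(pheno_paths), is.null(geno_paths)))
    stop("pheno_paths and geno_paths must be given together")
  if (!is.null(pheno_paths) && length(pheno_paths) != length(geno_paths))
    stop("pheno_paths and geno_paths must have the same length")
  structure(list(sim = sim, pheno_paths = pheno_paths,
                 geno_paths = geno_paths, snps = snps, coding = coding,
                 lipids = lipids, diseases = diseases,
                 mediators = mediators,
                 covariates_lipid = covariates_lipid,
                 covariates_disease = covariates_disease,
                 estimator = estimator, n_boot = as.integer(n_boot),
                 alpha = alpha, n_tests = as.integer(n_tests),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

assoc_row <- function(cohort, analysis, outcome, covariate_set, res,
                      exposure = res$term) {
  data.frame(cohort = cohort, analysis = analysis, outcome = outcome,
             exposure = exposure, covariate_set = covariate_set,
             beta = res$beta, se = res$se, p = res$p,
             n_persons = res$n_persons, n_obs = res$n_obs,
             n_events = res$n_events, stringsAsFactors = FALSE)
}

empty_assoc <- function() {
  data.frame(cohort = character(), analysis = character(),
             outcome = character(), exposure = character(),
             covariate_set = character(), beta = numeric(),
             se = numeric(), p = numeric(), n_persons = integer(),
             n_obs = integer(), n_events = integer(),
             stringsAsFactors = FALSE)
}

meta_over_cohorts <- function(rows) {
  if (!nrow(rows)) return(rows)
  key <- interaction(rows$analysis, rows$outcome, rows$exposure,
                     rows$covariate_set, drop = TRUE)
  out <- lapply(split(rows, key), function(g) {
    if (nrow(g) < 1) return(NULL)
    mr <- fixed_effect_meta(g$beta, g$se, labels = g$cohort)
    data.frame(cohort = "META", analysis = g$analysis[1],
               outcome = g$outcome[1], exposure = g$exposure[1],
               covariate_set = g$covariate_set[1],
               beta = mr$beta_meta, se = mr$se_meta, p = mr$p,
               n_persons = sum(g$n_persons), n_obs = sum(g$n_obs),
               n_events = if (all(is.na(g$n_events))) NA_integer_
                 else sum(g$n_events, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$analysis, out$outcome, out$exposure, out$covariate_set), ]
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) multi-cohort data, then per cohort: genotype QC
#' with tag-set assignment; for each SNP the 16 unconditional/conditional
#' lipid models (4 outcomes x \{basic, +each other lipid\}); pairwise-SNP
#' models for every unordered SNP pair and lipid outcome; univariate Cox
#' disease models; mediation models for each SNP x mediator x disease.
#' Results are meta-analysed across cohorts (rows tagged
#' `cohort = "META"`), attenuation percentages are derived from the
#' meta-level conditional models, and everything is written as TSV plus
#' a JSON manifest when `out_dir` is given.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with data.frames `qc`, `assoc_lipids`,
#'   `assoc_disease`, `mediation`, `attenuation` and the `manifest` list.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "input"
  result <- tryCatch({
    # ---- stage: data ----
    if (is.null(config$pheno_paths)) {
      say("stage simulate: ", config$sim$n_cohorts, " cohorts x ",
          config$sim$n_per_cohort, " persons (seed ", config$sim$seed, ")")
      cohorts <- simulate_multicohort(config$sim)
    } else {
      say("stage read: ", length(config$pheno_paths), " cohorts")
      cohorts <- mapply(function(p, g) {
        ph <- read_phenotypes(p)
        list(pheno = ph, geno = read_genotypes(g))
      }, config$pheno_paths, config$geno_paths, SIMPLIFY = FALSE)
      names(cohorts) <- vapply(cohorts, function(co)
        co$pheno$cohort_id[1], "")
    }
    snps <- config$snps
    if (is.null(snps)) snps <- cohorts[[1]]$geno$snp_ids
    diseases <- config$diseases
    if (is.null(diseases))
      diseases <- sub("^event_ind_", "",
                      grep("^event_ind_", names(cohorts[[1]]$pheno),
                           value = TRUE))

    # ---- stage: QC ----
    stage <- "qc"
    qc_all <- empty_qc <- data.frame()
    for (k in seq_along(cohorts)) {
      gm <- cohorts[[k]]$geno
      qc <- snp_qc(gm)
      qc <- qc[qc$snp_id %in% snps, , drop = FALSE]
      if (nrow(qc)) {
        if (length(snps) > 1) {
          sets <- select_tag_sets(ld_matrix(
            genotype_matrix(gm$dosages[, snps, drop = FALSE],
                            gm$person_ids, snps)))
          set_id <- integer(nrow(qc))
          for (j in seq_along(sets))
            set_id[qc$snp_id %in% sets[[j]]] <- j
        } else set_id <- rep(1L, nrow(qc))
        qc <- cbind(cohort = names(cohorts)[k], qc, set_id = set_id)
        for (i in seq_len(nrow(qc))) {
          if (!isTRUE(qc$hwe_pass[i]))
            say(sprintf("warning: %s fails HWE filter in %s (p = %.3g)",
                        qc$snp_id[i], qc$cohort[i], qc$hwe_p[i]))
          if (!isTRUE(qc$maf_pass[i]))
            say(sprintf("warning: %s below MAF filter in %s (%.3f)",
                        qc$snp_id[i], qc$cohort[i], qc$maf[i]))
        }
        qc_all <- rbind(qc_all, qc)
      }
    }
    say("stage qc: ", nrow(qc_all), " SNP-cohort rows")

    # ---- stage: lipid associations ----
    stage <- "assoc_lipids"
    lip_rows <- empty_assoc()
    for (k in seq_along(cohorts)) {
      co <- cohorts[[k]]; cname <- names(cohorts)[k]
      for (s in snps) {
        for (y in config$lipids) {
          for (adj in c(list(NULL), as.list(setdiff(config$lipids, y)))) {
            res <- fit_linear_longitudinal(
              co$pheno, co$geno, outcome = y, snp = s,
              coding = config$coding,
              covariates = config$covariates_lipid, adjust_for = adj)
            lip_rows <- rbind(lip_rows, assoc_row(
              cname,
              if (is.null(adj)) "unconditional" else "conditional", y,
              if (is.null(adj)) "basic" else paste0("basic+", adj), res))
          }
        }
      }
      if (length(snps) > 1) {
        prs <- utils::combn(sort(snps), 2, simplify = FALSE)
        for (pr in prs) for (y in config$lipids) {
          res1 <- fit_linear_longitudinal(
            co$pheno, co$geno, outcome = y, snp = pr[1],
            coding = config$coding,
            covariates = config$covariates_lipid, other_snps = pr[2])
          tab <- attr(res1, "coefficients")
          for (s in pr) {
            lip_rows <- rbind(lip_rows, assoc_row(
              cname, "pairwise", y,
              paste0("basic+", setdiff(pr, s)),
              new_assoc_result(s, tab$beta[tab$term == s],
                               tab$se[tab$term == s],
                               res1$n_persons, res1$n_obs,
                               model_desc = res1$model_desc),
              exposure = s))
          }
        }
      }
    }
    say("stage assoc_lipids: ", nrow(lip_rows), " rows")

    # ---- stage: disease models ----
    stage <- "assoc_disease"
    dz_rows <- empty_assoc()
    for (k in seq_along(cohorts)) {
      co <- cohorts[[k]]; cname <- names(cohorts)[k]
      for (s in snps) for (d in diseases) {
        res <- fit_cox(co$pheno, co$geno, outcome = d, snp = s,
                       coding = config$coding,
                       covariates = config$covariates_disease)
        dz_rows <- rbind(dz_rows,
                         assoc_row(cname, "disease", d, "basic", res))
      }
    }
    say("stage assoc_disease: ", nrow(dz_rows), " rows")

    # ---- stage: mediation ----
    stage <- "mediation"
    med_rows <- data.frame()
    for (k in seq_along(cohorts)) {
      co <- cohorts[[k]]; cname <- names(cohorts)[k]
      for (s in snps) for (mm in config$mediators) for (d in diseases) {
        mr <- mediate(co$pheno, co$geno, snp = s, mediator = mm,
                      outcome = d,
                      covariates = config$covariates_disease,
                      estimator = config$estimator,
                      n_boot = config$n_boot,
                      seed = (config$seed + 131L * k) %%
                        .Machine$integer.max)
        med_rows <- rbind(med_rows, data.frame(
          cohort = cname, snp = s, mediator = mm, outcome = d,
          estimator = mr$estimator,
          beta_TE = mr$beta_TE, beta_DE = mr$beta_DE,
          beta_IE = mr$beta_IE, se_TE = mr$se_TE, se_DE = mr$se_DE,
          se_IE = mr$se_IE,
          ci_IE_lo = mr$ci95_IE[1], ci_IE_hi = mr$ci95_IE[2],
          p_IE = mr$p_IE, prop_mediated = mr$prop_mediated,
          n = mr$n, n_events = mr$n_events, n_boot = mr$n_boot,
          stringsAsFactors = FALSE))
      }
    }
    say("stage mediation: ", nrow(med_rows), " rows")

    # ---- stage: meta ----
    stage <- "meta"
    assoc_all <- rbind(lip_rows, dz_rows)
    meta_rows <- meta_over_cohorts(assoc_all)
    med_meta <- data.frame()
    if (nrow(med_rows)) {
      key <- interaction(med_rows$snp, med_rows$mediator,
                         med_rows$outcome, drop = TRUE)
      med_meta <- do.call(rbind, lapply(split(med_rows, key), function(g) {
        mi <- fixed_effect_meta(g$beta_IE, g$se_IE, labels = g$cohort)
        mt <- fixed_effect_meta(g$beta_TE, g$se_TE, labels = g$cohort)
        md <- fixed_effect_meta(g$beta_DE, g$se_DE, labels = g$cohort)
        data.frame(cohort = "META", snp = g$snp[1],
                   mediator = g$mediator[1], outcome = g$outcome[1],
                   estimator = g$estimator[1],
                   beta_TE = mt$beta_meta, beta_DE = md$beta_meta,
                   beta_IE = mi$beta_meta, se_TE = mt$se_meta,
                   se_DE = md$se_meta, se_IE = mi$se_meta,
                   ci_IE_lo = mi$ci95[1], ci_IE_hi = mi$ci95[2],
                   p_IE = mi$p,
                   prop_mediated = if (mt$beta_meta != 0)
                     100 * mi$beta_meta / mt$beta_meta else NA_real_,
                   n = sum(g$n), n_events = sum(g$n_events),
                   n_boot = g$n_boot[1], stringsAsFactors = FALSE)
      }))
    }
    say("stage meta: ", nrow(meta_rows) + nrow(med_meta), " rows")

    # ---- stage: attenuation summary ----
    stage <- "attenuation"
    att_rows <- data.frame()
    if (nrow(meta_rows)) {
      mcond <- meta_rows[meta_rows$analysis == "conditional", ]
      muncd <- meta_rows[meta_rows$analysis == "unconditional", ]
      for (i in seq_len(nrow(mcond))) {
        base <- muncd[muncd$outcome == mcond$outcome[i] &
                        muncd$exposure == mcond$exposure[i], ]
        if (nrow(base) == 1 && base$beta != 0) {
          att <- conditional_attenuation(base$beta, mcond$beta[i])
          att_rows <- rbind(att_rows, data.frame(
            exposure = mcond$exposure[i], outcome = mcond$outcome[i],
            adjusted_by = sub("^basic\\+", "", mcond$covariate_set[i]),
            beta_unadj = base$beta, beta_adj = mcond$beta[i],
            attenuation_pct = att$percent,
            attenuation_raw = att$percent_raw,
            stringsAsFactors = FALSE))
        }
      }
    }

    manifest <- list(
      package = "lipmed",
      version = as.character(utils::packageVersion("lipmed")),
      seed = config$seed,
      n_cohorts = length(cohorts),
      snps = snps, diseases = diseases,
      p_mt = bonferroni_threshold(config$alpha, config$n_tests),
      n_tests = config$n_tests,
      rows = list(qc = nrow(qc_all), assoc_lipids = nrow(lip_rows),
                  assoc_disease = nrow(dz_rows),
                  mediation = nrow(med_rows),
                  meta = nrow(meta_rows) + nrow(med_meta)))

    out <- list(qc = qc_all,
                assoc_lipids = lip_rows,
                assoc_disease = dz_rows,
                assoc_meta = meta_rows,
                mediation = med_rows,
                mediation_meta = med_meta,
                attenuation = att_rows,
                manifest = manifest)
    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in c("qc", "assoc_lipids", "assoc_disease", "assoc_meta",
                   "mediation", "mediation_meta", "attenuation"))
        write_results(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
      jsonlite::write_json(manifest,
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      say("stage write: outputs in ", out_dir)
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Build configurations from a YAML or JSON file
#'
#' Reads a configuration file mirroring the [sim_config] and
#' [pipeline_config] arguments.  Keys under `sim:` go to [sim_config]
#' (matrix-valued settings — `ld_targets`, `lipid_corr`,
#' `snp_lipid_betas` — may be written as lists of rows); all other
#' recognised keys go to [pipeline_config].
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return A [pipeline_config].
#' @export
config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim
  if (!is.null(sim_args)) {
    for (mkey in c("ld_targets", "lipid_corr", "snp_lipid_betas")) {
      if (!is.null(sim_args[[mkey]]) && !is.matrix(sim_args[[mkey]]))
        sim_args[[mkey]] <- do.call(rbind, sim_args[[mkey]])
    }
    for (vkey in c("mafs", "lipid_means", "lipid_sds",
                   "lipid_sex_effects", "lipid_age_slopes"))
      if (!is.null(sim_args[[vkey]]))
        sim_args[[vkey]] <- unlist(sim_args[[vkey]])
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) stop("unknown sim config key(s): ",
                          paste(bad, collapse = ", "))
    sim <- do.call(sim_config, sim_args)
  } else sim <- sim_config()
  pipe_args <- raw[setdiff(names(raw), "sim")]
  bad <- setdiff(names(pipe_args), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown pipeline config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipeline_config, c(list(sim = sim), pipe_args))
}
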