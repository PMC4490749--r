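# Study orchestration: phantom imaging -> morphometry -> cross simulation ->
# QTL mapping from one configuration (R list or YAML file), with provenance
# (manifest, log, deterministic reruns from the master seed).

#' Load and validate a study configuration
#'
#' @param config A named list, or the path of a YAML file containing one.
#' @return The validated configuration list.
#' @export
study_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  if (is.null(config$seed)) abort("`seed` is mandatory in a study configuration")
  if (is.null(config$out_dir)) abort("`out_dir` is mandatory in a study configuration")
  if (!is.null(config$cross) && !is.null(config$cross$file) &&
      (!is.null(config$cross$n_f2) || !is.null(config$cross$qtl))) {
    abort("cross stage: give either `file` or simulation parameters, not both")
  }
  config
}

#' Run a reproducible phantom-to-QTL study
#'
#' Executes the configured stages: (1) phantom generation, segmentation and
#' morphometry for `phantoms$n_specimens` synthetic specimens, writing a
#' phenotype CSV; (2) cross simulation (or reading a cross CSV), heritability
#' screening against the F1 cohort; (3) QTL mapping: genotype probabilities,
#' extended Haley-Knott scan with interactive sex covariate, permutation
#' threshold, penalties, penalized stepwise model search, position refinement
#' and support intervals. All randomness derives from the single master seed,
#' so re-running an identical configuration reproduces every output file.
#'
#' @param config A configuration list or YAML path (see [study_config()]).
#' @return Invisibly, a list of stage results and output paths.
#' @export
run_study <- function(config) {
  config <- study_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  t0 <- Sys.time()
  logit <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    inform(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  fail <- function(stage, e) {
    writeLines(sprintf("FAILED at stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  seed <- as.integer(config$seed)
  results <- list()
  timings <- list()
  stage <- function(name, code) {
    logit("stage %s: start", name)
    st <- Sys.time()
    r <- tryCatch(force(code), error = function(e) fail(name, e))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    logit("stage %s: done (%.1fs)", name, timings[[name]])
    r
  }

  # ---- imaging stage ------------------------------------------------------
  if (!is.null(config$phantoms)) {
    results$phenotypes <- stage("phantom+morphometry", {
      pc <- config$phantoms
      nspec <- pc$n_specimens %||% 1
      segp <- config$segmentation %||% list()
      morp <- config$morphometry %||% list()
      rows <- purrr::map_dfr(seq_len(nspec), function(i) {
        args <- pc$spec %||% list()
        args$seed <- derive_seed(seed, "phantom", i)
        vol <- generate_phantom(do.call(phantom_spec, args))
        seg <- segment_phases(vol, bone_threshold = segp$bone_threshold %||% "otsu")
        seg <- label_components(
          seg,
          lacuna_volume_range_um3 = segp$lacuna_volume_range_um3 %||%
            (c(50, 1000) * vol$voxel_size_um^3),
          min_canal_volume_um3 = segp$min_canal_volume_um3 %||%
            (1500 * vol$voxel_size_um^3)
        )
        assemble_phenotypes(
          seg, specimen = sprintf("specimen_%03d", i),
          k_neighbors = morp$k_neighbors %||% 6,
          n_theta_bins = morp$n_theta_bins %||% 360
        )
      })
      write_phenotype_csv(rows, file.path(out, "phenotypes.csv"))
      rows
    })
  }

  # ---- cross stage --------------------------------------------------------
  cross <- NULL
  if (!is.null(config$cross)) {
    cross <- stage("cross", {
      cc <- config$cross
      if (!is.null(cc$file)) {
        read_cross_csv(cc$file)
      } else {
        qtl <- if (!is.null(cc$qtl)) dplyr::bind_rows(lapply(cc$qtl, as_tibble))
        ints <- if (!is.null(cc$interactions)) {
          dplyr::bind_rows(lapply(cc$interactions, as_tibble))
        }
        cr <- simulate_cross(
          map = sim_genetic_map(), n_f2 = cc$n_f2 %||% 755,
          n_f1 = cc$n_f1 %||% 12, qtl = qtl, interactions = ints,
          sex_effect = cc$sex_effect %||% 0, env_sd = cc$env_sd %||% 1,
          p_male = cc$p_male %||% 0.47,
          missing_rate = cc$missing_rate %||% 0.02,
          seed = derive_seed(seed, "cross")
        )
        write_cross_csv(cr, file.path(out, "cross.csv"))
        if (length(cr$pheno_f1)) {
          write.csv(tibble(pheno = cr$pheno_f1),
                    file.path(out, "phenotypes_f1.csv"), row.names = FALSE)
        }
        cr
      }
    })
    if (length(cross$pheno_f1) >= 2) {
      results$heritability <- stage("heritability", {
        h <- select_phenotypes(
          tibble(pheno = cross$pheno_f1), tibble(pheno = cross$pheno_f2),
          criterion_percent = config$qtl$heritability_criterion %||% 40
        )
        write.csv(h, file.path(out, "heritability.csv"), row.names = FALSE)
        h
      })
    }
  }

  # ---- QTL stage ----------------------------------------------------------
  if (!is.null(cross) && !is.null(config$qtl)) {
    qc <- config$qtl
    results$qtl <- stage("qtl", {
      probs <- genotype_probabilities(cross, step_cM = qc$step_cM %||% 2)
      scan <- scan_one_ehk(probs, cross$pheno_f2, cross$sex,
                           mode = "interactive",
                           method = qc$scan_method %||% "ehk")
      write.csv(tidy(scan), file.path(out, "scan.csv"), row.names = FALSE)
      thr <- permutation_threshold(
        probs, cross$pheno_f2, cross$sex, n_perm = qc$n_perm %||% 100,
        alpha = qc$alpha %||% 0.05, seed = derive_seed(seed, "threshold"),
        method = qc$perm_method %||% "hk"
      )
      pen <- derive_penalties(
        probs, cross$pheno_f2, cross$sex, n_perm = qc$n_perm %||% 100,
        alpha = qc$alpha %||% 0.05, seed = derive_seed(seed, "penalties"),
        pair_step_cM = qc$pair_step_cM %||% 10
      )
      write.csv(
        tibble(T_main = pen$T_main, T_heavy = pen$T_heavy,
               T_light = pen$T_light, alpha = pen$alpha, n_perm = pen$n_perm,
               scaled_down = pen$scaled_down, threshold_single = as.numeric(thr)),
        file.path(out, "penalties.csv"), row.names = FALSE
      )
      model <- stepwise_model_search(probs, cross$pheno_f2, cross$sex, pen,
                                     max_qtl = qc$max_qtl %||% 10)
      if (nrow(model$loci) > 0 && isTRUE(qc$refine %||% TRUE)) {
        model <- refine_positions(model, cross, cross$pheno_f2, cross$sex,
                                  step_cM = qc$refine_step_cM %||% 0.1)
      }
      write.csv(tidy(model), file.path(out, "model.csv"), row.names = FALSE)
      if (nrow(model$loci) > 0) {
        ivs <- purrr::map_dfr(unique(model$loci$chr), function(ch) {
          lod_support_interval(scan, chr = ch)
        })
        write.csv(ivs, file.path(out, "support_intervals.csv"),
                  row.names = FALSE)
      }
      p <- autoplot(scan, threshold = thr)
      ggplot2::ggsave(file.path(out, "scan.png"), p,
                      width = 10, height = 3, dpi = 120)
      list(probs = probs, scan = scan, threshold = thr, penalties = pen,
           model = model)
    })
  }

  # ---- manifest -----------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("osteoqtl")),
    r_version = R.version.string,
    stages = names(timings),
    timings_sec = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logit("study complete (%.1fs total)",
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(c(results, list(out_dir = out, manifest = manifest)))
}
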