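#' Pipeline run configuration
#'
#' Bundles inputs, output directory and seed for the staged pipeline. When a
#' CSV input is not supplied, the corresponding synthetic generator supplies
#' the data (seeded, hence reproducible).
#'
#' @param out_dir output directory for report CSVs (created if absent).
#' @param seed integer master seed.
#' @param synthetic a [synthetic_config]; defaults to
#'   `synthetic_config(seed)`.
#' @param spectra_csv optional long-format spectra CSV whose `spectrum_id`
#'   encodes `fish|state|patch` (pipe-separated).
#' @param dyads_csv optional contest dyad CSV.
#' @param trials_csv optional MIS trial CSV.
#' @param n_fish_spectra total fish in the synthetic conspicuousness dataset
#'   (cycled over dominant and subordinate states; stage 1 uses the dominant
#'   subset).
#' @param verbose print progress messages?
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, synthetic = synthetic_config(seed),
                       spectra_csv = NULL, dyads_csv = NULL,
                       trials_csv = NULL, n_fish_spectra = 20,
                       verbose = FALSE) {
  for (f in c(spectra_csv, dyads_csv, trials_csv))
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f, call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, spectra_csv = spectra_csv,
                 dyads_csv = dyads_csv, trials_csv = trials_csv,
                 n_fish_spectra = n_fish_spectra, verbose = verbose),
            class = "run_config")
}

say <- function(config, ...) if (isTRUE(config$verbose)) message(...)

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

write_table <- function(df, config, name) {
  path <- file.path(ensure_dir(config$out_dir), name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

flatten_fit <- function(fit, model) {
  at <- fit$anova_table
  cbind(model = model, at, shapiro_p = fit$shapiro_p,
        transform = fit$transform)
}

load_patches <- function(config) {
  if (is.null(config$spectra_csv)) {
    gen_conspicuousness_dataset(config$synthetic, config$n_fish_spectra,
                                seed = config$seed)
  } else {
    sp <- read_spectra(config$spectra_csv)
    lapply(names(sp), function(id) {
      parts <- strsplit(id, "|", fixed = TRUE)[[1]]
      if (length(parts) != 3)
        stop("spectrum_id must be fish|state|patch, got: ", id, call. = FALSE)
      color_patch(parts[1], parts[2], parts[3], sp[[id]])
    })
  }
}

#' Run pipeline stages
#'
#' `run_stage1()` computes the pairwise patch contrasts under ambient light,
#' aggregates them per fish, and fits the dominant-fish adjacency models
#' (signal design and efficacy). `run_stage2()` adds the two-state
#' adjacency-by-stripe models with variance partitions, the per-pair-type
#' dominance change tests, and the contest analyses (dyad matching, outcome
#' models, stripe-outcome association at both timepoints). `run_stage3()`
#' fits the mirror-trial punishment models with Tukey post-hoc contrasts and
#' fold effects. `run_all()` runs the three stages and writes a run
#' manifest. Every table is written as CSV into `config$out_dir`; outputs
#' are deterministic given the configuration and seed.
#'
#' @param config a [run_config].
#' @return a named list of the computed tables and fits, invisibly; CSVs on
#'   disk as a side effect.
#' @export
run_stage1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say(config, "stage 1: contrasts and adjacency models")
  patches <- load_patches(config)
  system <- gen_visual_system(config$synthetic)
  env <- gen_light_environment(config$synthetic)
  records <- pairwise_contrasts(patches, default_adjacency(), system, env)
  aggregated <- aggregate_per_fish(records)
  fit_chr <- adjacency_lmm(aggregated, "chromatic", "dominant_only")
  fit_ach <- adjacency_lmm(aggregated, "achromatic", "dominant_only")
  models <- rbind(flatten_fit(fit_chr, "stage1_chromatic_adjacency"),
                  flatten_fit(fit_ach, "stage1_achromatic_adjacency"))
  write_table(records, config, "contrasts.csv")
  write_table(aggregated, config, "aggregated_contrasts.csv")
  write_table(models, config, "stage1_models.csv")
  invisible(list(records = records, aggregated = aggregated,
                 fit_chromatic = fit_chr, fit_achromatic = fit_ach))
}

#' @rdname run_stage1
#' @export
run_stage2 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say(config, "stage 2: signal message and contest analysis")
  contrasts_path <- file.path(config$out_dir, "contrasts.csv")
  records <- if (file.exists(contrasts_path))
    utils::read.csv(contrasts_path, stringsAsFactors = FALSE)
  else run_stage1(config)$records
  aggregated <- aggregate_per_fish(records)

  fit_chr <- adjacency_lmm(aggregated, "chromatic", "dominant_and_subordinate")
  fit_ach <- adjacency_lmm(aggregated, "achromatic", "dominant_and_subordinate")
  change <- per_patch_change_tests(records)

  dyads <- if (is.null(config$dyads_csv))
    gen_contests(config$synthetic, seed = config$seed + 1L)
  else utils::read.csv(config$dyads_csv, stringsAsFactors = FALSE)
  check_dyads(dyads)
  matching <- matching_test(dyads)
  fit_mass <- outcome_lmm(dyads, "mass")
  fit_fa <- outcome_lmm(dyads, "fighting_ability")
  glmm_end <- stripe_outcome_glmm(dyads, "end")
  # both fish start contests dark-striped, so the begin-timepoint test is
  # routinely degenerate (p = 1); no need to warn inside the pipeline
  glmm_begin <- suppressWarnings(stripe_outcome_glmm(dyads, "begin"))

  models <- rbind(flatten_fit(fit_chr, "stage2_chromatic_adjacency_x_stripe"),
                  flatten_fit(fit_ach, "stage2_achromatic_adjacency_x_stripe"),
                  flatten_fit(fit_mass, "stage2_outcome_mass"),
                  flatten_fit(fit_fa, "stage2_outcome_fighting_ability"))
  varpart <- rbind(cbind(model = "chromatic", variance_partition(fit_chr)),
                   cbind(model = "achromatic", variance_partition(fit_ach)))
  glmms <- data.frame(
    model = c("stripe_outcome_end", "stripe_outcome_begin"),
    chisq = c(glmm_end$chisq, glmm_begin$chisq),
    df = c(glmm_end$df, glmm_begin$df),
    p = c(glmm_end$p, glmm_begin$p),
    odds_ratio = c(glmm_end$odds_ratio, glmm_begin$odds_ratio),
    separation = c(glmm_end$separation, glmm_begin$separation))

  write_table(models, config, "stage2_models.csv")
  write_table(varpart, config, "stage2_variance_partition.csv")
  write_table(change, config, "stage2_change_tests.csv")
  write_table(dyads, config, "dyads.csv")
  write_table(matching, config, "stage2_matching.csv")
  write_table(glmms, config, "stage2_stripe_outcome.csv")
  invisible(list(fit_chromatic = fit_chr, fit_achromatic = fit_ach,
                 change_tests = change, dyads = dyads, matching = matching,
                 fit_mass = fit_mass, fit_fighting_ability = fit_fa,
                 glmm_end = glmm_end, glmm_begin = glmm_begin))
}

#' @rdname run_stage1
#' @export
run_stage3 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say(config, "stage 3: out-of-equilibrium punishment analysis")
  trials <- if (is.null(config$trials_csv))
    gen_mis_trials(config$synthetic, seed = config$seed + 2L)
  else utils::read.csv(config$trials_csv, stringsAsFactors = FALSE)
  validate_mis_trials(trials)
  fit_bouts <- mis_lmm(trials, "bouts")
  fit_lat <- mis_lmm(trials, "latency")
  tukey_bouts <- tukey_posthoc(fit_bouts)
  tukey_lat <- tukey_posthoc(fit_lat)
  folds <- fold_effects(trials, seed = config$seed + 3L)
  models <- rbind(flatten_fit(fit_bouts, "stage3_bouts"),
                  flatten_fit(fit_lat, "stage3_latency"))
  posthoc <- rbind(cbind(model = "bouts", tukey_bouts),
                   cbind(model = "latency", tukey_lat))
  write_table(trials, config, "mis_trials.csv")
  write_table(models, config, "stage3_models.csv")
  write_table(posthoc, config, "stage3_tukey.csv")
  write_table(cbind(folds, n_censored = attr(folds, "n_censored")),
              config, "stage3_fold_effects.csv")
  invisible(list(trials = trials, fit_bouts = fit_bouts,
                 fit_latency = fit_lat, tukey_bouts = tukey_bouts,
                 tukey_latency = tukey_lat, fold_effects = folds))
}

#' @rdname run_stage1
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  s1 <- run_stage1(config)
  s2 <- run_stage2(config)
  s3 <- run_stage3(config)
  cfg_flat <- config$synthetic
  cfg_flat$grid <- sprintf("%g-%g by %g", min(cfg_flat$grid),
                           max(cfg_flat$grid), diff(cfg_flat$grid[1:2]))
  manifest <- c(
    sprintf("package: stripesignal %s",
            as.character(utils::packageVersion("stripesignal"))),
    sprintf("seed: %d", config$seed),
    sprintf("inputs: %s",
            paste(c(spectra = config$spectra_csv, dyads = config$dyads_csv,
                    trials = config$trials_csv, "synthetic"), collapse = ", ")),
    "config:",
    vapply(names(cfg_flat), function(k)
      sprintf("  %s: %s", k, paste(format(cfg_flat[[k]], digits = 12),
                                   collapse = ", ")), character(1)))
  writeLines(manifest, file.path(ensure_dir(config$out_dir), "manifest.txt"))
  invisible(list(stage1 = s1, stage2 = s2, stage3 = s3))
}
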