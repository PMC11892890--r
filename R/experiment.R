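#' Experiment configuration
#'
#' Bundles every setting of the synthetic protocol: phantom, scan geometry,
#' artifact model, network architectures and training hyperparameters.  One
#' global seed deterministically spawns the per-module sub-seeds.
#'
#' @param phantom A [foam_spec()] (the test phantom uses the same spec with
#'   a derived seed, so training and evaluation never share an object).
#' @param n_angles_lq Low-quality angle count.
#' @param factor High-/low-quality angle ratio; the high-quality count is
#'   `factor * n_angles_lq`.
#' @param artifacts An [artifact_config()].
#' @param depth MS-D depth used for all three stages.
#' @param training A [training_config()].
#' @param bypass Train the bypass pipeline (and, if `ablation = TRUE`, also
#'   the no-bypass variant).
#' @param ablation Also run the no-bypass variant.
#' @param out_dir Output directory for stacks, models and the manifest.
#' @param seed Global seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = scaled_foam_spec(64L),
                              n_angles_lq = 32L, factor = 4L,
                              artifacts = artifact_config(),
                              depth = 20L,
                              training = training_config(),
                              bypass = TRUE, ablation = FALSE,
                              out_dir = tempfile("mstar_exp_"),
                              seed = 1L) {
  stopifnot(inherits(phantom, "foam_spec"),
            inherits(artifacts, "artifact_config"),
            inherits(training, "training_config"))
  if (!is_count(n_angles_lq) || !is_count(factor))
    stopf("n_angles_lq and factor must be positive integers")
  structure(list(phantom = phantom, n_angles_lq = as.integer(n_angles_lq),
                 factor = as.integer(factor), artifacts = artifacts,
                 depth = as.integer(depth), training = training,
                 bypass = bypass, ablation = ablation, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full synthetic experiment
#'
#' Executes the complete protocol: generate a training and a test phantom,
#' simulate paired low-/high-quality scans, train the multi-stage pipeline
#' (optionally also the no-bypass ablation), enhance the test scan, and
#' evaluate against the high-quality reference.  All artifacts (stacks,
#' model checkpoints, metric reports) are written under `cfg$out_dir`
#' together with a manifest listing every file and the resolved
#' configuration; rerunning with the same config and seed reproduces the
#' metric reports exactly.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print progress.
#' @return The manifest (named list), invisibly also written as YAML.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  keep <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  phantom_train <- cfg$phantom
  phantom_train$seed <- sub_seed(cfg$seed, 11L)
  phantom_test <- cfg$phantom
  phantom_test$seed <- sub_seed(cfg$seed, 12L)
  art_train <- cfg$artifacts; art_train$seed <- sub_seed(cfg$seed, 21L)
  art_test <- cfg$artifacts; art_test$seed <- sub_seed(cfg$seed, 22L)
  train_cfg <- cfg$training; train_cfg$seed <- sub_seed(cfg$seed, 31L)

  say("simulating scans")
  scan_train <- simulate_paired_scan(generate_foam_phantom(phantom_train),
                                     cfg$n_angles_lq, cfg$factor, art_train)
  scan_test <- simulate_paired_scan(generate_foam_phantom(phantom_test),
                                    cfg$n_angles_lq, cfg$factor, art_test)
  keep("proj_lq_test.tif", function(p) write_stack(scan_test$p_lq, p))
  keep("recon_hq_test.tif", function(p) write_stack(scan_test$r_hq, p))

  specs <- function(bypass) {
    want <- if (bypass) c(1L, 2L, 3L) else c(1L, 1L, 1L)
    lapply(want, function(c_in) msd_spec(c_in = c_in, depth = cfg$depth))
  }

  results <- list()
  variants <- c(if (cfg$bypass) "bypass", if (cfg$ablation) "no_bypass")
  for (variant in variants) {
    bp <- variant == "bypass"
    say("training %s pipeline", variant)
    models <- train_all(scan_train, specs(bp), train_cfg, bypass = bp)
    for (nm in c("f_p", "f_s", "f_r"))
      keep(sprintf("%s_%s.json", variant, nm),
           function(p) write_stage_model(models[[nm]], p))
    enh <- if (bp) enhance(scan_test$p_lq, models)
           else enhance_no_bypass(scan_test$p_lq, models)
    keep(sprintf("recon_%s.tif", variant),
         function(p) write_stack(enh$r_hat, p))
    report <- evaluate_volume(enh$r_hat, scan_test$r_hq,
                              reference_id = "hq_reconstruction")
    keep(sprintf("report_%s.json", variant),
         function(p) write_eval_report(report, p))
    results[[variant]] <- list(mean_psnr = report$mean_psnr,
                               mean_ssim = report$mean_ssim)
  }

  corrupted <- fbp_reconstruct(rearrange(scan_test$p_lq))
  report_corr <- evaluate_volume(corrupted, scan_test$r_hq,
                                 reference_id = "hq_reconstruction")
  keep("report_corrupted.json",
       function(p) write_eval_report(report_corr, p))
  results$corrupted <- list(mean_psnr = report_corr$mean_psnr,
                            mean_ssim = report_corr$mean_ssim)

  manifest <- list(config = resolved_config(cfg), files = files,
                   results = results)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(manifest)
}

resolved_config <- function(cfg) {
  list(phantom = unclass(cfg$phantom), n_angles_lq = cfg$n_angles_lq,
       factor = cfg$factor, artifacts = unclass(cfg$artifacts),
       depth = cfg$depth, training = lapply(unclass(cfg$training), function(x)
         if (identical(x, Inf)) ".inf" else x),
       bypass = cfg$bypass, ablation = cfg$ablation, seed = cfg$seed)
}
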