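#!/usr/bin/env Rscript
# Full-scale corrupted-baseline protocol: a 512-voxel foam with 100000
# bubbles, scanned clean at 1024 angles and corrupted at 256 angles, with
# mean PSNR/SSIM of the corrupted FBP reconstructions evaluated against
# the clean high-quality reconstruction at two noise levels.
#
# This is the hours-long, tens-of-GB companion of the scaled-down study in
# tests/testthat/test-acceptance.R; run it only on a machine with plenty
# of memory and time:
#   Rscript scripts/full_scale_baseline.R [--seed 1] [--out results/full_scale.json]

suppressPackageStartupMessages({
  library(mstar)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "results/full_scale.json")
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

message("generating 512^3 foam phantom (100000 bubbles) ...")
vol <- generate_foam_phantom(foam_spec(grid_size = 512L,
                                       n_bubbles = 100000L,
                                       seed = opt$seed))

message("forward projecting at 1024 angles ...")
p_hq <- forward_project(vol, angle_set(1024L))
rm(vol); gc()
cal <- calibrate_absorption(p_hq, 0.5)
p_hq <- cal$p

message("reconstructing the high-quality reference ...")
r_hq <- fbp_reconstruct(rearrange(p_hq))

lq_idx <- (seq_len(256L) - 1L) * 4L + 1L
p_lq_clean <- projection_stack(p_hq$data[lq_idx, , , drop = FALSE],
                               p_hq$angles[lq_idx])
rm(p_hq); gc()

results <- list()
for (I0 in c(100, 30)) {
  message(sprintf("corrupting and reconstructing at I0 = %g ...", I0))
  cfg <- artifact_config(I0 = I0, P_ring = 0.1, P_zinger = 0.001,
                         seed = opt$seed)
  r_corr <- fbp_reconstruct(rearrange(corrupt(p_lq_clean, cfg)))
  rep <- evaluate_volume(r_corr, r_hq)
  rm(r_corr); gc()
  message(sprintf("  I0 = %g: mean PSNR %.2f dB, mean SSIM %.3f",
                  I0, rep$mean_psnr, rep$mean_ssim))
  results[[sprintf("corrupted_I0_%g", I0)]] <-
    list(psnr = rep$mean_psnr, ssim = rep$mean_ssim, n = 512L)
}

dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(results, opt$out, auto_unbox = TRUE, digits = NA)
message("wrote ", opt$out)
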