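#' Bundle the three stage models of the multi-stage pipeline
#'
#' With bypass connections (the default) each stage receives the raw data
#' and all previously enhanced representations, so the channel counts are
#' exactly (1, 2, 3); the no-bypass ablation links stages directly and uses
#' (1, 1, 1).
#'
#' @param f_p,f_s,f_r [stage_model()]s for the projection, sinogram and
#'   reconstruction stages.
#' @param upsample_factor Integer ratio of high-quality to low-quality angle
#'   counts (4 at full scale).
#' @param bypass Logical; `FALSE` selects the no-bypass variant.
#' @return An object of class `pipeline_models`.
#' @export
pipeline_models <- function(f_p, f_s, f_r, upsample_factor = 4L,
                            bypass = TRUE) {
  for (m in list(f_p, f_s, f_r))
    if (!inherits(m, "stage_model")) stopf("all stages must be stage_models")
  if (!is_count(upsample_factor)) stopf("upsample_factor must be an integer >= 1")
  want <- if (bypass) c(1L, 2L, 3L) else c(1L, 1L, 1L)
  got <- c(f_p$spec$c_in, f_s$spec$c_in, f_r$spec$c_in)
  if (!identical(got, want))
    stopf("stage input channels are (%s) but the %s pipeline requires (%s)",
          paste(got, collapse = ", "),
          if (bypass) "bypass" else "no-bypass",
          paste(want, collapse = ", "))
  structure(list(f_p = f_p, f_s = f_s, f_r = f_r,
                 upsample_factor = as.integer(upsample_factor),
                 bypass = bypass),
            class = "pipeline_models")
}

#' @export
print.pipeline_models <- function(x, ...) {
  cat(sprintf("pipeline_models (%s): stages c_in = %d/%d/%d, upsample x%d\n",
              if (x$bypass) "with bypass" else "no bypass",
              x$f_p$spec$c_in, x$f_s$spec$c_in, x$f_r$spec$c_in,
              x$upsample_factor))
  invisible(x)
}

# Apply the projection-stage network to every projection image.
apply_stage1 <- function(model, p_raw) {
  d <- dim(p_raw$data)
  out <- array(0, dim = d)
  for (a in seq_len(d[1]))
    out[a, , ] <- msd_forward(model, p_raw$data[a, , ])
  projection_stack(out, p_raw$angles)
}

# Channel stacks entering stage 2, already angle-upsampled to the HQ grid.
# Bypass order: raw first, enhanced last (stage networks that pass their
# last input channel through therefore forward the enhanced data).
stage2_channels <- function(p_raw, p_hat, factor, bypass) {
  s_hat_up <- angle_upsample(rearrange(p_hat), factor)
  if (bypass)
    list(angle_upsample(rearrange(p_raw), factor), s_hat_up)
  else
    list(s_hat_up)
}

# Apply the sinogram-stage network row by row over multi-channel input.
apply_stage_rows <- function(model, channels) {
  d <- dim(channels[[1]]$data)
  out <- array(0, dim = d)
  for (m in seq_len(d[1])) {
    x <- array(0, dim = c(d[2], d[3], length(channels)))
    for (c in seq_along(channels)) x[, , c] <- channels[[c]]$data[m, , ]
    out[m, , ] <- msd_forward(model, x)
  }
  sinogram_stack(out, channels[[1]]$angles)
}

# Reconstruction-stage input volumes; all three channels share the HQ angle
# grid (the first two are reconstructed from upsampled sinograms).
stage3_channels <- function(s2_channels, s_hat, bypass) {
  if (bypass)
    list(fbp_reconstruct(s2_channels[[1]]), fbp_reconstruct(s2_channels[[2]]),
         fbp_reconstruct(s_hat))
  else
    list(fbp_reconstruct(s_hat))
}

apply_stage_slices <- function(model, vols) {
  d <- dim(vols[[1]])
  out <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    x <- array(0, dim = c(d[2], d[3], length(vols)))
    for (c in seq_along(vols)) x[, , c] <- vols[[c]][z, , ]
    out[z, , ] <- msd_forward(model, x)
  }
  out
}

#' Multi-stage artifact reduction (chained inference)
#'
#' Runs the three stage networks in sequence.  Stage 1 enhances each raw
#' projection.  Stage 2 consumes the angle-upsampled sinograms of the raw
#' and enhanced projections (two channels) and outputs an enhanced sinogram
#' at the high-quality angle count.  Stage 3 consumes the reconstructions
#' of the raw sinogram, the enhanced-projection sinogram and the enhanced
#' sinogram (three channels) and outputs the enhanced reconstruction.
#' Inputs are never mutated.
#'
#' @param p_raw Corrupted [projection_stack()] with equally spaced angles.
#' @param models A [pipeline_models()] with `bypass = TRUE`.
#' @return List with elements `p_hat` ([projection_stack()]), `s_hat`
#'   ([sinogram_stack()] at the upsampled angle count) and `r_hat`
#'   (3D array `(Z, N, N)`).
#' @export
enhance <- function(p_raw, models) {
  stopifnot(inherits(models, "pipeline_models"))
  if (!models$bypass)
    stopf("models were built with bypass = FALSE; use enhance_no_bypass()")
  p_hat <- apply_stage1(models$f_p, p_raw)
  ch2 <- stage2_channels(p_raw, p_hat, models$upsample_factor, bypass = TRUE)
  s_hat <- apply_stage_rows(models$f_s, ch2)
  ch3 <- stage3_channels(ch2, s_hat, bypass = TRUE)
  r_hat <- apply_stage_slices(models$f_r, ch3)
  list(p_hat = p_hat, s_hat = s_hat, r_hat = r_hat)
}

#' @rdname enhance
#'
#' @description `enhance_no_bypass()` is the ablation variant without bypass
#'   connections: stage 2 sees only the enhanced-projection sinogram and
#'   stage 3 only the reconstruction of the enhanced sinogram.
#' @export
enhance_no_bypass <- function(p_raw, models) {
  stopifnot(inherits(models, "pipeline_models"))
  if (models$bypass)
    stopf("models were built with bypass = TRUE; use enhance()")
  p_hat <- apply_stage1(models$f_p, p_raw)
  ch2 <- stage2_channels(p_raw, p_hat, models$upsample_factor, bypass = FALSE)
  s_hat <- apply_stage_rows(models$f_s, ch2)
  ch3 <- stage3_channels(ch2, s_hat, bypass = FALSE)
  r_hat <- apply_stage_slices(models$f_r, ch3)
  list(p_hat = p_hat, s_hat = s_hat, r_hat = r_hat)
}
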