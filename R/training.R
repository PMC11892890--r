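#' Training configuration
#'
#' Hyperparameters for sequential per-stage supervised training: ADAM with
#' mean-squared-error loss, an initial learning rate of 1e-3, per-stage
#' epoch budgets of (200, 200, 500), and early stopping after 10 epochs
#' without validation-loss improvement.
#'
#' @param epochs Length-3 integer vector of per-stage epoch budgets.
#' @param learning_rate ADAM learning rate (> 0).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param val_fraction Held-out fraction of training images in (0, 1).
#' @param batch_size Images per gradient update.
#' @param seed Integer seed controlling splits, shuffling and
#'   initialization.
#' @param max_seconds Wall-clock cap per stage (replaces an open-ended
#'   training duration limit; `Inf` disables it).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = c(200L, 200L, 500L), learning_rate = 1e-3,
                            early_stop_patience = 10L, val_fraction = 0.1,
                            batch_size = 1L, seed = 1L, max_seconds = Inf) {
  if (length(epochs) != 3L || any(epochs < 1))
    stopf("epochs must be three positive integers")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (val_fraction <= 0 || val_fraction >= 1)
    stopf("val_fraction must be in (0, 1)")
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  if (!is_count(early_stop_patience)) stopf("early_stop_patience must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), max_seconds = max_seconds),
            class = "training_config")
}

#' Simulate a paired low-/high-quality scan of one object
#'
#' Forward-projects the volume at `factor * n_angles_lq` angles, calibrates
#' absorption to `cfg$gamma_target`, keeps the clean high-quality stack,
#' and corrupts the low-quality subset (every `factor`-th angle, starting
#' at 0, so low-quality angle i coincides with high-quality angle
#' `i * factor`).  The high-quality reference volume is the FBP of the
#' clean high-quality sinograms.
#'
#' @param vol 3D attenuation array `(Z, Y, X)` with square slices.
#' @param n_angles_lq Low-quality angle count.
#' @param factor High-/low-quality angle ratio (integer >= 1).
#' @param cfg An [artifact_config()].
#' @return An object of class `paired_scan` with elements `p_lq`
#'   (corrupted), `p_hq` (clean, calibrated), `r_hq` (reference volume),
#'   `factor` and `scale` (absorption calibration factor).
#' @export
simulate_paired_scan <- function(vol, n_angles_lq, factor = 4L, cfg) {
  if (!is_count(n_angles_lq)) stopf("n_angles_lq must be a positive integer")
  if (!is_count(factor)) stopf("factor must be an integer >= 1")
  p_hq <- forward_project(vol, angle_set(n_angles_lq * factor))
  cal <- calibrate_absorption(p_hq, cfg$gamma_target)
  p_hq <- cal$p
  lq_idx <- (seq_len(n_angles_lq) - 1L) * factor + 1L
  p_lq_clean <- projection_stack(p_hq$data[lq_idx, , , drop = FALSE],
                                 p_hq$angles[lq_idx])
  p_lq <- corrupt(p_lq_clean, cfg)
  structure(list(p_lq = p_lq, p_hq = p_hq,
                 r_hq = fbp_reconstruct(rearrange(p_hq)),
                 factor = as.integer(factor), scale = cal$scale),
            class = "paired_scan")
}

#' Build per-stage supervised training pairs
#'
#' Stage 1 pairs each corrupted low-quality projection with the clean
#' high-quality projection at the same angle.  Stage 2 pairs the
#' angle-upsampled raw and enhanced sinogram rows (inputs computed with the
#' frozen stage-1 model) with the high-quality sinogram rows.  Stage 3
#' pairs the three reconstruction channels with the high-quality
#' reconstruction slices.
#'
#' @param scan A [simulate_paired_scan()] result (or a list with the same
#'   fields).
#' @param stage 1, 2 or 3.
#' @param models_so_far For stage 2, a list with `f_p`; for stage 3, a list
#'   with `f_p` and `f_s`.
#' @param bypass Logical; `FALSE` builds the no-bypass variant's inputs.
#' @return List with `inputs` (list of `(H, W, c)` arrays), `targets`
#'   (list of `(H, W)` matrices) and `stage`.
#' @export
build_pairs <- function(scan, stage, models_so_far = NULL, bypass = TRUE) {
  stopifnot(inherits(scan, "paired_scan"))
  if (!stage %in% 1:3) stopf("stage must be 1, 2 or 3")
  factor <- scan$factor
  if (stage == 1L) {
    d <- dim(scan$p_lq$data)
    hq_idx <- (seq_len(d[1]) - 1L) * factor + 1L
    inputs <- lapply(seq_len(d[1]), function(a)
      array(scan$p_lq$data[a, , ], dim = c(d[2], d[3], 1L)))
    targets <- lapply(seq_len(d[1]), function(a) scan$p_hq$data[hq_idx[a], , ])
    return(list(inputs = inputs, targets = targets, stage = 1L))
  }
  if (is.null(models_so_far$f_p))
    stopf("stage %d pairs need the trained stage-1 model", stage)
  p_hat <- apply_stage1(models_so_far$f_p, scan$p_lq)
  ch2 <- stage2_channels(scan$p_lq, p_hat, factor, bypass = bypass)
  s_hq <- rearrange(scan$p_hq)
  if (stage == 2L) {
    d <- dim(ch2[[1]]$data)
    inputs <- lapply(seq_len(d[1]), function(m) {
      x <- array(0, dim = c(d[2], d[3], length(ch2)))
      for (c in seq_along(ch2)) x[, , c] <- ch2[[c]]$data[m, , ]
      x
    })
    targets <- lapply(seq_len(d[1]), function(m) s_hq$data[m, , ])
    return(list(inputs = inputs, targets = targets, stage = 2L))
  }
  if (is.null(models_so_far$f_s))
    stopf("stage 3 pairs need the trained stage-2 model")
  s_hat <- apply_stage_rows(models_so_far$f_s, ch2)
  ch3 <- stage3_channels(ch2, s_hat, bypass = bypass)
  d <- dim(ch3[[1]])
  inputs <- lapply(seq_len(d[1]), function(z) {
    x <- array(0, dim = c(d[2], d[3], length(ch3)))
    for (c in seq_along(ch3)) x[, , c] <- ch3[[c]][z, , ]
    x
  })
  targets <- lapply(seq_len(d[1]), function(z) scan$r_hq[z, , ])
  list(inputs = inputs, targets = targets, stage = 3L)
}

# Channel-wise normalization constants over a list of (H, W, c) arrays.
norm_stats <- function(inputs) {
  c_in <- dim(inputs[[1]])[3]
  stats <- vapply(seq_len(c_in), function(c) {
    v <- unlist(lapply(inputs, function(x) as.numeric(x[, , c])))
    s <- stats::sd(v)
    c(mean(v), if (is.finite(s) && s > 0) s else 1)
  }, numeric(2))
  matrix(stats, nrow = 2)
}

#' Train one stage network
#'
#' Minimizes mean-squared error (in normalized target units) over the
#' training pairs with ADAM, holding out `val_fraction` of the images as a
#' fixed validation split.  Training stops at the epoch budget, after
#' `early_stop_patience` epochs without validation improvement, or at the
#' wall-clock cap; the returned model carries the best-validation
#' parameters.  Deterministic given the config seed.
#'
#' @param pairs Output of [build_pairs()] (at least 2 pairs).
#' @param spec An [msd_spec()] whose `c_in` matches the pair inputs.
#' @param cfg A [training_config()].
#' @param stage Which epoch budget to use (1, 2 or 3).
#' @param verbose Print per-epoch losses.
#' @return A trained [stage_model()]; `$history` holds per-epoch train and
#'   validation losses.
#' @export
train_stage <- function(pairs, spec, cfg = training_config(), stage = pairs$stage,
                        verbose = FALSE) {
  n <- length(pairs$inputs)
  if (n < 2L) stopf("need at least 2 pairs to split off a validation set")
  if (dim(pairs$inputs[[1]])[3] != spec$c_in)
    stopf("pairs have %d channels but spec$c_in is %d",
          dim(pairs$inputs[[1]])[3], spec$c_in)
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (n_val >= n) n_val <- n - 1L
  split_seed <- sub_seed(cfg$seed, 100L + stage)
  val_idx <- with_seed(split_seed, sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)

  norm_in <- norm_stats(pairs$inputs[train_idx])
  tvals <- unlist(lapply(pairs$targets[train_idx], as.numeric))
  tsd <- stats::sd(tvals)
  norm_out <- c(mean(tvals), if (is.finite(tsd) && tsd > 0) tsd else 1)

  normalize <- function(idx) {
    list(
      x = lapply(idx, function(i) {
        x <- pairs$inputs[[i]]
        for (c in seq_len(spec$c_in))
          x[, , c] <- (x[, , c] - norm_in[1, c]) / norm_in[2, c]
        x
      }),
      y = lapply(idx, function(i)
        (pairs$targets[[i]] - norm_out[1]) / norm_out[2]))
  }
  tr <- normalize(train_idx)
  va <- normalize(val_idx)

  init <- msd_init(msd_spec(spec$c_in, spec$depth, spec$c_out, spec$dilations,
                            seed = sub_seed(cfg$seed, 200L + stage)))
  theta <- init$params
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf
  best_theta <- theta
  patience_left <- cfg$early_stop_patience
  hist_train <- hist_val <- numeric(0)
  t0 <- Sys.time()

  val_loss <- function(th) {
    mean(vapply(seq_along(va$x), function(i) {
      out <- msd_forward_cpp(th, va$x[[i]], spec$depth, spec$c_out,
                             spec$dilations)[, , 1]
      mean((out - va$y[[i]])^2)
    }, numeric(1)))
  }

  for (epoch in seq_len(cfg$epochs[stage])) {
    ord <- with_seed(sub_seed(cfg$seed, 300L * stage + epoch),
                     sample(seq_along(tr$x)))
    ep_loss <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      g <- numeric(length(theta))
      for (b in batch) {
        lg <- msd_loss_grad_cpp(theta, tr$x[[b]], tr$y[[b]], spec$depth,
                                spec$dilations)
        if (!is.finite(lg$loss))
          stopf("training diverged: non-finite loss at epoch %d", epoch)
        ep_loss <- ep_loss + lg$loss
        g <- g + lg$grad
      }
      g <- g / length(batch)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      i <- i + cfg$batch_size
    }
    ep_loss <- ep_loss / length(ord)
    vl <- val_loss(theta)
    hist_train <- c(hist_train, ep_loss)
    hist_val <- c(hist_val, vl)
    if (verbose)
      message(sprintf("stage %d epoch %3d: train %.5g val %.5g",
                      stage, epoch, ep_loss, vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl
      best_theta <- theta
      patience_left <- cfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > cfg$max_seconds)
      break
  }

  stage_model(spec, best_theta, norm_in = norm_in, norm_out = norm_out,
              history = list(train = hist_train, val = hist_val,
                             best_val = best_val, epochs_run = length(hist_val),
                             final_train = tail(hist_train, 1)))
}

#' Train the full multi-stage pipeline
#'
#' Sequentially trains the projection, sinogram and reconstruction networks:
#' each stage is trained to convergence and frozen before the next stage's
#' training pairs are built from its best-validation checkpoint.  No
#' gradient crosses a stage boundary.
#'
#' @param scan A [simulate_paired_scan()] result.
#' @param specs List of three [msd_spec()]s (projection, sinogram,
#'   reconstruction); defaults to depth-100 networks with the channel
#'   counts implied by `bypass`.
#' @param cfg A [training_config()].
#' @param bypass Train the bypass (default) or no-bypass variant.
#' @param verbose Print per-epoch losses.
#' @return A [pipeline_models()]; attribute `"log"` records the training
#'   event sequence and attribute `"history"` the per-stage loss curves.
#' @export
train_all <- function(scan, specs = NULL, cfg = training_config(),
                      bypass = TRUE, verbose = FALSE) {
  stopifnot(inherits(scan, "paired_scan"))
  if (is.null(specs)) {
    want <- if (bypass) c(1L, 2L, 3L) else c(1L, 1L, 1L)
    specs <- lapply(want, function(c_in) msd_spec(c_in = c_in))
  }
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  note("build_pairs stage 1")
  pairs1 <- build_pairs(scan, 1L)
  note("train stage 1")
  f_p <- train_stage(pairs1, specs[[1]], cfg, stage = 1L, verbose = verbose)
  note("freeze stage 1")

  note("build_pairs stage 2")
  pairs2 <- build_pairs(scan, 2L, list(f_p = f_p), bypass = bypass)
  note("train stage 2")
  f_s <- train_stage(pairs2, specs[[2]], cfg, stage = 2L, verbose = verbose)
  note("freeze stage 2")

  note("build_pairs stage 3")
  pairs3 <- build_pairs(scan, 3L, list(f_p = f_p, f_s = f_s), bypass = bypass)
  note("train stage 3")
  f_r <- train_stage(pairs3, specs[[3]], cfg, stage = 3L, verbose = verbose)
  note("freeze stage 3")

  models <- pipeline_models(f_p, f_s, f_r, upsample_factor = scan$factor,
                            bypass = bypass)
  attr(models, "log") <- log
  attr(models, "history") <- list(stage1 = f_p$history, stage2 = f_s$history,
                                  stage3 = f_r$history)
  models
}
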