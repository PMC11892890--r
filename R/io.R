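#' Write / read image stacks as multi-page 32-bit float TIFF
#'
#' Projections are written one page per angle, sinograms one page per
#' detector row, volumes one page per Z slice.  Angles (in degrees) and the
#' stack kind are stored in a YAML sidecar `<path>.meta.yaml` so that every
#' file the pipeline writes is re-readable by the pipeline.
#'
#' @param x A [projection_stack()], [sinogram_stack()] or 3D volume array.
#' @param path Output file path (`.tif`).
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the restored object.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "projection_stack")) {
    kind <- "projections"; data <- x$data; angles <- x$angles
  } else if (inherits(x, "sinogram_stack")) {
    kind <- "sinograms"; data <- x$data; angles <- x$angles
  } else if (is.array(x) && length(dim(x)) == 3L) {
    kind <- "volume"; data <- x; angles <- NULL
  } else stopf("x must be a projection_stack, sinogram_stack or 3D array")
  # TIFF pages are stored affinely rescaled to [0, 1] (32-bit float); the
  # offset/scale live in the sidecar so reading restores original units.
  lo <- min(data)
  hi <- max(data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(data)[1]), function(i) (data[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = kind, dim = dim(data), offset = lo, scale = scale)
  if (!is.null(angles)) meta$angles_deg <- angles * 180 / pi
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) stopf("missing sidecar metadata: %s", meta_path)
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  data <- array(0, dim = d)
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]] * meta$scale + meta$offset
  switch(meta$kind,
    projections = projection_stack(data, as.numeric(meta$angles_deg) * pi / 180),
    sinograms = sinogram_stack(data, as.numeric(meta$angles_deg) * pi / 180),
    volume = data,
    stopf("unknown stack kind '%s'", meta$kind))
}

#' Save / load a stage model
#'
#' Self-describing versioned JSON checkpoint: architecture spec, flat
#' parameter vector, normalization constants and training metadata.
#'
#' @param model A [stage_model()].
#' @param path Output path (`.json`).
#' @return `read_stage_model()` returns the restored [stage_model()].
#' @export
write_stage_model <- function(model, path) {
  stopifnot(inherits(model, "stage_model"))
  obj <- list(format = "mstar-stage-model", version = 1L,
              spec = unclass(model$spec), params = model$params,
              norm_in = as.numeric(model$norm_in), norm_out = model$norm_out,
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stage_model
#' @export
read_stage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mstar-stage-model"))
    stopf("%s is not a stage model checkpoint", path)
  spec <- msd_spec(obj$spec$c_in, obj$spec$depth, obj$spec$c_out,
                   obj$spec$dilations, obj$spec$seed)
  stage_model(spec, as.numeric(obj$params),
              norm_in = matrix(as.numeric(obj$norm_in), nrow = 2),
              norm_out = as.numeric(obj$norm_out), history = obj$history)
}
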