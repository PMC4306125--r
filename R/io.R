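#' Cine sequence container
#'
#' Ordered 2D intensity frames with pixel spacing (mm) and frame interval
#' (ms). Frame 1 of the list is frame 0 of the cycle: the end-diastolic
#' reference configuration.
#'
#' @param frames list of numeric matrices of identical dimension.
#' @param pixel_spacing in-plane pixel size in mm, length 1 or 2 (x, y).
#' @param frame_interval time between frames in ms.
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, pixel_spacing = c(1, 1),
                          frame_interval = 50) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- lapply(frames, dim)
  same <- vapply(dims, identical, logical(1), dims[[1]])
  if (!all(same))
    stop("frames with mismatching sizes: ",
         paste(which(!same) - 1L, collapse = ", "))
  structure(list(frames = frames,
                 pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
                 frame_interval = as.numeric(frame_interval)),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("cine sequence: %d frames of %d x %d px, %.3g x %.3g mm/px, %.4g ms/frame\n",
              length(x$frames), d[1], d[2],
              x$pixel_spacing[1], x$pixel_spacing[2], x$frame_interval))
  invisible(x)
}

to_gray <- function(a) {
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE],
                                       c(1, 2), mean)
  a
}

#' Read a cine sequence from disk
#'
#' Supported inputs: a directory of grayscale PNG or TIFF frames (lexical
#' file order = temporal order) or a NIfTI 3D volume interpreted as a time
#' stack (third dimension = frame). Pixel spacing and frame interval are
#' taken from NIfTI header fields when present; otherwise defaults are used
#' with a warning.
#'
#' @param path directory of PNG/TIFF frames or a NIfTI file.
#' @param format `"auto"`, `"png"`, `"tiff"` or `"nifti"`.
#' @param pixel_spacing,frame_interval metadata overrides (mm, ms).
#' @return A [cine_sequence()].
#' @export
read_cine <- function(path, format = c("auto", "png", "tiff", "nifti"),
                      pixel_spacing = NULL, frame_interval = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      if (length(list.files(path, "\\.png$", ignore.case = TRUE))) "png"
      else "tiff"
    } else "nifti"
  }
  if (format %in% c("png", "tiff")) {
    pat <- if (format == "png") "\\.png$" else "\\.tiff?$"
    files <- sort(list.files(path, pat, full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no ", format, " frames found in ", path)
    reader <- if (format == "png") png::readPNG else tiff::readTIFF
    frames <- lapply(files, function(f) to_gray(reader(f)))
    if (is.null(pixel_spacing)) {
      warning("no pixel spacing metadata in ", format,
              " frames; assuming 1 mm/px")
      pixel_spacing <- c(1, 1)
    }
    if (is.null(frame_interval)) {
      warning("no frame interval metadata; assuming 50 ms")
      frame_interval <- 50
    }
  } else {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) != 3L) stop("expected a 3D NIfTI volume (slices = frames)")
    frames <- lapply(seq_len(d[3]), function(t) vol[, , t])
    pd <- RNifti::pixdim(vol)
    if (is.null(pixel_spacing)) pixel_spacing <- pd[1:2]
    if (is.null(frame_interval)) {
      if (length(pd) >= 3L && is.finite(pd[3]) && pd[3] > 0 && pd[3] != 1) {
        frame_interval <- pd[3]
      } else {
        warning("no temporal spacing in NIfTI header; assuming 50 ms")
        frame_interval <- 50
      }
    }
  }
  cine_sequence(frames, pixel_spacing = pixel_spacing,
                frame_interval = frame_interval)
}

#' Write a cine sequence as a PNG frame stack
#'
#' Frames are clamped to [0, 1] and written as `frame_000.png`,
#' `frame_001.png`, ... so that [read_cine()] restores them in order.
#'
#' @param cine a [cine_sequence()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cine_png <- function(cine, dir) {
  stopifnot(inherits(cine, "cine_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(cine$frames)) {
    img <- pmin(pmax(cine$frames[[t]], 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%03d.png", t - 1L)))
  }
  invisible(dir)
}

#' Run configuration
#'
#' All the knobs of a registration + strain run in one serializable object,
#' so a run is reproducible from its emitted config copy.
#'
#' @param input input path (or `"phantom"`); `format` as in [read_cine()].
#' @param format input format hint.
#' @param reference_frame index of the end-diastolic reference (default 0).
#' @param grid_spacing FFD control-point spacing in pixels.
#' @param lambda contour-penalty weight.
#' @param contour_source `"file"`, `"snake"` or `"none"`.
#' @param outdir output directory.
#' @param seed run seed: all randomness (phantom noise, any stochastic
#'   tie-breaks) flows from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(input = "phantom", format = "auto",
                       reference_frame = 0L, grid_spacing = 8,
                       lambda = 1, contour_source = "none",
                       outdir = "lvstrain_out", seed = 1L,
                       log_level = "info") {
  stopifnot(reference_frame >= 0, grid_spacing > 0, lambda >= 0,
            contour_source %in% c("file", "snake", "none"))
  structure(list(input = input, format = format,
                 reference_frame = as.integer(reference_frame),
                 grid_spacing = grid_spacing, lambda = lambda,
                 contour_source = contour_source, outdir = outdir,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' Write registration and strain results to a directory
#'
#' Emits per-frame transform JSON, dense displacement fields as TSV
#' matrices (`field_###_ux.tsv` / `_uy.tsv`), per-frame cost-trajectory
#' logs, the strain curves CSV, a copy of the run configuration, and a
#' manifest with md5 checksums of every file. A `.incomplete` marker is
#' present while writing and removed on success.
#'
#' @param seq a `displacement_sequence` from
#'   [extract_displacement_sequence()] (or a list with a `fields` element).
#' @param outdir output directory.
#' @param strain_curves optional tibble from [segment_curves()].
#' @param config optional [run_config()] to copy alongside the results.
#' @return The manifest (named list), invisibly written as
#'   `manifest.json`.
#' @export
write_results <- function(seq, outdir, strain_curves = NULL, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(outdir, ".incomplete")
  file.create(marker)
  files <- character(0)
  fields <- seq$fields %||% list()
  transforms <- seq$transforms %||% list()
  for (t in seq_along(fields)) {
    if (is.null(fields[[t]])) next
    fx <- file.path(outdir, sprintf("field_%03d_ux.tsv", t - 1L))
    fy <- file.path(outdir, sprintf("field_%03d_uy.tsv", t - 1L))
    write_matrix_tsv(fields[[t]]$u[, , 1], fx)
    write_matrix_tsv(fields[[t]]$u[, , 2], fy)
    files <- c(files, fx, fy)
    tr <- if (t <= length(transforms)) transforms[[t]] else NULL
    if (!is.null(tr)) {
      fj <- file.path(outdir, sprintf("transform_%03d.json", t - 1L))
      transform_to_json(tr, fj)
      files <- c(files, fj)
      traj <- attr(tr, "trajectory")
      if (!is.null(traj)) {
        fc <- file.path(outdir, sprintf("cost_%03d.csv", t - 1L))
        utils::write.csv(traj, fc, row.names = FALSE)
        files <- c(files, fc)
      }
    }
  }
  if (!is.null(strain_curves)) {
    fs <- file.path(outdir, "strain_curves.csv")
    utils::write.csv(strain_curves, fs, row.names = FALSE)
    files <- c(files, fs)
  }
  if (!is.null(config)) {
    fk <- file.path(outdir, "run_config.json")
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                digits = NA), fk)
    files <- c(files, fk)
  }
  manifest <- list(n_frames = length(fields),
                   files = as.list(tools::md5sum(files)))
  names(manifest$files) <- basename(files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "manifest.json"))
  file.remove(marker)
  invisible(manifest)
}
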