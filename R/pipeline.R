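#' Segmentation configuration
#'
#' Collects the tunable parameters of [segment_bitewing()] with their
#' defaults: high-pass cutoff frequency 30, Gaussian filter with the
#' standard denominator, rotation sweep of +/-15 degrees in 1-degree
#' steps, minimum tooth width 8% of the row width, and a valley
#' acceptance ceiling of 0.15 times the mean in-band column mass.
#'
#' @param cutoff High-pass cutoff frequency \eqn{D_0}.
#' @param mode `"gaussian"` or `"ideal"` high-pass filter.
#' @param denominator `"standard"` or `"as_printed"` Gaussian form.
#' @param angle_range,step Rotation sweep half-width and spacing
#'   (degrees).
#' @param min_tooth_width_frac Minimum tooth width as a fraction of the
#'   row image width.
#' @param valley_ceiling Valley acceptance ceiling (fraction of mean
#'   in-band column mass).
#' @return A list of class `"segment_config"`.
#' @export
segment_config <- function(cutoff = 30, mode = "gaussian",
                           denominator = "standard",
                           angle_range = 15, step = 1,
                           min_tooth_width_frac = 0.08,
                           valley_ceiling = 0.15) {
  structure(list(cutoff = cutoff, mode = mode, denominator = denominator,
                 angle_range = angle_range, step = step,
                 min_tooth_width_frac = min_tooth_width_frac,
                 valley_ceiling = valley_ceiling),
            class = "segment_config")
}

#' Segment a bitewing film into half-tooth images
#'
#' Runs the full chain: preprocessing ([preprocess_bitewing()]), row
#' separating line ([find_row_separator()]), upper/lower split
#' ([split_rows()]), per-row interdental lines
#' ([find_tooth_separators()]), masked single-tooth crops
#' ([crop_and_mask()]) and left/right halves ([split_halves()]).
#' Errors raised by a stage are propagated with the stage name
#' prepended. Crops are taken in the rotated (levelled) frame.
#'
#' @param src Grayscale bitewing, intensities in `[0, 255]`.
#' @param config A [segment_config()].
#' @param bitewing_id Identifier recorded in provenance and the report.
#' @return An object of class `"bitewing_segmentation"`: a list with
#'   `halves` (list of `"half_tooth"` objects) and `report` (nested list
#'   mirroring the `segmentation.json` schema, version 1.0: angles,
#'   indices, scores, bounding boxes and mask fractions per tooth).
#' @export
segment_bitewing <- function(src, config = segment_config(),
                             bitewing_id = "bitewing") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("segmentation stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  src <- as_radiograph(src)
  if (min(src) == max(src))
    stop("segmentation stage 'preprocess': image has no content",
         call. = FALSE)
  pre <- stage("preprocess",
               preprocess_bitewing(src, config$cutoff, config$mode,
                                   config$denominator))
  if (sum(pre$binary) == 0)
    stop("segmentation stage 'preprocess': image has no foreground content",
         call. = FALSE)
  row_sep <- stage("row_separator",
                   find_row_separator(pre$binary, config$angle_range,
                                      config$step))
  parts <- stage("split_rows", split_rows(src, pre$binary, row_sep))

  halves <- list()
  report_rows <- list()
  for (rn in c("upper", "lower")) {
    row_img <- if (rn == "upper") parts$upper else parts$lower
    row_bin <- if (rn == "upper") parts$upper_bin else parts$lower_bin
    if (sum(row_bin) == 0) {
      report_rows[[rn]] <- list(n_teeth = 0L, separators = list(),
                                teeth = list())
      next
    }
    mtw <- max(2L, round(config$min_tooth_width_frac * ncol(row_bin)))
    seps <- stage(paste0(rn, "_tooth_separators"),
                  find_tooth_separators(row_bin, config$angle_range,
                                        config$step, mtw,
                                        config$valley_ceiling))
    n_teeth <- length(seps) + 1L
    teeth_rep <- vector("list", n_teeth)
    for (m in seq_len(n_teeth)) {
      left <- if (m > 1L) seps[[m - 1L]] else NULL
      right <- if (m <= length(seps)) seps[[m]] else NULL
      crop <- stage(paste0(rn, "_crop"),
                    crop_and_mask(row_img, left, right, row = rn))
      pair <- split_halves(crop, bitewing_id, tooth = m)
      halves <- c(halves, pair)
      teeth_rep[[m]] <- list(tooth = m, bbox = unname(crop$bbox),
                             mask_fraction = crop$mask_fraction)
    }
    report_rows[[rn]] <- list(
      n_teeth = n_teeth,
      separators = lapply(seps, function(s)
        list(angle = s$angle, index = s$index, score = s$score,
             center = s$center)),
      teeth = teeth_rep)
  }

  report <- list(
    schema_version = "1.0",
    bitewing_id = bitewing_id,
    image_extent = dim(src),
    config = unclass(config),
    row_separator = list(angle = row_sep$angle, index = row_sep$index,
                         score = row_sep$score),
    rows = report_rows)
  structure(list(halves = halves, report = report),
            class = "bitewing_segmentation")
}

#' @export
print.bitewing_segmentation <- function(x, ...) {
  cat(sprintf("Bitewing segmentation '%s'\n", x$report$bitewing_id))
  cat(sprintf("  row separator: angle %+.1f deg at row %d\n",
              x$report$row_separator$angle, x$report$row_separator$index))
  cat(sprintf("  teeth: %d upper, %d lower -> %d half-tooth images\n",
              x$report$rows$upper$n_teeth, x$report$rows$lower$n_teeth,
              length(x$halves)))
  invisible(x)
}

#' Write segmentation outputs to disk
#'
#' Writes each half-tooth image as
#' `DIR/{upper,lower}/tooth_{k}_{left,right}.png` and the run report as
#' `DIR/segmentation.json` (schema version 1.0).
#'
#' @param seg A `"bitewing_segmentation"` from [segment_bitewing()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "bitewing_segmentation"))
  for (rn in c("upper", "lower"))
    dir.create(file.path(dir, rn), recursive = TRUE, showWarnings = FALSE)
  for (h in seg$halves)
    write_radiograph(h$image,
                     file.path(dir, h$row,
                               sprintf("tooth_%d_%s.png", h$tooth, h$side)))
  jsonlite::write_json(seg$report, file.path(dir, "segmentation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
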