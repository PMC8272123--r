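#' Score a segmentation against synthetic ground truth
#'
#' Compares a [segment_bitewing()] result with the ground truth of the
#' [generate_bitewing()] scene it was run on: the row-separator angle
#' error (the recovered angle should cancel the applied scene rotation),
#' the tooth counts, and for every ground-truth interdental gap whether
#' some detected separating line passes through it.
#'
#' Separating lines live in rotated frames, so each line is sampled
#' along the row image's height, mapped back into pre-rotation scene
#' coordinates by undoing the composed rotation (scene rotation plus
#' recovered row angle, both about the image center), and counted as a
#' hit if any sampled point falls inside the gap's column interval
#' within the rows spanned by the two adjacent crowns.
#'
#' @param seg A `"bitewing_segmentation"`.
#' @param truth The `truth` component of [generate_bitewing()].
#' @return A list with `angle_error` (degrees), `teeth_true`,
#'   `teeth_detected`, `gaps_total`, `gaps_hit`.
#' @export
segmentation_recovery <- function(seg, truth) {
  stopifnot(inherits(seg, "bitewing_segmentation"))
  rep <- seg$report
  H <- rep$image_extent[1L]; W <- rep$image_extent[2L]
  center <- c((H + 1) / 2, (W + 1) / 2)
  total_angle <- truth$rotation + rep$row_separator$angle
  a <- -total_angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  row_off <- c(upper = 0L, lower = rep$row_separator$index - 1L)

  gaps_total <- 0L; gaps_hit <- 0L
  for (rn in c("upper", "lower")) {
    b <- truth$boundaries[[rn]]
    if (nrow(b) == 0L) next
    teeth <- truth$teeth[truth$teeth$row == rn, ]
    seps <- seg$report$rows[[rn]]$separators
    h_row <- if (rn == "upper") rep$row_separator$index - 1L else
      H - rep$row_separator$index + 1L
    # sample each line through the row image, in pre-rotation coords
    pts <- lapply(seps, function(s) {
      line <- separator_line(s$angle, s$index, s$score, "column", s$center)
      i_row <- seq_len(h_row)
      jj <- line_column_at_row(line, i_row)
      ii_full <- i_row + row_off[[rn]]
      di <- ii_full - center[1L]; dj <- jj - center[2L]
      cbind(i = center[1L] + ca * di - sa * dj,
            j = center[2L] + sa * di + ca * dj)
    })
    for (k in seq_len(nrow(b))) {
      gaps_total <- gaps_total + 1L
      rt <- max(teeth$top[k], teeth$top[k + 1L])
      rb <- min(teeth$bottom[k], teeth$bottom[k + 1L])
      # one pixel of slop: bilinear rotation has 1-px support and the
      # truth band is recorded on the integer grid, so a line through
      # the crown-boundary transition pixel still separates the teeth
      hit <- any(vapply(pts, function(p)
        any(p[, "i"] >= rt & p[, "i"] <= rb &
              p[, "j"] >= b[k, "from"] - 1 &
              p[, "j"] <= b[k, "to"] + 1), logical(1)))
      if (hit) gaps_hit <- gaps_hit + 1L
    }
  }
  list(angle_error = abs(rep$row_separator$angle + truth$rotation),
       teeth_true = nrow(truth$teeth),
       teeth_detected = rep$rows$upper$n_teeth + rep$rows$lower$n_teeth,
       gaps_total = gaps_total, gaps_hit = gaps_hit)
}
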