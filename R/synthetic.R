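#' Synthetic bitewing scene specification
#'
#' Describes a synthetic bitewing-like radiograph: a dark background, a
#' mid-intensity alveolar band supporting each tooth, and two rows of
#' bright crowns separated by an occlusal gap, with optional global
#' rotation, bright restoration blobs and dark caries notches. The
#' default intensity bands (background 15, alveolar bone 100, teeth
#' 180, noise sd 8) reproduce the three-part intensity structure of
#' clinical bitewings -- background close to 0, alveolar bone at an
#' averaged value, teeth above 120 -- and are separated by at least 3
#' noise standard deviations so that Otsu binarization is well posed.
#'
#' @param rows,cols Image extent in pixels.
#' @param teeth_per_row Integer count or length-2 range; the count is
#'   drawn per row when a range is given.
#' @param gap_width Length-2 integer range of interdental gap widths
#'   (pixels).
#' @param global_rotation Rotation applied to the whole scene (degrees,
#'   see [rotate_image()] for the sign convention).
#' @param background,alveolar,tooth Mean intensities of the three bands.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (clipped to `[0, 255]`).
#' @param p_restoration,p_caries Per tooth-half probability of a
#'   restoration blob / caries notch.
#' @param restoration_intensity Intensity of restoration blobs
#'   (radiopaque, at least 240).
#' @param caries_intensity Intensity of caries notches (radiolucent,
#'   at most 80).
#' @param seed Integer seed; generation is fully deterministic given
#'   the spec.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(rows = 320, cols = 480, teeth_per_row = c(4, 8),
                       gap_width = c(8, 14), global_rotation = 0,
                       background = 15, alveolar = 100, tooth = 180,
                       noise_sd = 8, p_restoration = 0, p_caries = 0,
                       restoration_intensity = 250, caries_intensity = 60,
                       seed = 1) {
  stopifnot(rows >= 100, cols >= 100)
  if (!(background < alveolar && alveolar < tooth))
    stop("intensity bands must be ordered background < alveolar < tooth",
         call. = FALSE)
  if (alveolar - background < 3 * noise_sd || tooth - alveolar < 3 * noise_sd)
    stop("intensity bands must be separated by at least 3 noise sd",
         call. = FALSE)
  if (tooth <= 120)
    stop("tooth intensity must exceed 120", call. = FALSE)
  if (restoration_intensity < 240 || caries_intensity > 80)
    stop("lesion intensities must satisfy restoration >= 240, caries <= 80",
         call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 teeth_per_row = as.integer(teeth_per_row),
                 gap_width = as.integer(gap_width),
                 global_rotation = global_rotation,
                 background = background, alveolar = alveolar, tooth = tooth,
                 noise_sd = noise_sd,
                 p_restoration = p_restoration, p_caries = p_caries,
                 restoration_intensity = restoration_intensity,
                 caries_intensity = caries_intensity,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

sample_count <- function(range) {
  if (length(range) == 1L) return(range)
  sample(seq(range[1L], range[2L]), 1L)
}

# superellipse crown mask on a local grid (rounded-rectangle shape)
crown_mask <- function(nr, nc, exponent = 2.5) {
  a <- nr / 2; b <- nc / 2 - 0.5
  di <- (seq_len(nr) - (nr + 1) / 2) / a
  dj <- (seq_len(nc) - (nc + 1) / 2) / b
  outer(abs(di)^exponent, abs(dj)^exponent, `+`) <= 1
}

# draw a disk of given intensity clipped to a mask, in-place on canvas
draw_disk <- function(canvas, mask_rows, mask_cols, crown, ci, cj, r, value) {
  rr <- seq(max(mask_rows[1L], ci - r), min(mask_rows[2L], ci + r))
  cc <- seq(max(mask_cols[1L], cj - r), min(mask_cols[2L], cj + r))
  d <- outer((rr - ci)^2, (cc - cj)^2, `+`) <= r^2
  inside <- crown[rr - mask_rows[1L] + 1L, cc - mask_cols[1L] + 1L, drop = FALSE]
  sel <- d & inside
  block <- canvas[rr, cc, drop = FALSE]
  block[sel] <- value
  canvas[rr, cc] <- block
  canvas
}

#' Generate one synthetic bitewing with exhaustive ground truth
#'
#' Draws two rows of superellipse crowns on alveolar pedestals over a
#' dark background, plants optional per-half lesions, adds clipped
#' Gaussian noise, and finally rotates the whole scene. Ground truth is
#' recorded in pre-rotation coordinates: the occlusal row-gap band, the
#' interdental gap column intervals per row, per-tooth bounding boxes,
#' per-half finding labels, and the pre-rotation noisy canvas itself
#' (so clean half-tooth crops can be extracted without re-running the
#' segmentation).
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (the rotated scene) and `truth`, a list
#'   with `row_gap` (`c(top, bottom)` rows), `rotation`, `boundaries`
#'   (per row, a matrix of gap column intervals `(from, to)`), `teeth`
#'   (data frame of bounding boxes), `labels` (data frame with one row
#'   per tooth half) and `canvas` (the pre-rotation image).
#' @export
generate_bitewing <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    rows <- spec$rows; cols <- spec$cols
    margin_x <- round(0.04 * cols)
    alv_top <- round(0.03 * rows)
    # narrow occlusal gap: its height bounds the set of zero-mass
    # separating angles, keeping the minimizing angle identifiable to
    # about the 1-degree sweep step at typical bitewing aspect ratios
    gap_half <- max(3L, round(0.01 * rows))
    gap_center <- round(rows / 2)
    row_gap <- c(gap_center - gap_half, gap_center + gap_half)

    layout_row <- function(n) {
      usable <- cols - 2L * margin_x
      gaps <- if (n > 1L)
        sample(seq(spec$gap_width[1L], spec$gap_width[2L]), n - 1L,
               replace = TRUE) else integer(0)
      rem <- usable - sum(gaps)
      wts <- stats::runif(n, 0.85, 1.15)
      widths <- floor(rem * wts / sum(wts))
      widths[n] <- rem - sum(widths[-n])
      if (any(widths < 16L))
        stop("infeasible scene geometry: teeth do not fit", call. = FALSE)
      starts <- margin_x + 1L + c(0L, cumsum(widths[-n] + gaps))
      list(starts = starts, widths = widths,
           boundaries = if (n > 1L)
             cbind(from = starts[-n] + widths[-n],
                   to = starts[-1L] - 1L) else
             matrix(integer(0), 0, 2,
                    dimnames = list(NULL, c("from", "to"))))
    }

    canvas <- matrix(spec$background, rows, cols)
    teeth <- list(); labels <- list(); boundaries <- list()

    for (rn in c("upper", "lower")) {
      n <- sample_count(spec$teeth_per_row)
      lay <- layout_row(n)
      boundaries[[rn]] <- lay$boundaries
      for (m in seq_len(n)) {
        wdt <- lay$widths[m]; start <- lay$starts[m]; end <- start + wdt - 1L
        ch <- round(stats::runif(1, 0.27, 0.33) * rows)
        if (rn == "upper") {
          crown_bottom <- row_gap[1L] - 1L
          crown_top <- crown_bottom - ch + 1L
          ped <- c(alv_top, crown_top + round(0.15 * ch))
        } else {
          crown_top <- row_gap[2L] + 1L
          crown_bottom <- crown_top + ch - 1L
          ped <- c(crown_bottom - round(0.15 * ch), rows - alv_top)
        }
        if (crown_top < alv_top + 5L || crown_bottom > rows - alv_top - 5L)
          stop("infeasible scene geometry: crowns exceed the image",
               call. = FALSE)
        canvas[seq(ped[1L], ped[2L]), seq(start + 2L, end - 2L)] <-
          spec$alveolar
        cm <- crown_mask(ch, wdt)
        block <- canvas[seq(crown_top, crown_bottom), seq(start, end),
                        drop = FALSE]
        block[cm] <- spec$tooth
        canvas[seq(crown_top, crown_bottom), seq(start, end)] <- block

        mid <- ceiling(wdt / 2)
        half_cols <- list(left = c(start, start + mid - 1L),
                          right = c(start + mid, end))
        for (side in c("left", "right")) {
          hc <- half_cols[[side]]
          has_rest <- stats::runif(1) < spec$p_restoration
          has_car <- stats::runif(1) < spec$p_caries
          place <- function(value, near_occlusal) {
            r <- sample(5:8, 1L)
            r <- min(r, floor((hc[2L] - hc[1L]) / 2) - 2L,
                     floor(ch / 2) - 4L)
            if (r < 3L) return(FALSE)
            cj <- round(stats::runif(1, hc[1L] + r + 1, hc[2L] - r - 1))
            ci <- if (near_occlusal) {
              if (rn == "upper") crown_bottom - r - 4L else crown_top + r + 4L
            } else {
              round(stats::runif(1, crown_top + r + 5, crown_bottom - r - 5))
            }
            canvas <<- draw_disk(canvas, c(crown_top, crown_bottom),
                                 c(start, end), cm, ci, cj, r, value)
            TRUE
          }
          if (has_rest) has_rest <- place(spec$restoration_intensity, TRUE)
          if (has_car) has_car <- place(spec$caries_intensity, FALSE)
          labels[[length(labels) + 1L]] <-
            data.frame(row = rn, tooth = m, side = side,
                       caries = has_car, restoration = has_rest)
        }
        teeth[[length(teeth) + 1L]] <-
          data.frame(row = rn, tooth = m, top = crown_top, left = start,
                     bottom = crown_bottom, right = end)
      }
    }

    canvas <- clip255(canvas + matrix(stats::rnorm(rows * cols,
                                                   sd = spec$noise_sd),
                                      rows, cols))
    image <- if (spec$global_rotation != 0)
      rotate_image(canvas, spec$global_rotation, "bilinear") else canvas
    list(image = image,
         truth = list(row_gap = row_gap, rotation = spec$global_rotation,
                      boundaries = boundaries,
                      teeth = do.call(rbind, teeth),
                      labels = do.call(rbind, labels),
                      canvas = canvas))
  })
}

#' Generate a single synthetic half-tooth image
#'
#' Draws half of a crown (the cut edge on the image's right border for a
#' left half) over a dark background, with an optional lesion, and adds
#' clipped Gaussian noise. These images emulate what
#' [segment_bitewing()] emits and feed the database and classifier
#' modules directly.
#'
#' @param finding `"normal"`, `"caries"`, `"restoration"` or `"both"`.
#' @param seed Integer seed.
#' @param rows,cols Image extent (native, pre-standardization).
#' @param spec A [scene_spec()] providing the intensity bands.
#' @return A list with `image` (matrix), `findings` (character vector,
#'   possibly empty) and `id`.
#' @export
generate_half_tooth <- function(finding = c("normal", "caries",
                                            "restoration", "both"),
                                seed = 1, rows = 120, cols = 56,
                                spec = scene_spec()) {
  finding <- match.arg(finding)
  withr::with_seed(seed, {
    full <- matrix(spec$background, rows, 2L * cols)
    ch <- round(stats::runif(1, 0.75, 0.9) * rows)
    cw <- round(stats::runif(1, 0.75, 0.9) * 2 * cols)
    top <- round((rows - ch) / 2); left <- round((2 * cols - cw) / 2)
    cm <- crown_mask(ch, cw)
    block <- full[seq(top + 1L, top + ch), seq(left + 1L, left + cw),
                  drop = FALSE]
    block[cm] <- spec$tooth
    full[seq(top + 1L, top + ch), seq(left + 1L, left + cw)] <- block
    place <- function(value) {
      r <- max(2L, min(sample(5:8, 1L), floor((cw / 2 - 4) / 2),
                       floor((ch - 8) / 2)))
      rand_in <- function(lo, hi)
        if (hi > lo) round(stats::runif(1, lo, hi)) else round((lo + hi) / 2)
      # keep lesions on the crown body (middle rows, off the cut edge)
      # where the superellipse is wide, so the disk is not clipped away
      ci <- rand_in(top + max(r + 4, 0.25 * ch), top + min(ch - r - 4,
                                                           0.75 * ch))
      cj <- rand_in(left + max(r + 2, 0.15 * cw), left + cw / 2 - r)
      full <<- draw_disk(full, c(top + 1L, top + ch), c(left + 1L, left + cw),
                         cm, ci, cj, r, value)
    }
    if (finding %in% c("restoration", "both")) place(spec$restoration_intensity)
    if (finding %in% c("caries", "both")) place(spec$caries_intensity)
    img <- clip255(full[, seq_len(cols)] +
                     matrix(stats::rnorm(rows * cols, sd = spec$noise_sd),
                            rows, cols))
    findings <- switch(finding, normal = character(0), caries = "caries",
                       restoration = "restoration",
                       both = c("caries", "restoration"))
    list(image = img, findings = findings,
         id = sprintf("half_%s_%d", finding, seed))
  })
}

#' Generate a labeled corpus of half-tooth images
#'
#' Generates `n` synthetic bitewings (rotations and tooth counts drawn
#' per image), extracts every ground-truth half-tooth crop from the
#' pre-rotation canvas, and labels each half by drawing findings with
#' the given prevalences. The defaults reproduce the class imbalance of
#' the study population this package models: about 16.4% of tooth
#' halves carry a restoration and about 2.4% a caries lesion
#' (610 and 88 of 3716).
#'
#' @param n Number of bitewings (at least 1).
#' @param teeth_per_row,rotation_range Ranges sampled per image.
#' @param p_restoration,p_caries Per-half finding prevalences.
#' @param seed Integer seed.
#' @param dir Optional output directory; if given, half images are
#'   written as PNGs together with `labels.csv`
#'   (`image,finding_caries,finding_restoration`) and
#'   `ground_truth.json`.
#' @param ... Further arguments passed to [scene_spec()].
#' @return A list with `samples` (list of labeled samples, each with
#'   `image`, `findings`, `id`, `source`) and `labels` (data frame).
#' @export
generate_corpus <- function(n, teeth_per_row = c(4, 8),
                            rotation_range = c(-10, 10),
                            p_restoration = 610 / 3716,
                            p_caries = 88 / 3716,
                            seed = 1, dir = NULL, ...) {
  stopifnot(n >= 1)
  draws <- withr::with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max, n),
    rots = stats::runif(n, rotation_range[1L], rotation_range[2L])))
  samples <- list(); truths <- list()
  for (i in seq_len(n)) {
    sp <- scene_spec(teeth_per_row = teeth_per_row,
                     global_rotation = draws$rots[i],
                     p_restoration = p_restoration, p_caries = p_caries,
                     seed = draws$seeds[i], ...)
    gb <- generate_bitewing(sp)
    tr <- gb$truth
    for (k in seq_len(nrow(tr$teeth))) {
      tt <- tr$teeth[k, ]
      crop <- tr$canvas[tt$top:tt$bottom, tt$left:tt$right, drop = FALSE]
      mid <- ceiling(ncol(crop) / 2)
      for (side in c("left", "right")) {
        img <- if (side == "left") crop[, seq_len(mid), drop = FALSE]
               else crop[, seq(mid + 1L, ncol(crop)), drop = FALSE]
        lab <- tr$labels[tr$labels$row == tt$row & tr$labels$tooth == tt$tooth &
                           tr$labels$side == side, ]
        id <- sprintf("bw%04d_%s_t%02d_%s", i, tt$row, tt$tooth, side)
        samples[[length(samples) + 1L]] <- list(
          image = img,
          findings = c("caries", "restoration")[c(lab$caries, lab$restoration)],
          id = id, source = id)
      }
    }
    truths[[i]] <- list(bitewing = i, rotation = tr$rotation,
                        row_gap = tr$row_gap, boundaries = tr$boundaries,
                        teeth = tr$teeth, labels = tr$labels)
  }
  labels <- data.frame(
    image = vapply(samples, `[[`, character(1), "id"),
    finding_caries = vapply(samples, function(s) "caries" %in% s$findings,
                            logical(1)),
    finding_restoration = vapply(samples,
                                 function(s) "restoration" %in% s$findings,
                                 logical(1)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples)
      write_radiograph(s$image, file.path(dir, paste0(s$id, ".png")))
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(samples = samples, labels = labels)
}

#' Generate a half-tooth pool with fixed per-finding counts
#'
#' Builds a pool of labeled half-tooth images with exactly the given
#' number of restoration, caries and normal samples (the defaults are
#' the class counts of the clinical population this package models:
#' 610 restorations, 88 caries, 3018 normal, 3716 in all). Useful for
#' exercising database balancing under a realistic class imbalance.
#'
#' @param n_restoration,n_caries,n_normal Sample counts per class.
#' @param seed Integer seed.
#' @param rows,cols Native half-image extent.
#' @return A list of labeled samples (`image`, `findings`, `id`,
#'   `source`), shuffled deterministically.
#' @export
generate_finding_pool <- function(n_restoration = 610, n_caries = 88,
                                  n_normal = 3018, seed = 1,
                                  rows = 120, cols = 56) {
  kinds <- c(rep("restoration", n_restoration), rep("caries", n_caries),
             rep("normal", n_normal))
  n <- length(kinds)
  withr::with_seed(seed, {
    kinds <- sample(kinds)
    seeds <- sample.int(.Machine$integer.max, n)
  })
  lapply(seq_len(n), function(i) {
    s <- generate_half_tooth(kinds[i], seed = seeds[i], rows = rows,
                             cols = cols)
    s$id <- sprintf("pool_%05d_%s", i, kinds[i])
    s$source <- s$id
    s
  })
}
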