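#' Standardize a half-tooth image to 200 x 100 pixels
#'
#' Resamples the image to 200 rows by 100 columns with bilinear
#' interpolation (teeth are taller than wide, so rows are the long
#' axis), trading resolution for a fixed classifier input extent.
#'
#' @param img Intensity matrix (or a `"half_tooth"` object).
#' @return A 200 x 100 intensity matrix in `[0, 255]`.
#' @export
standardize_half_image <- function(img) {
  if (inherits(img, "half_tooth")) img <- img$image
  if (is.null(dim(img)) || nrow(img) < 1L || ncol(img) < 1L)
    stop("cannot standardize an empty image", call. = FALSE)
  resize_bilinear(img, 200L, 100L)
}

#' Contrast enhancement for standardized half images
#'
#' `"stretch"` maps the 2nd and 98th intensity percentiles linearly onto
#' `[0, 255]` (clipping the tails); `"equalize"` applies histogram
#' equalization. Either highlights radiopaque restorations against the
#' crown. A constant image is returned unchanged.
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @param method `"stretch"` or `"equalize"`.
#' @return Enhanced matrix, same extent, values in `[0, 255]`.
#' @export
enhance_contrast <- function(img, method = c("stretch", "equalize")) {
  method <- match.arg(method)
  if (min(img) == max(img)) return(img)
  if (method == "stretch") {
    p <- stats::quantile(img, c(0.02, 0.98), names = FALSE)
    if (p[2L] <= p[1L]) return(img)
    clip255((img - p[1L]) * 255 / (p[2L] - p[1L]))
  } else {
    out <- EBImage::equalize(EBImage::Image(t(img) / 255),
                             range = c(0, 1), levels = 256)
    clip255(t(EBImage::imageData(out)) * 255)
  }
}

#' Randomly augment a half-tooth image
#'
#' Applies a randomly parameterized composition of the transform
#' families used to enlarge the minority class: vertical and horizontal
#' flips (each with probability `flip_prob`), rotation, zoom about the
#' center, translation, contrast gain about mid-gray, and brightness
#' shift. The output keeps the input extent and the `[0, 255]` range,
#' and is fully determined by `seed`. The drawn parameters are attached
#' as the `"augment_params"` attribute for the augmentation log.
#'
#' @param img 200 x 100 (or any) intensity matrix.
#' @param seed Integer seed.
#' @param zoom Length-2 zoom factor range (default +/-10%).
#' @param rotation Length-2 rotation range in degrees (default +/-10).
#' @param translation Length-2 translation range in pixels, drawn
#'   independently per axis (default +/-10).
#' @param contrast Length-2 contrast gain range (default 0.8-1.2).
#' @param brightness Length-2 brightness shift range (default +/-20).
#' @param flip_prob Probability of each flip (default 0.5).
#' @return Transformed matrix with attribute `"augment_params"`.
#' @export
augment_image <- function(img, seed, zoom = c(0.9, 1.1),
                          rotation = c(-10, 10), translation = c(-10, 10),
                          contrast = c(0.8, 1.2), brightness = c(-20, 20),
                          flip_prob = 0.5) {
  pars <- withr::with_seed(seed, list(
    flip_v = stats::runif(1) < flip_prob,
    flip_h = stats::runif(1) < flip_prob,
    rotation = stats::runif(1, rotation[1L], rotation[2L]),
    zoom = stats::runif(1, zoom[1L], zoom[2L]),
    shift = round(stats::runif(2, translation[1L], translation[2L])),
    gain = stats::runif(1, contrast[1L], contrast[2L]),
    brightness = stats::runif(1, brightness[1L], brightness[2L])))
  apply_augmentation(img, pars)
}

# deterministic application of a drawn parameter set
apply_augmentation <- function(img, pars) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  if (isTRUE(pars$flip_v)) out <- out[rev(seq_len(h)), , drop = FALSE]
  if (isTRUE(pars$flip_h)) out <- out[, rev(seq_len(w)), drop = FALSE]
  if (pars$rotation != 0) out <- rotate_image(out, pars$rotation, "bilinear")
  if (pars$zoom != 1) {
    zh <- max(2L, round(h * pars$zoom)); zw <- max(2L, round(w * pars$zoom))
    z <- resize_bilinear(out, zh, zw)
    out <- matrix(0, h, w)
    ri <- seq_len(min(h, zh)); ci <- seq_len(min(w, zw))
    off_r <- floor(abs(zh - h) / 2); off_c <- floor(abs(zw - w) / 2)
    if (zh >= h && zw >= w) {
      out <- z[off_r + seq_len(h), off_c + seq_len(w), drop = FALSE]
    } else {
      out[floor((h - zh) / 2) + ri, floor((w - zw) / 2) + ci] <- z[ri, ci]
    }
  }
  if (any(pars$shift != 0))
    out <- translate_image(out, pars$shift[1L], pars$shift[2L])
  if (pars$gain != 1 || pars$brightness != 0)
    out <- clip255((out - 127.5) * pars$gain + 127.5 + pars$brightness)
  attr(out, "augment_params") <- pars
  out
}

#' Build a balanced per-finding database
#'
#' Turns a pool of labeled half-tooth samples into one balanced binary
#' database for a single finding. Positives (samples whose finding set
#' contains `finding`) are augmented with randomly transformed copies
#' ([augment_image()]) up to `target_count` when scarce, or subsampled
#' without replacement down to `target_count` when abundant; negatives
#' are subsampled to `target_count`. Every image is standardized to
#' 200 x 100 ([standardize_half_image()]) and contrast-enhanced. The
#' result holds `2 * target_count` images with full provenance: each
#' augmented copy records its source sample and transform parameters.
#'
#' @param samples List of labeled samples; each element needs `image`
#'   (matrix), `findings` (character vector over
#'   `c("caries", "restoration")`) and `id`.
#' @param finding `"caries"` or `"restoration"`.
#' @param target_count Images per class after balancing (default 350).
#' @param seed Integer seed driving selection and augmentation.
#' @param enhance Contrast enhancement method (`"stretch"`,
#'   `"equalize"` or `"none"`).
#' @return An object of class `"finding_database"`: a list with
#'   `finding`, `positives` and `negatives` (lists of 200 x 100
#'   matrices), `pos_meta` and `neg_meta` (data frames: `id`, `source`,
#'   `augmented`), `augmentation_log`, and (after [split_dataset()]) a
#'   `split` assignment.
#' @export
balance_database <- function(samples, finding = c("caries", "restoration"),
                             target_count = 350, seed = 1,
                             enhance = c("stretch", "equalize", "none")) {
  finding <- match.arg(finding)
  enhance <- match.arg(enhance)
  is_pos <- vapply(samples, function(s) finding %in% s$findings, logical(1))
  pos <- samples[is_pos]; neg <- samples[!is_pos]
  if (length(pos) == 0L)
    stop("cannot build a database with zero positive samples", call. = FALSE)
  if (length(neg) < target_count)
    stop(sprintf("need at least %d negative samples, have %d",
                 target_count, length(neg)), call. = FALSE)

  prep <- function(img) {
    out <- standardize_half_image(img)
    if (enhance != "none") out <- enhance_contrast(out, enhance)
    out
  }

  draws <- withr::with_seed(seed, {
    n_aug <- max(0L, target_count - length(pos))
    list(pos_keep = if (length(pos) > target_count)
           sort(sample.int(length(pos), target_count)) else
           seq_along(pos),
         aug_src = if (n_aug > 0L)
           sample.int(length(pos), n_aug, replace = TRUE) else integer(0),
         aug_seeds = if (n_aug > 0L)
           sample.int(.Machine$integer.max, n_aug) else integer(0),
         neg_keep = sort(sample.int(length(neg), target_count)))
  })

  pos_imgs <- lapply(pos[draws$pos_keep], function(s) prep(s$image))
  pos_meta <- data.frame(
    id = vapply(pos[draws$pos_keep], `[[`, character(1), "id"),
    source = vapply(pos[draws$pos_keep], `[[`, character(1), "id"),
    augmented = FALSE)
  aug_log <- list()
  for (k in seq_along(draws$aug_src)) {
    src <- pos[[draws$aug_src[k]]]
    aug <- augment_image(prep(src$image), seed = draws$aug_seeds[k])
    aug_id <- sprintf("%s_aug%03d", src$id, k)
    aug_log[[aug_id]] <- attr(aug, "augment_params")
    attr(aug, "augment_params") <- NULL
    pos_imgs[[length(pos_imgs) + 1L]] <- aug
    pos_meta <- rbind(pos_meta,
                      data.frame(id = aug_id, source = src$id,
                                 augmented = TRUE))
  }
  neg_imgs <- lapply(neg[draws$neg_keep], function(s) prep(s$image))
  neg_meta <- data.frame(
    id = vapply(neg[draws$neg_keep], `[[`, character(1), "id"),
    source = vapply(neg[draws$neg_keep], `[[`, character(1), "id"),
    augmented = FALSE)

  structure(list(finding = finding, target_count = as.integer(target_count),
                 positives = pos_imgs, negatives = neg_imgs,
                 pos_meta = pos_meta, neg_meta = neg_meta,
                 augmentation_log = aug_log, split = NULL, seed = seed),
            class = "finding_database")
}

#' @export
print.finding_database <- function(x, ...) {
  cat(sprintf("Finding database: %s\n", x$finding))
  cat(sprintf("  %d positives (%d augmented) + %d negatives = %d images\n",
              length(x$positives), sum(x$pos_meta$augmented),
              length(x$negatives),
              length(x$positives) + length(x$negatives)))
  if (!is.null(x$split))
    print(table(x$split$split, x$split$class))
  invisible(x)
}

#' Assign train / validation / test splits
#'
#' Splits a balanced database, stratified by class: a fraction
#' `train_frac` of each class goes to the training pool (of which
#' `val_frac_within_train` becomes the validation set) and the rest to
#' the test set. Assignment is made at the provenance-group level --
#' an augmented copy is never placed in a different split than its
#' source image, which rules out train/test leakage. Original
#' (non-augmented) images are preferred when filling the test set;
#' only if a class has too few originals are whole provenance groups
#' (source plus copies) moved into the test set to fill the quota.
#'
#' @param db A `"finding_database"` from [balance_database()].
#' @param train_frac Fraction per class assigned to train+validation
#'   (default 0.7; must be strictly between 0 and 1).
#' @param val_frac_within_train Fraction of the training pool used for
#'   validation (default 0.2).
#' @param seed Integer seed.
#' @return `db` with a `split` data frame (`id`, `source`, `class`,
#'   `augmented`, `split`).
#' @export
split_dataset <- function(db, train_frac = 0.7, val_frac_within_train = 0.2,
                          seed = 1) {
  stopifnot(inherits(db, "finding_database"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1 (empty split)",
         call. = FALSE)

  assign_class <- function(meta, cls, rng_offset) {
    n <- nrow(meta)
    n_test <- round(n * (1 - train_frac))
    if (n_test < 1L || n - n_test < 2L)
      stop("database too small to fill all splits", call. = FALSE)
    split <- rep(NA_character_, n)
    withr::with_seed(seed + rng_offset, {
      groups <- split(seq_len(n), meta$source)
      gsize <- vapply(groups, length, integer(1))
      originals_alone <- names(groups)[gsize == 1L]
      originals_alone <- sample(originals_alone)
      test_n <- 0L
      for (g in originals_alone) {
        if (test_n >= n_test) break
        split[groups[[g]]] <- "test"
        test_n <- test_n + 1L
      }
      if (test_n < n_test) {
        multi <- sample(names(groups)[gsize > 1L])
        for (g in multi) {
          if (test_n >= n_test) break
          split[groups[[g]]] <- "test"
          test_n <- test_n + length(groups[[g]])
        }
      }
      rest_groups <- names(groups)[vapply(groups, function(ix)
        all(is.na(split[ix])), logical(1))]
      n_rest <- sum(is.na(split))
      n_val <- round(n_rest * val_frac_within_train)
      val_n <- 0L
      for (g in sample(rest_groups)) {
        if (val_n >= n_val) break
        split[groups[[g]]] <- "validation"
        val_n <- val_n + length(groups[[g]])
      }
      split[is.na(split)] <- "train"
    })
    if (!all(c("train", "validation", "test") %in% split))
      stop("database too small to fill all splits", call. = FALSE)
    data.frame(id = meta$id, source = meta$source, class = cls,
               augmented = meta$augmented, split = split)
  }

  db$split <- rbind(assign_class(db$pos_meta, "positive", 0L),
                    assign_class(db$neg_meta, "negative", 1L))
  db
}

#' Write a finding database to disk
#'
#' Writes the per-finding directory tree
#' `finding/{pos,neg}/{train,validation,test}/` of PNGs plus
#' `database_manifest.json` holding the split assignment and the
#' augmentation log.
#'
#' @param db A split `"finding_database"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_finding_database <- function(db, dir) {
  stopifnot(inherits(db, "finding_database"))
  if (is.null(db$split)) stop("run split_dataset() first", call. = FALSE)
  imgs <- c(db$positives, db$negatives)
  ids <- c(db$pos_meta$id, db$neg_meta$id)
  for (k in seq_along(imgs)) {
    row <- db$split[db$split$id == ids[k], ]
    sub <- file.path(dir, db$finding,
                     if (row$class == "positive") "pos" else "neg",
                     row$split)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    write_radiograph(imgs[[k]], file.path(sub, paste0(ids[k], ".png")))
  }
  jsonlite::write_json(
    list(finding = db$finding, target_count = db$target_count,
         split = db$split, augmentation_log = db$augmentation_log),
    file.path(dir, "database_manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
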