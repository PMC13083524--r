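#' @title Slide tiling and tissue filtering
#'
#' @description
#' Slides are cut into a non-overlapping grid of square patches (partial
#' edge tiles dropped so every patch has identical shape), tissue content
#' is estimated per patch against a slide-level Otsu threshold (stained
#' tissue is darker than the glass background), patches with more than 90%
#' tissue are kept, and the per-patient patch budget is equalized across
#' the cohort at the minimum valid-patch count.
#'
#' @name wsi-tiling
NULL

slide_gray <- function(slide) {
  d <- dim(slide)
  if (is.null(d) || length(d) == 2L) return(slide)
  if (length(d) == 3L) {
    return((slide[, , 1] + slide[, , 2] + slide[, , 3]) / 3)
  }
  stop("slide must be a 2-D or (h, w, 3) array")
}

#' Tile a slide into square patches
#'
#' Non-overlapping, row-major grid; edge remainders that cannot fill a
#' complete patch are dropped. Grid coordinates are 0-based with origin at
#' the top-left; `pixel_origin` is `(row, col) * patch_size`.
#'
#' @param slide 2-D matrix or `(h, w, 3)` array of intensities in `0..255`.
#' @param patch_size tile side in pixels (default 256).
#' @param patient_id carried onto each patch.
#' @return List of `patch` objects (fields `patient_id`, `row_index`,
#'   `col_index`, `pixel_origin`, `image`, `tissue_fraction` = NA until
#'   scored).
#' @export
tile_slide <- function(slide, patch_size = 256L, patient_id = "unknown") {
  d <- dim(slide)
  h <- d[1]; w <- d[2]
  if (h < patch_size || w < patch_size) {
    stop(sprintf("slide %dx%d is smaller than one %d-pixel patch",
                 h, w, patch_size))
  }
  nr <- h %/% patch_size
  nc <- w %/% patch_size
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      rr <- (r - 1L) * patch_size + seq_len(patch_size)
      ci <- (cc - 1L) * patch_size + seq_len(patch_size)
      img <- if (length(d) == 3L) slide[rr, ci, , drop = FALSE] else {
        array(slide[rr, ci], dim = c(patch_size, patch_size, 1L))
      }
      k <- k + 1L
      out[[k]] <- structure(list(
        patient_id = patient_id,
        row_index = r - 1L,
        col_index = cc - 1L,
        pixel_origin = c((r - 1L) * patch_size, (cc - 1L) * patch_size),
        image = img,
        tissue_fraction = NA_real_
      ), class = "patch")
    }
  }
  out
}

#' Otsu threshold of a slide
#'
#' The grayscale intensity threshold maximizing between-class variance of
#' the 256-bin histogram. Computed once per slide (a per-patch threshold
#' would be degenerate on uniform patches). Pixels strictly below the
#' threshold are treated as tissue.
#'
#' @param slide 2-D matrix or `(h, w, 3)` array, intensities `0..255`.
#' @return Numeric threshold in `(0, 255]`.
#' @export
compute_otsu_threshold <- function(slide) {
  g <- round(slide_gray(slide))
  g <- pmin(pmax(g, 0), 255)
  if (max(g) == min(g)) {
    stop("degenerate histogram: slide has constant intensity")
  }
  h <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for threshold t = level k (tissue: value < k+1)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)  # first maximizer
  levels[k] + 1
}

#' Fraction of tissue pixels in a patch
#'
#' Tissue pixels are those whose grayscale value lies strictly below the
#' slide-level threshold.
#'
#' @param patch a `patch` from [tile_slide()] or a raw image array.
#' @param slide_threshold threshold from [compute_otsu_threshold()].
#' @return Real in `[0, 1]`.
#' @export
tissue_fraction <- function(patch, slide_threshold) {
  img <- if (inherits(patch, "patch")) patch$image else patch
  g <- slide_gray(if (length(dim(img)) == 3L && dim(img)[3] == 1L) {
    img[, , 1]
  } else img)
  mean(g < slide_threshold)
}

score_patches <- function(patches, slide_threshold) {
  lapply(patches, function(p) {
    p$tissue_fraction <- tissue_fraction(p, slide_threshold)
    p
  })
}

#' Keep patches whose tissue fraction strictly exceeds the minimum
#'
#' The validity rule is strict (`> min_tissue`, default 0.90), keeping only
#' patches in which tissue accounts for more than 90% of the area. Order
#' preserved; idempotent.
#'
#' @param patches list of scored `patch` objects.
#' @param min_tissue threshold in `[0, 1]`.
#' @return Filtered list.
#' @export
filter_valid <- function(patches, min_tissue = 0.90) {
  keep <- vapply(patches, function(p) {
    if (is.na(p$tissue_fraction)) {
      stop("tissue_fraction not set; score patches first")
    }
    p$tissue_fraction > min_tissue
  }, logical(1))
  patches[keep]
}

#' Uniform per-patient patch budget
#'
#' The number of patches used per patient is the maximum count obtainable
#' uniformly from everyone, i.e. the cohort minimum of valid-patch counts.
#'
#' @param valid_counts named integer vector or list, patients to counts.
#' @return Integer budget.
#' @export
cohort_budget <- function(valid_counts) {
  counts <- unlist(valid_counts)
  if (length(counts) == 0L) stop("no patients")
  bad <- names(counts)[counts == 0L]
  if (length(bad) > 0L) {
    stop(sprintf("patients with no valid patches: %s",
                 paste(bad, collapse = ", ")))
  }
  as.integer(min(counts))
}

#' Select a patient's bag of patches
#'
#' Default policy is deterministic: take the `budget` patches with highest
#' tissue fraction, breaking ties by ascending `(row_index, col_index)`.
#' The `"random"` policy draws a seeded uniform sample instead.
#'
#' @param valid list of valid scored patches for one patient.
#' @param budget bag size.
#' @param seed integer, used by the random policy.
#' @param policy `"top_tissue"` (default) or `"random"`.
#' @param label optional 0/1 patient label carried on the bag.
#' @return A `patch_bag` (fields `patient_id`, `label`, `patches`,
#'   `budget`).
#' @export
select_patches <- function(valid, budget, seed = 1L,
                           policy = c("top_tissue", "random"),
                           label = NA_integer_) {
  policy <- match.arg(policy)
  if (length(valid) < budget) {
    stop(sprintf("only %d valid patches but budget is %d",
                 length(valid), budget))
  }
  if (policy == "top_tissue") {
    tf <- vapply(valid, function(p) p$tissue_fraction, numeric(1))
    ri <- vapply(valid, function(p) p$row_index, integer(1))
    ci <- vapply(valid, function(p) p$col_index, integer(1))
    ord <- order(-tf, ri, ci)
    sel <- valid[ord[seq_len(budget)]]
  } else {
    sel <- with_seed(seed, valid[sample.int(length(valid), budget)])
  }
  pid <- unique(vapply(sel, function(p) p$patient_id, character(1)))
  stopifnot(length(pid) == 1L)
  structure(list(patient_id = pid, label = label, patches = sel,
                 budget = as.integer(budget)),
            class = "patch_bag")
}

#' Stack a bag's patches into an `(n, h, w, 3)` array scaled to `[0, 1]`
#' @param bag a `patch_bag`.
#' @return Numeric array ready for the backbone.
#' @export
bag_to_array <- function(bag) {
  stopifnot(inherits(bag, "patch_bag"))
  n <- length(bag$patches)
  d <- dim(bag$patches[[1]]$image)
  if (d[3] == 1L) d[3] <- 3L
  x <- array(0, dim = c(n, d[1], d[2], 3L))
  for (i in seq_len(n)) {
    img <- bag$patches[[i]]$image
    if (dim(img)[3] == 1L) img <- array(img, dim = c(d[1], d[2], 3L))
    x[i, , , ] <- img / 255
  }
  x
}

#' Tile, score, filter and bag every slide of a cohort
#'
#' Applies the full preprocessing chain: per-slide Otsu threshold, tissue
#' scoring, strict validity filtering, cohort-minimum budget (optionally
#' capped), and per-patient selection.
#'
#' @param slides named list of slide arrays (patient id to slide).
#' @param labels named 0/1 vector.
#' @param patch_size tile side.
#' @param min_tissue validity threshold.
#' @param max_budget optional cap on the uniform budget (e.g. 64).
#' @param policy,seed passed to [select_patches()].
#' @return List with `bags` (named list of `patch_bag`) and `budget`.
#' @export
build_patch_bags <- function(slides, labels, patch_size = 256L,
                             min_tissue = 0.90, max_budget = NULL,
                             policy = "top_tissue", seed = 1L) {
  valid <- lapply(names(slides), function(pid) {
    sl <- slides[[pid]]
    thr <- compute_otsu_threshold(sl)
    ps <- tile_slide(sl, patch_size, patient_id = pid)
    filter_valid(score_patches(ps, thr), min_tissue)
  })
  names(valid) <- names(slides)
  budget <- cohort_budget(lapply(valid, length))
  if (!is.null(max_budget)) budget <- min(budget, as.integer(max_budget))
  bags <- lapply(names(valid), function(pid) {
    select_patches(valid[[pid]], budget,
                   seed = seed_mix(seed, match(pid, names(valid))),
                   policy = policy, label = labels[[pid]])
  })
  names(bags) <- names(valid)
  list(bags = bags, budget = budget)
}
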