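#' @title Image pyramids and grid tiling
#' @description Multi-resolution pyramid construction (2x area-mean
#'   downsampling per level), tissue masks, and extraction of non-overlapping
#'   299x299 patch grids with a minimum-tissue filter.
#' @name pyramid-tiling
NULL

new_pyramid <- function(slide_id, levels, base_resolution, check = TRUE) {
  if (check) {
    stopifnot(length(levels) >= 1)
    for (n in seq_along(levels)) {
      img <- levels[[n]]
      stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
      if (n > 1) {
        prev <- dim(levels[[n - 1]])
        if (!all(dim(img)[1:2] == ceiling(prev[1:2] / 2)))
          stop("level ", n - 1, " dimensions are not the ceiling half of level ", n - 2)
      }
    }
  }
  structure(list(slide_id = slide_id, levels = levels,
                 base_resolution = base_resolution),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  dims <- vapply(x$levels, function(l) {
    if (is.null(l)) "<not loaded>" else paste(dim(l)[1:2], collapse = "x")
  }, character(1))
  cat(sprintf("slide_pyramid '%s': %d level(s), base %.3g um/pixel\n",
              x$slide_id, length(x$levels), x$base_resolution))
  cat(sprintf("  level %d: %s (%.3g um/pixel)\n",
              seq_along(dims) - 1L, dims,
              x$base_resolution * 2^(seq_along(dims) - 1L)), sep = "")
  invisible(x)
}

# Exact 2x area-mean pooling of one matrix; odd trailing rows/columns form
# partial (2x1 / 1x2 / 1x1) blocks so output dims are ceiling(input / 2).
pool2_matrix <- function(m) {
  rg <- (seq_len(nrow(m)) + 1L) %/% 2L
  cg <- (seq_len(ncol(m)) + 1L) %/% 2L
  s <- rowsum(m, rg, reorder = TRUE)
  s <- t(rowsum(t(s), cg, reorder = TRUE))
  counts <- tcrossprod(tabulate(rg), tabulate(cg))
  s / counts
}

downsample_half <- function(img) {
  out <- array(0, c(ceiling(dim(img)[1] / 2), ceiling(dim(img)[2] / 2), 3))
  for (c in 1:3) out[, , c] <- pool2_matrix(img[, , c])
  out
}

#' Build a multi-resolution image pyramid
#'
#' Level 0 is the base image; level `n` is the base downsized by `2^n` using
#' exact 2x2 area-mean pooling applied recursively (odd dimensions round up,
#' edge blocks average the pixels actually present).
#'
#' @param base_image numeric array `H x W x 3`, intensities in `[0, 1]`.
#' @param n_levels number of levels to build (>= 1), including the base.
#' @param base_resolution declared resolution of level 0 in micrometres per
#'   pixel (default 0.49, so level `n` has resolution `0.49 * 2^n`).
#' @param slide_id identifier carried through the pipeline.
#' @return a `slide_pyramid` object.
#' @seealso [level_resolution()], [extract_patches()]
#' @export
build_pyramid <- function(base_image, n_levels, base_resolution = 0.49,
                          slide_id = "slide") {
  stopifnot(is.array(base_image), length(dim(base_image)) == 3,
            dim(base_image)[3] == 3)
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (min(dim(base_image)[1:2]) < 1) stop("base image is empty")
  if (2^(n_levels - 1) > max(dim(base_image)[1:2]))
    stop("n_levels = ", n_levels, " would produce an empty level for a ",
         dim(base_image)[1], "x", dim(base_image)[2], " base image")
  levels <- vector("list", n_levels)
  levels[[1]] <- base_image
  for (n in seq_len(n_levels - 1)) {
    levels[[n + 1]] <- downsample_half(levels[[n]])
  }
  new_pyramid(slide_id, levels, base_resolution)
}

#' Resolution of a pyramid level
#'
#' @param level pyramid level index (0-based).
#' @param base_resolution level-0 resolution in micrometres per pixel.
#' @return `base_resolution * 2^level`, in micrometres per pixel.
#' @export
#' @examples
#' level_resolution(4, 0.49) # 7.84
#' level_resolution(8, 0.49) # 125.44
level_resolution <- function(level, base_resolution = 0.49) {
  if (any(level < 0)) stop("level must be non-negative")
  base_resolution * 2^level
}

#' Compute a tissue mask for one pyramid level
#'
#' A pixel is tissue iff its mean channel intensity is below `threshold`
#' (the slide background is near-white). The rule is a fixed luminance
#' threshold; synthetic backgrounds make it exact.
#'
#' @param level_image numeric array `H x W x 3` in `[0, 1]`.
#' @param threshold luminance cut; default 0.9 of full scale.
#' @return a `tissue_mask`: list with logical matrix `mask` and scalar
#'   `tissue_fraction` (the mean of the mask).
#' @export
build_tissue_mask <- function(level_image, threshold = 0.9) {
  stopifnot(is.array(level_image), length(dim(level_image)) == 3)
  lum <- (level_image[, , 1] + level_image[, , 2] + level_image[, , 3]) / 3
  mask <- lum < threshold
  structure(list(mask = mask, tissue_fraction = mean(mask)),
            class = "tissue_mask")
}

new_patch_set <- function(slide_id, level, resolution, coords, patches,
                          weak_label = NA_character_, n_grid = NA_integer_) {
  structure(list(slide_id = slide_id, level = level, resolution = resolution,
                 coords = coords, patches = patches, weak_label = weak_label,
                 n_grid = n_grid),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set '%s' level %d (%.3g um/pixel): %d patch(es), label %s\n",
              x$slide_id, x$level, x$resolution, length(x$patches),
              if (is.na(x$weak_label)) "<none>" else x$weak_label))
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$patches)

#' Extract a non-overlapping patch grid from one pyramid level
#'
#' Tiles the level image with a regular grid anchored at the top-left
#' corner, stride equal to the patch size (tiles are non-overlapping and
#' partial edge tiles are discarded). Tiles whose tissue coverage under
#' [build_tissue_mask()] is below `min_tissue` are removed. If more than
#' `max_patches` tiles survive, a seeded uniform subsample is returned.
#'
#' @param pyramid a `slide_pyramid`.
#' @param level level index (0-based) to tile.
#' @param patch_size tile side in pixels (default 299).
#' @param min_tissue minimum tissue coverage per retained tile (default 0.5).
#' @param max_patches cap on the number of returned tiles (default 1000).
#' @param seed seed for the subsampling step.
#' @param mask_threshold luminance threshold passed to [build_tissue_mask()].
#' @return a `patch_set`; empty (with a warning) if the level is smaller
#'   than `patch_size` in either dimension.
#' @export
extract_patches <- function(pyramid, level, patch_size = 299L,
                            min_tissue = 0.5, max_patches = 1000L,
                            seed = 1L, mask_threshold = 0.9) {
  stopifnot(inherits(pyramid, "slide_pyramid"))
  if (level < 0 || level >= length(pyramid$levels))
    stop("level ", level, " does not exist in this pyramid")
  img <- pyramid$levels[[level + 1L]]
  if (is.null(img)) stop("level ", level, " was not loaded")
  res <- level_resolution(level, pyramid$base_resolution)
  H <- dim(img)[1]; W <- dim(img)[2]
  empty <- function() new_patch_set(pyramid$slide_id, level, res,
                                    data.frame(row_index = integer(0),
                                               col_index = integer(0),
                                               coverage = numeric(0)),
                                    list(), n_grid = 0L)
  if (H < patch_size || W < patch_size) {
    warning("level ", level, " (", H, "x", W, ") is smaller than patch_size ",
            patch_size, "; returning an empty patch set")
    return(empty())
  }
  nr <- H %/% patch_size
  nc <- W %/% patch_size
  mask <- build_tissue_mask(img, threshold = mask_threshold)$mask
  mcrop <- mask[seq_len(nr * patch_size), seq_len(nc * patch_size), drop = FALSE]
  rg <- rep(seq_len(nr), each = patch_size)
  cg <- rep(seq_len(nc), each = patch_size)
  s <- rowsum(mcrop + 0, rg, reorder = TRUE)
  s <- t(rowsum(t(s), cg, reorder = TRUE))
  coverage <- s / patch_size^2 # nr x nc matrix of per-tile tissue fractions
  keep <- which(coverage >= min_tissue, arr.ind = TRUE)
  coords <- data.frame(row_index = keep[, 1] - 1L,
                       col_index = keep[, 2] - 1L,
                       coverage = coverage[keep])
  # deterministic order: row-major over the grid
  ord <- order(coords$row_index, coords$col_index)
  coords <- coords[ord, , drop = FALSE]
  if (nrow(coords) > max_patches) {
    pick <- local_seed(mix_seed(seed, "subsample", pyramid$slide_id, level),
                       sort(sample.int(nrow(coords), max_patches)))
    coords <- coords[pick, , drop = FALSE]
  }
  rownames(coords) <- NULL
  patches <- lapply(seq_len(nrow(coords)), function(i) {
    r0 <- coords$row_index[i] * patch_size
    c0 <- coords$col_index[i] * patch_size
    img[r0 + seq_len(patch_size), c0 + seq_len(patch_size), , drop = FALSE]
  })
  new_patch_set(pyramid$slide_id, level, res, coords, patches,
                n_grid = nr * nc)
}

#' Assign the slide-level weak label to every patch
#'
#' Weak supervision: every patch inherits its slide's diagnosis; no
#' patch-level annotation is consulted. Out-of-distribution slides carry no
#' class label and are never used for training, so label `"OOD"` is
#' rejected.
#'
#' @param patch_set a `patch_set`.
#' @param slide_label `"A"` or `"B"`.
#' @return the patch set with `weak_label` set.
#' @export
label_patches <- function(patch_set, slide_label) {
  stopifnot(inherits(patch_set, "patch_set"))
  if (!slide_label %in% c("A", "B"))
    stop("slide_label must be 'A' or 'B' (OOD slides are never labelled for training)")
  patch_set$weak_label <- slide_label
  patch_set
}
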