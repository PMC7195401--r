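#' Write an RGB image as binary PPM (P6)
#'
#' Images are stored as plain portable pixmaps, one file per pyramid level.
#' PPM is used because it is a self-describing, dependency-free raster
#' format; intensities in `[0, 1]` are quantised to 8 bits.
#'
#' @param img numeric array `H x W x 3` with values in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]
  w <- dim(img)[2]
  q <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  # PPM is row-major with channels interleaved
  px <- aperm(array(q, dim(img)), c(3, 2, 1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(px), con)
  invisible(path)
}

#' Read a binary PPM (P6) image
#'
#' @param path file written by [write_ppm()] (or any 8-bit P6 file).
#' @return numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of PPM header: ", path)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (magic != "P6") stop("not a binary PPM (P6) file: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255)
    stop("unsupported PPM header in ", path)
  raw <- readBin(con, "raw", n = 3 * w * h)
  if (length(raw) != 3 * w * h) stop("truncated PPM payload in ", path)
  px <- array(as.integer(raw), c(3, w, h))
  aperm(px, c(3, 2, 1)) / maxval
}

#' Write a slide pyramid to disk
#'
#' One directory per slide, holding `level_<n>.ppm` for every level plus a
#' small `pyramid.json` with the slide id and declared base resolution.
#'
#' @param pyramid a `slide_pyramid` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyramid, dir) {
  stopifnot(inherits(pyramid, "slide_pyramid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (n in seq_along(pyramid$levels)) {
    write_ppm(pyramid$levels[[n]], file.path(dir, sprintf("level_%d.ppm", n - 1L)))
  }
  meta <- list(slide_id = pyramid$slide_id,
               n_levels = length(pyramid$levels),
               base_resolution = pyramid$base_resolution)
  jsonlite::write_json(meta, file.path(dir, "pyramid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a slide pyramid from disk
#'
#' @param dir directory written by [write_pyramid()].
#' @param levels optional integer vector of level indices (0-based) to load;
#'   default loads all levels.
#' @return a `slide_pyramid` object.
#' @export
read_pyramid <- function(dir, levels = NULL) {
  meta_path <- file.path(dir, "pyramid.json")
  if (!file.exists(meta_path)) stop("not a pyramid directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  idx <- if (is.null(levels)) seq_len(meta$n_levels) - 1L else as.integer(levels)
  imgs <- vector("list", max(idx) + 1L)
  for (n in idx) {
    imgs[[n + 1L]] <- read_ppm(file.path(dir, sprintf("level_%d.ppm", n)))
  }
  new_pyramid(meta$slide_id, imgs, meta$base_resolution)
}
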