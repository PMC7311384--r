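#' Multi-channel image container
#'
#' Lightweight container for fluorescence image data. `data` is a numeric
#' array indexed `[channel, row, col]` for 2D images or
#' `[channel, z, row, col]` for z-stacks. Intensities are stored on their
#' native scale (e.g. 0..255 for 8-bit data); `dtype_range` records that
#' scale so downstream contrast operations can map back to it.
#'
#' The coordinate convention throughout the package is 0-based `(row, col)`
#' with the origin at the top-left pixel and pixel-centre sampling: the
#' centre of pixel `(r, c)` sits at continuous coordinate `(r, c)`.
#'
#' @param data numeric array, `[channel, row, col]` or `[channel, z, row, col]`.
#' @param channel_names character vector, one name per channel.
#' @param pixel_size_um optional physical pixel size in micrometres.
#' @param dtype_range length-2 numeric `(min, max)` of the intensity scale;
#'   guessed from the data when `NULL` (0..1 for unit-scaled data, else the
#'   smallest of 0..255 / 0..65535 that covers it).
#' @return an object of class `mc_image`.
#' @export
mc_image <- function(data, channel_names = NULL, pixel_size_um = NULL,
                     dtype_range = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a 3D [channel, row, col] or 4D [channel, z, row, col] array")
  }
  nch <- dim(data)[1]
  if (is.null(channel_names)) {
    channel_names <- if (nch == 2L) c("red", "green") else paste0("ch", seq_len(nch))
  }
  if (length(channel_names) != nch) stop("one channel name per channel required")
  if (is.null(dtype_range)) dtype_range <- guess_dtype_range(data)
  if (any(data < dtype_range[1] - 1e-9) || any(data > dtype_range[2] + 1e-9)) {
    stop("intensities fall outside `dtype_range`")
  }
  structure(
    list(data = data, channel_names = channel_names,
         pixel_size_um = pixel_size_um, dtype_range = as.numeric(dtype_range)),
    class = "mc_image"
  )
}

guess_dtype_range <- function(data) {
  mx <- max(data)
  if (mx <= 1) c(0, 1) else if (mx <= 255) c(0, 255) else c(0, 65535)
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$data)
  geom <- if (length(d) == 3L) sprintf("%d x %d px", d[2], d[3])
          else sprintf("%d z x %d x %d px", d[2], d[3], d[4])
  cat(sprintf("<mc_image> %s; channels: %s; range [%g, %g]\n",
              geom, paste(x$channel_names, collapse = ", "),
              x$dtype_range[1], x$dtype_range[2]))
  invisible(x)
}

#' Extract one channel as a 2D matrix
#'
#' @param image an `mc_image` (must be 2D; run [max_project()] first for stacks).
#' @param channel channel index or name.
#' @return numeric matrix `[row, col]`.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "mc_image"))
  if (length(dim(image$data)) != 3L) stop("image has a z axis; max_project() first")
  if (is.character(channel)) {
    channel <- match(channel, image$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  image$data[channel, , ]
}

#' Maximum-intensity z-projection
#'
#' Collapses the z axis of a stack by taking, per channel, the per-pixel
#' maximum over all slices. A 2D image passes through unchanged.
#'
#' @param image an `mc_image`.
#' @return a 2D `mc_image`.
#' @export
max_project <- function(image) {
  stopifnot(inherits(image, "mc_image"))
  d <- dim(image$data)
  if (length(d) == 3L) return(image)
  out <- array(0, dim = d[c(1, 3, 4)])
  if (d[2] == 1L) {
    out[] <- image$data[, 1, , ]
  } else {
    for (ch in seq_len(d[1])) {
      out[ch, , ] <- apply(image$data[ch, , , ], c(2, 3), max)
    }
  }
  mc_image(out, image$channel_names, image$pixel_size_um, image$dtype_range)
}

#' Write a multi-channel image as a TIFF file
#'
#' Channels are written as successive TIFF pages (channel axis first);
#' intensities are scaled from `dtype_range` into the file's bit depth.
#'
#' @param image a 2D `mc_image`.
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @export
write_field_tiff <- function(image, path, bits_per_sample = 16L) {
  stopifnot(inherits(image, "mc_image"), length(dim(image$data)) == 3L)
  rng <- image$dtype_range
  pages <- lapply(seq_len(dim(image$data)[1]), function(ch) {
    m <- (image$data[ch, , ] - rng[1]) / (rng[2] - rng[1])
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a multi-channel TIFF written page-per-channel
#'
#' @param path TIFF file; pages are interpreted as channels.
#' @param channel_names optional channel names.
#' @param dtype_range intensity scale to map the file's unit-scaled samples
#'   onto (default keeps 0..1).
#' @return an `mc_image`.
#' @export
read_field_tiff <- function(path, channel_names = NULL, dtype_range = c(0, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) {
    arr[i, , ] <- dtype_range[1] + pages[[i]] * (dtype_range[2] - dtype_range[1])
  }
  mc_image(arr, channel_names, dtype_range = dtype_range)
}

# Symmetric (edge-inclusive) reflection padding; r may not exceed dim - 1.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr - 1 || r > nc - 1) stop("padding radius exceeds image size - 1")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci]
}
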