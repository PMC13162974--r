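# File I/O: images (PNG natively; TIFF when the tiff package is present),
# binary mask PNGs, YAML run configurations and CSV traces.

#' Read an image file as a numeric array
#'
#' Returns intensities in `[0, 1]`. PNG is supported natively; TIFF via
#' the optional tiff package. Greyscale images come back as `[H, W]`
#' matrices, colour images as `[H, W, C]` (an alpha channel, if present,
#' is dropped).
#'
#' @param path image file path.
#' @export
read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  im <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (supported: png, tiff)")
  )
  if (length(dim(im)) == 3L && dim(im)[3] == 4L) im <- im[, , 1:3]
  if (length(dim(im)) == 3L && dim(im)[3] == 2L) im <- im[, , 1]
  im
}

# image array [3, H, W] -> [H, W, 3] PNG
write_image_png <- function(image_chw, path) {
  png::writePNG(aperm(pmin(pmax(image_chw, 0), 1), c(2, 3, 1)), path)
}

#' Write a binary mask as an 8-bit single-channel PNG
#'
#' Foreground maps to 255, background to 0.
#'
#' @param mask binary matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0.5) * 1, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path single-channel (or colour, first channel used) PNG.
#' @return binary matrix.
#' @export
read_mask_png <- function(path) {
  m <- read_image_array(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m > 0.5) * 1
}

#' Read / write a run configuration
#'
#' YAML files holding [model_config()] fields and command settings; every
#' CLI run writes its resolved configuration next to its outputs.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config a named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_from_list <- function(lst) {
  keep <- intersect(names(lst), names(formals(model_config)))
  do.call(model_config, lst[keep])
}
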