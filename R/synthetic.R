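# Synthetic endoscopy-like scenes: a textured reddish mucosa background,
# one or more smooth blob lesions (Fourier-perturbed ellipses) with
# configurable contrast and boundary blur, and saturated specular
# highlights. The mask is the exact blob support before any blurring, so
# label noise enters only through the prompt-erosion pipeline.

#' Scene specification for the synthetic generator
#'
#' Defaults emulate the structure of public polyp datasets at the
#' network's working resolution: lesions spanning two orders of magnitude
#' in area (the lower end emulating sub-5 mm polyps), weak low-contrast
#' boundaries (contrast draws reach below a 5% intensity difference),
#' textured mucosa and specular highlights.
#'
#' @param image_size square image edge in pixels (default 352).
#' @param n_lesions lesions per scene (0, 1 or 2).
#' @param area_frac_range lesion area as a fraction of the image area.
#' @param blur_sigma_range Gaussian boundary-softness range (pixels).
#' @param contrast_range lesion/background intensity contrast range.
#' @param n_specular number of saturated highlight discs.
#' @param texture_wavelength characteristic background texture scale (px).
#' @export
scene_spec <- function(image_size = 352L, n_lesions = 1L,
                       area_frac_range = c(0.002, 0.25),
                       blur_sigma_range = c(0.8, 3),
                       contrast_range = c(0.03, 0.4),
                       n_specular = 3L, texture_wavelength = 40) {
  stopifnot(n_lesions %in% 0:2,
            all(area_frac_range > 0), all(area_frac_range < 1),
            area_frac_range[1] <= area_frac_range[2])
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 area_frac_range = area_frac_range,
                 blur_sigma_range = blur_sigma_range,
                 contrast_range = contrast_range,
                 n_specular = as.integer(n_specular),
                 texture_wavelength = texture_wavelength),
            class = "scene_spec")
}

#' Sample one synthetic polyp scene
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return list with `image` (array `[3, S, S]`, values in `[0, 1]`) and
#'   `mask` (binary `[S, S]` matrix, the exact lesion support).
#' @export
sample_polyp_scene <- function(spec = scene_spec(), seed = 0L) {
  with_seed(seed, {
    S <- spec$image_size
    gy <- matrix(rep(seq_len(S) - 1, times = S), S, S)
    gx <- matrix(rep(seq_len(S) - 1, each = S), S, S)
    base <- c(0.58, 0.30, 0.26)
    img <- array(0, c(3L, S, S))
    for (c in 1:3) {
      field <- matrix(0, S, S)
      for (j in 1:3) {
        wl <- spec$texture_wavelength * stats::runif(1, 0.6, 1.6)
        ang <- stats::runif(1, 0, pi)
        ph <- stats::runif(1, 0, 2 * pi)
        field <- field + stats::runif(1, 0.01, 0.04) *
          sin(2 * pi * (gy * cos(ang) + gx * sin(ang)) / wl + ph)
      }
      img[c, , ] <- base[c] + field
    }
    img <- img * (1 + 0.02 * array(stats::rnorm(3 * S * S), c(3, S, S)))

    mask <- matrix(0, S, S)
    if (spec$n_lesions > 0) for (l in seq_len(spec$n_lesions)) {
      frac <- stats::runif(1, spec$area_frac_range[1], spec$area_frac_range[2])
      r0 <- S * sqrt(frac / pi)
      amp <- stats::runif(4, 0, 0.15) / (2:5)
      if (r0 * (1 + sum(amp)) >= S / 2 - 2)
        stop("requested lesion area fraction does not fit in the image")
      margin <- r0 * (1 + sum(amp)) + 2
      cy <- stats::runif(1, margin, S - 1 - margin)
      cx <- stats::runif(1, margin, S - 1 - margin)
      ph <- stats::runif(4, 0, 2 * pi)
      dy <- gy - cy; dx <- gx - cx
      th <- atan2(dy, dx)
      rad <- r0 * (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
                     amp[3] * cos(4 * th + ph[3]) + amp[4] * cos(5 * th + ph[4]))
      blob <- (sqrt(dy^2 + dx^2) <= rad) * 1
      mask <- pmax(mask, blob)
      contrast <- stats::runif(1, spec$contrast_range[1], spec$contrast_range[2])
      sigma <- stats::runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
      soft <- blur_gaussian(blob, sigma)
      tint <- c(1.0, 0.75, 0.65)          # lesions slightly brighter, pinker
      for (c in 1:3) img[c, , ] <- img[c, , ] + contrast * tint[c] * soft
    }

    if (spec$n_specular > 0) for (s in seq_len(spec$n_specular)) {
      cy <- stats::runif(1, 2, S - 3); cx <- stats::runif(1, 2, S - 3)
      r <- stats::runif(1, 1, 3)
      disc <- (sqrt((gy - cy)^2 + (gx - cx)^2) <= r) * 1
      glow <- blur_gaussian(disc, 0.8)
      for (c in 1:3) img[c, , ] <- img[c, , ] + 0.9 * glow
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask)
  })
}

#' Write a synthetic fixture dataset to disk
#'
#' Produces `n` image/mask PNG pairs in a Kvasir-SEG-style layout
#' (`images/` and `masks/` with matching stems) plus a tab-separated
#' `index.tsv` listing stems and the per-scene seeds, so the same loader
#' serves synthetic and real data. Regeneration with the same master seed
#' is byte-identical.
#'
#' @param n number of scenes.
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if missing).
#' @param master_seed integer seed; scene i uses `master_seed + i`.
#' @return invisibly, the index data frame.
#' @export
build_fixture_set <- function(n, spec = scene_spec(), out_dir,
                              master_seed = 0L) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(stem = sprintf("scene_%03d", seq_len(n)),
                    seed = master_seed + seq_len(n))
  for (i in seq_len(n)) {
    sc <- sample_polyp_scene(spec, seed = idx$seed[i])
    png::writePNG(aperm(sc$image, c(2, 3, 1)),
                  file.path(out_dir, "images", paste0(idx$stem[i], ".png")))
    png::writePNG(sc$mask,
                  file.path(out_dir, "masks", paste0(idx$stem[i], ".png")))
  }
  utils::write.table(idx, file.path(out_dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(idx)
}

#' Load an images/masks folder into model tensors
#'
#' Reads a Kvasir-SEG-style folder (subdirectories `images/` and `masks/`
#' with matching file stems), resizes images bilinearly and masks with
#' nearest-neighbour sampling to `image_size`, and normalises to `[0, 1]`.
#'
#' @param dir dataset directory.
#' @param image_size target square resolution (default 352).
#' @return list with `images` `[N, 3, S, S]`, `masks` `[N, 1, S, S]` and
#'   `stems`.
#' @export
load_seg_folder <- function(dir, image_size = 352L) {
  ipaths <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (length(ipaths) == 0L) stop("no images found under ", file.path(dir, "images"))
  stems <- tools::file_path_sans_ext(basename(ipaths))
  S <- image_size
  n <- length(ipaths)
  images <- array(0, c(n, 3L, S, S))
  masks <- array(0, c(n, 1L, S, S))
  for (i in seq_len(n)) {
    im <- read_image_array(ipaths[i])                 # [H, W, C] in [0,1]
    for (c in 1:3)
      images[i, c, , ] <- resize_matrix(im[, , c], S, S, "bilinear")
    mpath <- find_mask_path(dir, stems[i])
    mk <- read_image_array(mpath)
    if (length(dim(mk)) == 3L) mk <- mk[, , 1]
    masks[i, 1L, , ] <- (resize_matrix(mk, S, S, "nearest") > 0.5) * 1
  }
  list(images = images, masks = masks, stems = stems)
}

find_mask_path <- function(dir, stem) {
  cand <- list.files(file.path(dir, "masks"), pattern = paste0("^", stem, "\\."),
                     full.names = TRUE)
  if (length(cand) == 0L) stop("no mask found for stem '", stem, "'")
  cand[[1]]
}
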