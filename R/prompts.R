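# Coarse-prompt simulation: iterative binary erosion of ground-truth masks
# emulates the rough region-of-interest annotations a clinician would
# supply, and factor-4 nearest-neighbour downsampling produces the
# low-resolution prompt the prompt encoder consumes.

#' Erosion specification
#'
#' @param element binary structuring element (2-D, odd dimensions,
#'   containing its centre); default 3x3 all-ones square.
#' @param iterations number of erosion passes (non-negative).
#' @param min_area area floor: erosion stops early rather than shrink the
#'   foreground below this many pixels (default 1, so a non-empty mask
#'   never vanishes).
#' @param iter_range range from which [simulate_coarse_prompt()] draws a
#'   per-sample iteration count (multi-level erosion); default 1..5.
#' @return a list of class `erosion_spec`.
#' @export
erosion_spec <- function(element = matrix(1, 3, 3), iterations = 1L,
                         min_area = 1L, iter_range = c(1L, 5L)) {
  element <- (element != 0) * 1
  d <- dim(element)
  if (any(d %% 2L == 0L)) stop("structuring element must have odd dimensions")
  if (element[(d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L] != 1)
    stop("structuring element must contain its centre")
  structure(list(element = element, iterations = as.integer(iterations),
                 min_area = as.integer(min_area),
                 iter_range = as.integer(iter_range)),
            class = "erosion_spec")
}

check_binary <- function(mask) {
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (values 0/1)")
  invisible(mask)
}

# one erosion pass: minimum over the structuring element's support,
# pixels outside the image counting as background
erode_once <- function(mask, element) {
  d <- dim(element)
  ry <- (d[1] - 1L) %/% 2L
  rx <- (d[2] - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(0, H + 2L * ry, W + 2L * rx)
  padded[ry + seq_len(H), rx + seq_len(W)] <- mask
  out <- matrix(1, H, W)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (element[i, j] == 0) next
    out <- pmin(out, padded[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)])
  }
  out
}

#' Iterative binary erosion with an area floor
#'
#' Applies standard binary erosion `spec$iterations` times; pixels outside
#' the image count as background, so a full-frame mask loses exactly its
#' one-pixel border per pass with the default element. If a pass would
#' drop the foreground area below `spec$min_area`, the last mask at or
#' above the floor is returned instead (so erosion is idempotent once the
#' floor is reached).
#'
#' @param mask binary 2-D matrix.
#' @param spec an [erosion_spec()].
#' @return binary matrix of the same size.
#' @export
erode_binary_mask <- function(mask, spec = erosion_spec()) {
  check_binary(mask)
  m <- mask
  it <- spec$iterations
  while (it > 0L) {
    e <- erode_once(m, spec$element)
    if (sum(e) < spec$min_area) return(m)
    m <- e
    it <- it - 1L
  }
  m
}

#' Nearest-neighbour mask downsampling
#'
#' Picks the pixel nearest each coarse-cell centre, so binary masks stay
#' binary.
#'
#' @param mask 2-D matrix with dimensions divisible by `factor`.
#' @param factor integer downsampling factor (default 4).
#' @export
downsample_mask <- function(mask, factor = 4L) {
  H <- nrow(mask); W <- ncol(mask)
  if (H %% factor != 0L || W %% factor != 0L)
    stop("mask dimensions must be divisible by the downsampling factor")
  mask[seq(factor %/% 2L, H, by = factor), seq(factor %/% 2L, W, by = factor)]
}

#' Simulate a clinician's coarse prompt from a ground-truth mask
#'
#' Draws an iteration count uniformly from `spec$iter_range` (multi-level
#' erosion), erodes the mask, and downsamples by a factor of 4 with
#' nearest-neighbour sampling. The prompt foreground is always a subset of
#' the downsampled ground-truth foreground. An empty ground truth yields
#' an empty prompt with a warning (the model must still run on it).
#'
#' @param gt binary ground-truth matrix (e.g. 352x352).
#' @param spec an [erosion_spec()].
#' @param rng_seed integer seed for the iteration-count draw.
#' @return binary prompt matrix of a quarter the input resolution
#'   (e.g. 88x88).
#' @export
simulate_coarse_prompt <- function(gt, spec = erosion_spec(), rng_seed = 0L) {
  check_binary(gt)
  if (sum(gt) == 0) {
    warning("empty ground-truth mask: returning an empty prompt")
    return(downsample_mask(gt, 4L))
  }
  iters <- with_seed(rng_seed,
    sample(seq(spec$iter_range[1], spec$iter_range[2]), 1L))
  sp <- spec
  sp$iterations <- iters
  downsample_mask(erode_binary_mask(gt, sp), 4L)
}

# stack per-image prompts into the [B, 1, h, w] batch the model expects
prompt_batch <- function(masks_hw_list) {
  h <- nrow(masks_hw_list[[1]]); w <- ncol(masks_hw_list[[1]])
  out <- array(0, c(length(masks_hw_list), 1L, h, w))
  for (i in seq_along(masks_hw_list)) out[i, 1L, , ] <- masks_hw_list[[i]]
  out
}
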