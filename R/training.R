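# Training objective, overlap metrics, synchronized augmentation, and the
# end-to-end optimisation loop (Adam, cosine annealing, gradient clipping).

#' Loss weights of the composite objective
#'
#' `L = lambda_dice * L_dice + lambda_bce * L_bce`, both weights 1 by
#' default; `eps` stabilises the Dice ratio for near-empty masks.
#'
#' @param lambda_dice,lambda_bce non-negative weights (their sum positive).
#' @param eps small positive smoothing constant (default 1e-6).
#' @export
loss_weights <- function(lambda_dice = 1, lambda_bce = 1, eps = 1e-6) {
  stopifnot(lambda_dice >= 0, lambda_bce >= 0, lambda_dice + lambda_bce > 0,
            eps > 0)
  structure(list(lambda_dice = lambda_dice, lambda_bce = lambda_bce, eps = eps),
            class = "loss_weights")
}

ag_dice_loss <- function(pred, target, eps = 1e-6) {
  inter <- ag_sum(ag_mul(pred, ag_tensor(target)))
  denom <- ag_addc(ag_sum(pred), sum(target))
  ag_addc(ag_mulc(ag_div(ag_addc(ag_mulc(inter, 2), eps),
                         ag_addc(denom, eps)), -1), 1)
}

#' Soft Dice loss
#'
#' `1 - (2*sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`,
#' with the sums taken over all pixels of the batch (batch Dice); set
#' `per_image = TRUE` to average per-image losses instead.
#'
#' @param pred predicted foreground probabilities, same shape as `target`.
#' @param target binary mask array.
#' @param w a [loss_weights()] (only `eps` is used here).
#' @param per_image average per-image Dice losses rather than pooling.
#' @return scalar in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, w = loss_weights(), per_image = FALSE) {
  if (!all(dim(pred) == dim(target))) stop("pred and target shapes differ")
  if (any(pred < 0 | pred > 1)) stop("pred must contain probabilities in [0, 1]")
  one <- function(p, t)
    1 - (2 * sum(p * t) + w$eps) / (sum(p) + sum(t) + w$eps)
  if (!per_image) return(one(pred, target))
  B <- dim(pred)[1]
  mean(vapply(seq_len(B), function(b) one(pred[b, , , ], target[b, , , ]),
              numeric(1)))
}

#' Binary cross-entropy from logits
#'
#' Mean over pixels of `-(t*log(p) + (1-t)*log(1-p))` with
#' `p = sigmoid(logits)`, evaluated in the numerically stable logit form.
#'
#' @param pred_logits unbounded logit array.
#' @param target binary array of the same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred_logits, target) {
  if (!all(dim(pred_logits) == dim(target))) stop("shape mismatch")
  ag_bce_with_logits(ag_tensor(pred_logits), target)$value
}

ag_composite_loss <- function(pred_logits, target, w = loss_weights()) {
  out <- NULL
  if (w$lambda_dice > 0) {
    d <- ag_dice_loss(ag_sigmoid(pred_logits), target, w$eps)
    out <- ag_mulc(d, w$lambda_dice)
  }
  if (w$lambda_bce > 0) {
    b <- ag_mulc(ag_bce_with_logits(pred_logits, target), w$lambda_bce)
    out <- if (is.null(out)) b else ag_add(out, b)
  }
  out
}

#' Composite segmentation loss
#'
#' `lambda_dice * dice_loss(sigmoid(logits), target) +
#'  lambda_bce * bce_loss(logits, target)`.
#'
#' @inheritParams bce_loss
#' @param w a [loss_weights()].
#' @export
composite_loss <- function(pred_logits, target, w = loss_weights()) {
  if (!all(dim(pred_logits) == dim(target))) stop("shape mismatch")
  ag_composite_loss(ag_tensor(pred_logits), target, w)$value
}

#' Overlap metrics for binary segmentation
#'
#' Binarises predictions at `threshold` (on the probability scale) and
#' computes per-image Dice, IoU, precision and recall plus their batch
#' means. Conventions: an empty prediction matched with an empty ground
#' truth scores 1 on all four metrics; an undefined ratio (empty
#' denominator against a non-empty counterpart) scores 0.
#'
#' @param pred_logits logit array `[B, 1, H, W]`.
#' @param target binary array of the same shape.
#' @param threshold probability threshold (default 0.5).
#' @return list with `per_image` (data frame), the four means, and the
#'   threshold.
#' @export
segmentation_metrics <- function(pred_logits, target, threshold = 0.5) {
  if (!all(dim(pred_logits) == dim(target))) stop("shape mismatch")
  B <- dim(pred_logits)[1]
  cut <- stats::qlogis(threshold)
  rows <- lapply(seq_len(B), function(b) {
    p <- pred_logits[b, , , ] >= cut
    g <- target[b, , , ] > 0.5
    tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
    if (tp + fp + fn == 0) {            # empty vs empty
      data.frame(dice = 1, iou = 1, precision = 1, recall = 1,
                 tp = tp, fp = fp, fn = fn, tn = tn)
    } else {
      data.frame(
        dice = 2 * tp / (2 * tp + fp + fn),
        iou = tp / (tp + fp + fn),
        precision = if (tp + fp > 0) tp / (tp + fp) else 0,
        recall = if (tp + fn > 0) tp / (tp + fn) else 0,
        tp = tp, fp = fp, fn = fn, tn = tn)
    }
  })
  per <- do.call(rbind, rows)
  list(per_image = per,
       dice = mean(per$dice), iou = mean(per$iou),
       precision = mean(per$precision), recall = mean(per$recall),
       threshold = threshold)
}

# ---- augmentation ---------------------------------------------------------

#' Augmentation specification
#'
#' Probability-triggered synchronized geometric transforms: horizontal and
#' vertical flips (probability 0.5 each) and small rotations (probability
#' 0.3, angle uniform in [-15, 15] degrees). Applied to training pairs
#' only; images are resampled bilinearly, masks nearest-neighbour.
#'
#' @param p_hflip,p_vflip,p_rotate trigger probabilities in `[0, 1]`.
#' @param angle_range rotation range in degrees.
#' @export
augment_spec <- function(p_hflip = 0.5, p_vflip = 0.5, p_rotate = 0.3,
                         angle_range = c(-15, 15)) {
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            p_rotate >= 0, p_rotate <= 1)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rotate = p_rotate,
                 angle_range = angle_range),
            class = "augment_spec")
}

#' Synchronized geometric augmentation of an image/mask pair
#'
#' Draws flips and a rotation from `seed` and applies the identical
#' transform to the image (bilinear interpolation) and its mask
#' (nearest-neighbour, so it stays binary); borders exposed by rotation
#' are filled with 0.
#'
#' @param image array `[C, H, W]`.
#' @param mask binary matrix `[H, W]`.
#' @param spec an [augment_spec()].
#' @param seed integer seed; identical seeds give identical outputs.
#' @param force optional list(hflip=, vflip=, angle=) overriding the draw
#'   (used to verify transform synchrony deterministically).
#' @return list(image=, mask=).
#' @export
augment_pair <- function(image, mask, spec = augment_spec(), seed = 0L,
                         force = NULL) {
  if (!all(dim(image)[2:3] == dim(mask))) stop("image/mask spatial dims differ")
  draw <- if (!is.null(force)) force else with_seed(seed, list(
    hflip = stats::runif(1) < spec$p_hflip,
    vflip = stats::runif(1) < spec$p_vflip,
    angle = if (stats::runif(1) < spec$p_rotate)
      stats::runif(1, spec$angle_range[1], spec$angle_range[2]) else 0
  ))
  C <- dim(image)[1]
  if (isTRUE(draw$hflip)) {
    image <- image[, , rev(seq_len(dim(image)[3])), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  if (isTRUE(draw$vflip)) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), ]
  }
  if (!is.null(draw$angle) && abs(draw$angle) > 1e-12) {
    for (c in seq_len(C))
      image[c, , ] <- rotate_matrix(image[c, , ], draw$angle, "bilinear")
    mask <- rotate_matrix(mask, draw$angle, "nearest")
  }
  list(image = image, mask = mask)
}

# ---- optimisation ---------------------------------------------------------

#' Training specification
#'
#' Published optimisation settings: Adam with initial learning rate 1e-4
#' and weight decay 1e-5, cosine-annealed to 0 over the run, batch size 8,
#' 100 epochs, global gradient-norm clipping at 1.0.
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param batch_size samples per step.
#' @param epochs passes over the dataset (used when `steps` is not given
#'   to [fit()]).
#' @param clip_norm global gradient-norm ceiling.
#' @export
train_spec <- function(lr = 1e-4, weight_decay = 1e-5, batch_size = 8L,
                       epochs = 100L, clip_norm = 1.0) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, epochs >= 1,
            clip_norm > 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), clip_norm = clip_norm),
            class = "train_spec")
}

#' Cosine-annealed learning rate
#'
#' `lr/2 * (1 + cos(pi * (step-1)/(total-1)))`: the initial rate at step 1,
#' annealed to 0 at the final step.
#'
#' @param step current step (1-based).
#' @param total total steps.
#' @param lr initial learning rate.
#' @export
cosine_lr <- function(step, total, lr) {
  if (total <= 1) return(lr)
  lr / 2 * (1 + cos(pi * (step - 1) / (total - 1)))
}

#' Train the model end to end
#'
#' Optimises the composite Dice + BCE objective with Adam, cosine
#' annealing and global gradient-norm clipping. Coarse prompts are
#' regenerated from the (possibly augmented) ground-truth masks at every
#' step via [simulate_coarse_prompt()], so the model never sees the exact
#' target through the prompt channel. Deterministic given `seed`.
#'
#' @param model a [wavesam_model()]; updated in place (parameters are
#'   reference objects) and also returned.
#' @param images array `[N, 3, S, S]` in `[0, 1]`.
#' @param masks binary array `[N, 1, S, S]`.
#' @param spec a [train_spec()].
#' @param steps number of optimisation steps (default
#'   `epochs * ceiling(N / batch_size)`).
#' @param seed integer seed controlling batching, prompts and augmentation.
#' @param erosion an [erosion_spec()] for prompt simulation.
#' @param augment an [augment_spec()], or `NULL` to disable augmentation.
#' @param w a [loss_weights()].
#' @param verbose print progress every 50 steps.
#' @return list with `model` and `trace` (data frame: step, lr, loss,
#'   grad_norm).
#' @export
fit <- function(model, images, masks, spec = train_spec(), steps = NULL,
                seed = 1L, erosion = erosion_spec(), augment = NULL,
                w = loss_weights(), verbose = FALSE) {
  N <- dim(images)[1]
  if (is.null(N) || N == 0L) stop("empty dataset")
  if (is.null(steps))
    steps <- spec$epochs * ceiling(N / spec$batch_size)
  params <- collect_params(model[c("wtca", "encoder", "prompt", "decoder")])
  opt <- lapply(params, function(p)
    list(m = p$value * 0, v = p$value * 0))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  trace <- data.frame(step = integer(steps), lr = numeric(steps),
                      loss = numeric(steps), grad_norm = numeric(steps))
  S <- dim(images)[3]
  for (t in seq_len(steps)) {
    idx <- with_seed(seed * 1009L + t,
      if (N <= spec$batch_size) seq_len(N)
      else sample(N, spec$batch_size))
    nb <- length(idx)
    xb <- array(0, c(nb, 3L, S, S))
    tb <- array(0, c(nb, 1L, S, S))
    prompts <- vector("list", nb)
    for (i in seq_len(nb)) {
      im <- images[idx[i], , , ]
      mk <- masks[idx[i], 1L, , ]
      if (!is.null(augment)) {
        aug <- augment_pair(im, mk, augment,
                            seed = (seed * 131L + t * 17L + i) %% 2147483647L)
        im <- aug$image; mk <- round(aug$mask)
      }
      xb[i, , , ] <- im
      tb[i, 1L, , ] <- mk
      prompts[[i]] <- suppressWarnings(simulate_coarse_prompt(
        mk, erosion, rng_seed = (seed * 7919L + t * 131L + i) %% 2147483647L))
    }
    mp <- prompt_batch(prompts)
    ag_zero_grad(params)
    logits <- ag_wavesam_forward(model, ag_tensor(xb), ag_tensor(mp),
                                 training = TRUE)
    loss <- ag_composite_loss(logits, tb, w)
    ag_backward(loss)
    gn2 <- 0
    for (p in params) {
      if (is.null(p$grad)) p$grad <- p$value * 0
      if (spec$weight_decay > 0) p$grad <- p$grad + spec$weight_decay * p$value
      gn2 <- gn2 + sum(p$grad^2)
    }
    gn <- sqrt(gn2)
    scale <- if (gn > spec$clip_norm) spec$clip_norm / gn else 1
    lr_t <- cosine_lr(t, steps, spec$lr)
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    for (nm in names(params)) {
      p <- params[[nm]]
      g <- p$grad * scale
      st <- opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      opt[[nm]] <- st
      p$value <- p$value - lr_t * (st$m / bc1) / (sqrt(st$v / bc2) + adam_eps)
    }
    trace$step[t] <- t
    trace$lr[t] <- lr_t
    trace$loss[t] <- as.numeric(loss$value)
    trace$grad_norm[t] <- min(gn, spec$clip_norm)
    if (verbose && t %% 50L == 0L)
      message(sprintf("step %d/%d  loss %.4f  lr %.2e", t, steps,
                      trace$loss[t], lr_t))
  }
  list(model = model, trace = trace)
}
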