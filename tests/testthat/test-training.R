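# Losses, metrics, augmentation and the optimisation loop.

abind2 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(2, d[2], d[3], d[4]))
  out[1, , , ] <- a; out[2, , , ] <- b
  out
}

test_that("Dice loss on the canonical fixtures", {
  t <- array(0, c(1, 1, 20, 20)); t[1, 1, 1:10, 1:10] <- 1
  expect_lt(dice_loss(t, t), 1e-8)                       # perfect overlap
  p <- array(0, c(1, 1, 20, 20)); p[1, 1, 11:20, 11:20] <- 1
  expect_gt(dice_loss(p, t), 1 - 1e-6)                   # disjoint, area 100
  # 2 px each, 1 px overlap -> 1 - 2/4
  t2 <- array(0, c(1, 1, 2, 2)); t2[1, 1, 1, ] <- 1
  p2 <- array(0, c(1, 1, 2, 2)); p2[1, 1, , 1] <- 1
  expect_equal(dice_loss(p2, t2), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(p2[, , 1, , drop = FALSE], t2), "shape")
  expect_error(dice_loss(p2 * 2, t2), "probabilities")
  # per-image form averages individual Dice losses
  expect_equal(dice_loss(abind2(p2, t2), abind2(t2, t2), per_image = TRUE),
               mean(c(0.5, 0)), tolerance = 1e-5)
})

test_that("BCE matches its closed forms", {
  t <- array(stats::rbinom(64, 1, 0.5), c(1, 1, 8, 8))
  expect_equal(bce_loss(array(0, dim(t)), t), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(array(ifelse(t > 0.5, 40, -40), dim(t)), t), 1e-12)
  ones <- array(1, c(1, 1, 8, 8))
  logits_p9 <- array(stats::qlogis(0.9), dim(ones))
  expect_equal(bce_loss(logits_p9, ones), -log(0.9), tolerance = 1e-10)
})

test_that("the composite loss is the weighted sum of its parts", {
  set.seed(1)
  logits <- rand_array(c(2, 1, 6, 6), 1)
  t <- array(stats::rbinom(72, 1, 0.4), c(2, 1, 6, 6))
  d <- dice_loss(stats::plogis(logits), t)
  b <- bce_loss(logits, t)
  expect_equal(composite_loss(logits, t, loss_weights(0, 1)), b)
  expect_equal(composite_loss(logits, t, loss_weights(1, 0)), d)
  expect_equal(composite_loss(logits, t), d + b, tolerance = 1e-12)
  expect_equal(composite_loss(logits, t, loss_weights(0.3, 1.7)),
               0.3 * d + 1.7 * b, tolerance = 1e-12)
  expect_error(loss_weights(0, 0))
})

test_that("segmentation metrics and the Dice-IoU identity", {
  t <- array(0, c(1, 1, 4, 4)); t[1, 1, 1, 1:2] <- 1
  p <- array(-10, c(1, 1, 4, 4)); p[1, 1, 1, 2:3] <- 10
  met <- segmentation_metrics(p, t)
  expect_equal(met$dice, 0.5)
  expect_equal(met$iou, 1 / 3)
  expect_equal(met$precision, 0.5)
  expect_equal(met$recall, 0.5)
  perfect <- segmentation_metrics(ifelse(t > 0.5, 10, -10), t)
  expect_equal(unlist(perfect[c("dice", "iou", "precision", "recall")]),
               c(dice = 1, iou = 1, precision = 1, recall = 1))
  empty <- segmentation_metrics(array(-5, c(1, 1, 4, 4)),
                                array(0, c(1, 1, 4, 4)))
  expect_equal(empty$dice, 1)                            # empty-vs-empty
  set.seed(2)
  logits <- rand_array(c(4, 1, 16, 16), 3)
  tg <- array(stats::rbinom(1024, 1, 0.3), c(4, 1, 16, 16))
  m <- segmentation_metrics(logits, tg)
  expect_true(all(abs(m$per_image$dice -
                        2 * m$per_image$iou / (1 + m$per_image$iou)) < 1e-9))
})

test_that("augmentation is deterministic, binary-preserving and synchronized", {
  sc <- sample_polyp_scene(scene_spec(image_size = 64L,
                                      area_frac_range = c(0.05, 0.1)),
                           seed = 5)
  a1 <- augment_pair(sc$image, sc$mask, seed = 7)
  a2 <- augment_pair(sc$image, sc$mask, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  # pure flips preserve foreground area
  fl <- augment_pair(sc$image, sc$mask,
                     force = list(hflip = TRUE, vflip = TRUE, angle = 0))
  expect_equal(sum(fl$mask), sum(sc$mask))
  expect_equal(fl$image[1, , ], sc$image[1, 64:1, 64:1])
  # forced rotation: image-channel-mean centroid and mask centroid move
  # by the same displacement (analytic transform of centroid coordinates)
  centroid <- function(m) {
    w <- m / sum(m)
    c(sum(row(m) * w), sum(col(m) * w))
  }
  rot <- augment_pair(sc$image, sc$mask,
                      force = list(hflip = FALSE, vflip = FALSE, angle = 12))
  imw0 <- apply(sc$image, c(2, 3), mean) * sc$mask  # weight by lesion support
  imw1 <- apply(rot$image, c(2, 3), mean) * rot$mask
  d_img <- centroid(imw1) - centroid(imw0)
  d_mask <- centroid(rot$mask) - centroid(sc$mask)
  expect_lt(max(abs(d_img - d_mask)), 0.35)
  # oracle: rotating the centroid coordinates directly
  th <- 12 * pi / 180; cc <- (64 + 1) / 2
  v0 <- centroid(sc$mask) - cc
  pred <- c(cos(th) * v0[1] - sin(th) * v0[2],
            sin(th) * v0[1] + cos(th) * v0[2]) + cc
  expect_lt(max(abs(pred - centroid(rot$mask))), 0.35)
  expect_error(augment_pair(sc$image, sc$mask[1:32, ]), "differ")
})

test_that("the cosine schedule starts at lr and anneals to zero", {
  expect_equal(cosine_lr(1, 300, 1e-4), 1e-4)
  expect_lt(cosine_lr(300, 300, 1e-4), 1e-10)
  lrs <- vapply(1:300, cosine_lr, numeric(1), total = 300, lr = 1e-4)
  expect_true(all(diff(lrs) <= 0))
})

test_that("short training runs are finite, clipped and deterministic", {
  dat <- make_scene_batch(4)
  m <- wavesam_model(test_config(), seed = 3)
  r <- fit(m, dat$images, dat$masks, spec = train_spec(batch_size = 4L),
           steps = 6L, seed = 5)
  expect_true(all(is.finite(r$trace$loss)))
  expect_true(all(r$trace$grad_norm <= 1 + 1e-6))
  expect_equal(r$trace$lr[1], 1e-4)
  m2 <- wavesam_model(test_config(), seed = 3)
  r2 <- fit(m2, dat$images, dat$masks, spec = train_spec(batch_size = 4L),
            steps = 6L, seed = 5)
  expect_equal(r$trace$loss, r2$trace$loss, tolerance = 1e-12)
  expect_error(fit(m, dat$images[0, , , , drop = FALSE], dat$masks), "empty")
})
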