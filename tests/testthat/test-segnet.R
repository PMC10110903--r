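# Segmentation network: architecture shape laws, determinism, gradient
# correctness, training behaviour on learnable toys, and the segmentation
# metrics against brute-force oracles.

test_that("full-scale preset has the 6x6x3x512 = 55296 bottleneck", {
  cfg <- UNetConfig("full", seed = 1)
  expect_equal(bottleneckShape(cfg), c(6L, 6L, 3L, 512L))
  expect_equal(latentLength(cfg), 55296L)
  expect_equal(cfg@learning_rate, 1e-4)
  expect_equal(cfg@batch_size, 4L)
})

test_that("desk preset and the latent length law for any 4-block config", {
  cfg <- UNetConfig("desk", seed = 1)
  expect_equal(bottleneckShape(cfg), c(2L, 2L, 1L, 64L))
  expect_equal(latentLength(cfg), 256L)
  # law: prod(input)/16^3 * last encoder channels
  for (shape in list(c(32, 32, 16), c(48, 16, 16), c(64, 32, 32))) {
    cc <- UNetConfig("desk", input_shape = shape, seed = 1)
    expect_equal(latentLength(cc),
                 prod(shape) / 16^3 * cc@encoder_channels[4])
  }
  expect_error(UNetConfig("desk", input_shape = c(30, 32, 16), seed = 1),
               "divisible by 16")
})

test_that("weight initialization and latent extraction are deterministic", {
  m1 <- buildModel(UNetConfig("desk", seed = 7))
  m2 <- buildModel(UNetConfig("desk", seed = 7))
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(UNetConfig("desk", seed = 8))
  expect_false(identical(m1@weights, m3@weights))
  set.seed(1)
  v <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  expect_identical(extractLatent(m1, v), extractLatent(m1, v))
  expect_length(extractLatent(m1, v), 256)
  expect_error(extractLatent(m1, v[1:16, , ]), "does not match")
})

test_that("latent flattening is x-fastest, then y, z, channel", {
  cfg <- tiny_unet_config()
  m <- buildModel(cfg)
  set.seed(2)
  v <- array(rnorm(16^3), c(16, 16, 16))
  lat <- extractLatent(m, v)
  fw <- desep:::.unet_forward(m@weights, cfg,
                              desep:::.normalize_volume(v, cfg),
                              encoder_only = TRUE)
  expect_identical(lat, as.vector(fw$bottleneck))
  # tiny config bottleneck is 1 x 1 x 1 x 5: element 2 is channel 2
  expect_equal(lat[2], fw$bottleneck[1, 1, 1, 2])
  expect_equal(dim(fw$bottleneck), c(1L, 1L, 1L, 5L))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_unet_config()
  m <- buildModel(cfg)
  set.seed(5)
  vol <- array(rnorm(prod(cfg@input_shape)), cfg@input_shape)
  msk <- array(0, cfg@input_shape); msk[6:10, 6:10, 6:10] <- 1
  lg <- desep:::.unet_loss_grad(m@weights, cfg, vol, msk)
  set.seed(9)
  for (k in names(m@weights)) {
    i <- sample(length(m@weights[[k]]), 1)
    h <- 1e-5
    wp <- m@weights; wp[[k]][i] <- wp[[k]][i] + h
    wm <- m@weights; wm[[k]][i] <- wm[[k]][i] - h
    num <- (desep:::.unet_loss_grad(wp, cfg, vol, msk, grad = FALSE)$loss -
              desep:::.unet_loss_grad(wm, cfg, vol, msk, grad = FALSE)$loss) /
      (2 * h)
    expect_equal(unname(lg$grad[[k]][i]), num, tolerance = 1e-4,
                 info = k)
  }
})

test_that("constant logits give a single-label mask; ties go foreground", {
  cfg <- tiny_unet_config()
  m <- buildModel(cfg)
  # zero final layer -> logits identical -> p = 0.5 everywhere -> foreground
  m@weights[["final.W"]][] <- 0
  m@weights[["final.b"]][] <- 0
  set.seed(3)
  v <- array(rnorm(16^3), c(16, 16, 16))
  mask <- segmentVolume(m, v)
  expect_true(all(mask))
  # biased background logits -> all background
  m@weights[["final.b"]] <- c(5, 0)
  expect_true(!any(segmentVolume(m, v)))
})

test_that("training descends near-monotonically on a convex toy at lr 1e-4", {
  # single informative voxel pattern; loss should be non-increasing up to a
  # small tolerance over consecutive epochs
  cfg <- UNetConfig("desk", input_shape = c(16, 16, 16),
                    encoder_channels = c(2, 2, 2, 2),
                    decoder_deconv_channels = c(2, 2, 2, 2),
                    decoder_conv_channels = c(2, 2, 2, 2),
                    learning_rate = 1e-4, seed = 10)
  m <- buildModel(cfg)
  set.seed(11)
  vol <- array(rnorm(16^3, sd = 0.1), c(16, 16, 16))
  vol[4:12, 4:12, 4:12] <- vol[4:12, 4:12, 4:12] + 2
  msk <- array(0, c(16, 16, 16)); msk[4:12, 4:12, 4:12] <- 1
  m <- trainModel(m, list(vol), list(msk), epochs = 15)
  h <- m@training_history
  expect_lt(tail(h, 1), h[1])
  expect_true(all(diff(h) < 1e-3))
})

test_that("training errors on malformed datasets", {
  cfg <- tiny_unet_config()
  m <- buildModel(cfg)
  expect_error(trainModel(m, list(), list()), "empty training dataset")
  v <- array(0, c(16, 16, 16))
  expect_error(trainModel(m, list(v), list(v[1:8, , ])), "does not match")
  bad <- v; bad[1] <- 0.5
  expect_error(trainModel(m, list(v), list(bad)), "binary")
})

test_that("training is deterministic and improves segmentation", {
  cfg <- desk_phantom_config(n = 6, seed = 51)
  co <- generateCohort(cfg)
  vols <- lapply(co@patients, function(p) p@baseline_volume)
  msks <- lapply(co@patients, function(p) p@baseline_mask * 1)
  net0 <- buildModel(UNetConfig("desk", seed = 51))
  pre <- mean(vapply(1:6, function(i)
    diceCoefficient(segmentVolume(net0, vols[[i]]), msks[[i]]), 0))
  n1 <- trainModel(net0, vols, msks, epochs = 8)
  n2 <- trainModel(net0, vols, msks, epochs = 8)
  expect_identical(n1@weights, n2@weights)
  expect_identical(n1@training_history, n2@training_history)
  post <- mean(vapply(1:6, function(i)
    diceCoefficient(segmentVolume(n1, vols[[i]]), msks[[i]]), 0))
  expect_gt(post, pre)
  expect_lt(tail(n1@training_history, 1), n1@training_history[1])
})

test_that("dice formula, boundaries and conventions", {
  a <- array(0, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- 1
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(0, c(6, 6, 6)); b[5:6, 5:6, 5:6] <- 1
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = 100, |B| = 100, |A n B| = 50 -> 0.5
  A <- array(0, c(10, 10, 2)); A[1:100] <- 1
  B <- array(0, c(10, 10, 2)); B[51:150] <- 1
  expect_equal(sum(A), 100); expect_equal(sum(B), 100)
  expect_equal(sum(A & B), 50)
  expect_equal(diceCoefficient(A, B), 0.5)
  # both empty -> 1; mismatched shapes -> error
  expect_equal(diceCoefficient(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(diceCoefficient(a, array(0, c(2, 2, 2))), "shapes differ")
  expect_true(diceCoefficient(a, b) == diceCoefficient(b, a))
})

test_that("ASSD hand cases and brute-force equivalence", {
  # identical masks -> 0
  a <- array(0, c(8, 8, 8)); a[3:5, 3:5, 3:5] <- 1
  expect_equal(assd(a, a), 0)
  # two single voxels 3 apart on one axis, 1 mm spacing -> 3 mm
  p1 <- array(0, c(8, 8, 8)); p1[2, 4, 4] <- 1
  p2 <- array(0, c(8, 8, 8)); p2[5, 4, 4] <- 1
  expect_equal(assd(p1, p2, c(1, 1, 1)), 3)
  # anisotropic spacing scales the distance
  expect_equal(assd(p1, p2, c(2, 1, 1)), 6)
  # empty mask is an error
  expect_error(assd(a, array(0, c(8, 8, 8))), "empty mask")
  # cube vs dilated cube matches the all-pairs oracle to 1e-9
  cube <- array(0, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1
  dil <- array(0, c(14, 14, 14)); dil[2:13, 2:13, 2:13] <- 1
  sp <- c(1, 1, 1)
  expect_equal(assd(cube, dil, sp), bf_assd(cube, dil, sp),
               tolerance = 1e-9)
  set.seed(12)
  r1 <- array(runif(6^3) < 0.3, c(6, 6, 6))
  r2 <- array(runif(6^3) < 0.3, c(6, 6, 6))
  sp2 <- c(1.2, 0.7, 2.5)
  expect_equal(assd(r1, r2, sp2), bf_assd(r1, r2, sp2), tolerance = 1e-9)
  expect_equal(assd(r1, r2, sp2), assd(r2, r1, sp2))
})
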