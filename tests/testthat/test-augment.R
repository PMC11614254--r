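geom_only <- function(...) {
  base <- list(rotation = NULL, scale = NULL, translation = NULL, crop = NULL,
               hflip = FALSE, vflip = FALSE, gamma = NULL,
               brightness_contrast = NULL, salt_pepper = NULL,
               gaussian_noise = NULL, blur_kernels = NULL,
               median_kernels = NULL, cutout = NULL)
  over <- list(...)
  base[names(over)] <- over
  do.call(augmentation_config, base)
}

test_that("with nothing firing the output is a center crop with mask unchanged", {
  set.seed(81)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- random_mask(64, 64)
  cfg <- augmentation_config(crop = 32, prob = 0) # nothing fires; crop centered
  a <- augment(img, msk, cfg)
  expect_identical(dim(a$image), c(32L, 32L))
  expect_identical(a$image, img[17:48, 17:48])
  expect_identical(a$mask, msk[17:48, 17:48])
})

test_that("horizontal flip reverses mask columns and is an involution", {
  set.seed(82)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- random_mask(32, 32)
  cfg <- geom_only(hflip = TRUE, prob = 1)
  a <- augment(img, msk, cfg)
  expect_identical(a$mask, msk[, 32:1])
  b <- augment(a$image, a$mask, cfg)
  expect_identical(b$mask, msk)
  expect_equal(b$image, img)
})

test_that("a +5 degree rotation moves a single-pixel mask as predicted analytically", {
  img <- matrix(0, 64, 64)
  msk <- matrix(FALSE, 64, 64)
  msk[20, 44] <- TRUE
  cfg <- geom_only(rotation = c(5, 5), prob = 1)
  set.seed(83)
  a <- augment(img, msk, cfg)
  got <- which(a$mask, arr.ind = TRUE)
  expect_equal(nrow(got), 1L)
  # forward rotation of the source pixel about the image center
  th <- 5 * pi / 180; ctr <- (64 + 1) / 2
  d <- c(20, 44) - ctr
  want <- c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2]) + ctr
  expect_lt(max(abs(as.numeric(got) - want)), 1)
})

test_that("small rotations approximately preserve mask area", {
  set.seed(84)
  msk <- matrix(FALSE, 64, 64); msk[25:40, 28:36] <- TRUE
  img <- msk * 1
  cfg <- geom_only(rotation = c(-5, 5), prob = 1)
  for (i in 1:10) {
    a <- augment(img, msk, cfg)
    expect_lt(abs(sum(a$mask) - sum(msk)) / sum(msk), 0.1)
  }
})

test_that("intensity transforms never touch the mask and stay in [0,1]", {
  set.seed(85)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- random_mask(64, 64)
  cfg <- augmentation_config(rotation = NULL, scale = NULL, translation = NULL,
                             crop = NULL, hflip = FALSE, vflip = FALSE, prob = 1)
  for (i in 1:5) {
    a <- augment(img, msk, cfg)
    expect_identical(a$mask, msk)
    expect_true(all(a$image >= 0 & a$image <= 1))
    expect_false(identical(a$image, img))
  }
})

test_that("augmentation is reproducible under a fixed RNG seed", {
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- random_mask(64, 64)
  cfg <- augmentation_config(crop = 48)
  set.seed(86); a1 <- augment(img, msk, cfg)
  set.seed(86); a2 <- augment(img, msk, cfg)
  expect_identical(a1, a2)
})

test_that("a crop larger than the image is a config error", {
  expect_error(augment(matrix(0, 32, 32), matrix(FALSE, 32, 32),
                       augmentation_config(crop = 64)),
               "crop")
})
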