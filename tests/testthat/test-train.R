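small_fit <- function(epochs = 1, seed = 5, dsc_every = 0) {
  man <- filter_empty_slices(phantom_store())
  model <- build_model(model_spec(width_multiplier = 0.0625), seed = seed)
  cfg <- train_config(epochs = epochs, batch_size = 8, lr0 = 1e-3,
                      milestones = integer(0), seed = seed)
  train_model(model, man, cfg, dsc_every = dsc_every)
}

test_that("history has one row per epoch with the scheduled learning rate", {
  fit <- small_fit(epochs = 1)
  h <- tidy(fit)
  expect_equal(nrow(h), 1L)
  expect_equal(h$lr, 1e-3)
  expect_true(is.finite(h$loss) && h$loss >= 0)
  g <- glance(fit)
  expect_equal(g$epochs, 1L)
})

test_that("training is reproducible for a fixed seed", {
  f1 <- small_fit(epochs = 1, seed = 11)
  f2 <- small_fit(epochs = 1, seed = 11)
  expect_equal(tidy(f1)$loss, tidy(f2)$loss, tolerance = 1e-6)
  f3 <- small_fit(epochs = 1, seed = 12)
  expect_false(isTRUE(all.equal(tidy(f1)$loss, tidy(f3)$loss, tolerance = 1e-9)))
})

test_that("the loss decreases over a short run and DSC is tracked", {
  fit <- small_fit(epochs = 4, dsc_every = 2)
  h <- tidy(fit)
  expect_lt(h$loss[4], h$loss[1])
  expect_true(is.na(h$dsc[1]) && !is.na(h$dsc[4]))
})

test_that("empty manifests and missing masks are training errors", {
  man <- phantom_store()
  model <- build_model(model_spec(width_multiplier = 0.0625), seed = 1)
  empty <- man[0, ]; attr(empty, "root") <- attr(man, "root")
  expect_error(train_model(model, empty), "no training data")
  noMask <- man[1:2, ]; noMask$mask <- NA_character_
  attr(noMask, "root") <- attr(man, "root")
  expect_error(train_model(model, noMask), "ground-truth mask")
})

test_that("augmented training runs end to end on crop-sized inputs", {
  man <- filter_empty_slices(phantom_store())
  man <- man[1:8, ]; attr(man, "root") <- attr(phantom_store(), "root")
  model <- build_model(model_spec(width_multiplier = 0.0625), seed = 2)
  aug <- augmentation_config(crop = 64, translation = 8)
  cfg <- train_config(epochs = 1, batch_size = 4, lr0 = 1e-3,
                      milestones = integer(0), seed = 2)
  fit <- train_model(model, man, cfg, aug_cfg = aug, dsc_every = 0)
  expect_equal(nrow(tidy(fit)), 1L)
})

test_that("YAML configs mirror the configuration objects field for field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "train:",
    "  epochs: 12",
    "  batch_size: 4",
    "  lr0: 1.0e-3",
    "  milestones: [6, 9]",
    "  seed: 3",
    "loss:",
    "  alpha: 0.6",
    "  beta: 0.4",
    "augment:",
    "  crop: 64",
    "  translation: 10"
  ), f)
  cfgs <- read_train_config(f)
  expect_equal(cfgs$train$epochs, 12L)
  expect_equal(cfgs$train$milestones, c(6L, 9L))
  expect_equal(cfgs$loss$alpha, 0.6)
  expect_equal(cfgs$loss$gamma, 0.75) # defaults fill unset fields
  expect_equal(cfgs$augment$crop, 64)
  expect_equal(cfgs$augment$rotation, c(-5, 5))
})

test_that("grouped CV trains one fold per patient group with no leakage", {
  man <- phantom_store()
  cv <- train_cv(model_spec(width_multiplier = 0.0625), man,
                 train_config(epochs = 1, batch_size = 8, lr0 = 1e-3,
                              milestones = integer(0), folds = 3, seed = 1))
  expect_length(cv$folds, 3L)
  expect_equal(nrow(cv$metrics), 3L)
  expect_setequal(cv$assignment$patient_id, unique(man$patient_id))
  expect_true(all(cv$metrics$dsc >= 0 & cv$metrics$dsc <= 1))
})
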