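test_that("grouped folds are a disjoint, exhaustive patient partition", {
  pats <- sprintf("p%02d", 1:13)
  tbl <- group_kfold_split(pats, k = 5, seed = 3)
  expect_setequal(tbl$patient_id, pats)
  expect_equal(sort(as.integer(table(tbl$fold)), decreasing = TRUE),
               c(3L, 3L, 3L, 2L, 2L))
  # every patient in exactly one fold
  expect_false(anyDuplicated(tbl$patient_id) > 0)
  # slice-weighted: a patient's slices never straddle folds by construction
  slices <- rep(pats, times = sample(3:8, 13, replace = TRUE))
  tbl2 <- group_kfold_split(slices, k = 5, seed = 3)
  expect_setequal(tbl2$patient_id, pats)
})

test_that("5 patients over 5 folds validate exactly one patient each", {
  tbl <- group_kfold_split(letters[1:5], k = 5, seed = 1)
  expect_equal(as.integer(table(tbl$fold)), rep(1L, 5))
  expect_error(group_kfold_split(letters[1:4], k = 5), "fewer distinct patients")
})

test_that("the 20% hold-out splits 80 scans into 64 train / 16 test", {
  ids <- sprintf("s%03d", 1:80)
  sp <- holdout_split(ids, test_fraction = 0.2, seed = 9)
  expect_equal(length(sp$test), 16L)
  expect_equal(length(sp$train), 64L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("empty-slice filtering keeps exactly the generator's organ slices", {
  man <- phantom_store()
  kept <- filter_empty_slices(man)
  expect_identical(kept$mask_area > 0, rep(TRUE, nrow(kept)))
  expect_identical(kept$image, man$image[man$mask_area > 0])
  # all-empty manifests are legal and come back empty
  empty <- man[man$mask_area == 0, ]
  attr(empty, "root") <- attr(man, "root")
  expect_equal(nrow(filter_empty_slices(empty)), 0L)
})

test_that("merging manifests preserves slices and rejects collisions", {
  man <- phantom_store()
  a <- man[man$patient_id == "phantom001", ]
  b <- man[man$patient_id == "phantom002", ]
  attr(a, "root") <- attr(b, "root") <- attr(man, "root")
  ab <- merge_datasets(a, b)
  expect_equal(nrow(ab), nrow(a) + nrow(b))
  expect_error(merge_datasets(a, a), "collision")
  # a same-patient manifest from a different source is not a collision
  b2 <- a; b2$source <- "hospital"
  attr(b2, "root") <- attr(man, "root")
  merged <- merge_datasets(a, b2)
  expect_equal(nrow(merged), 2L * nrow(a))
  # grouped folds on the merged manifest keep (source, patient) together:
  # the same patient_id from two sources is one group under patient_id only
  # if sources are not distinguished, so split on the composite key
  key <- paste(merged$source, merged$patient_id)
  tbl <- group_kfold_split(key, k = 2, seed = 1)
  expect_equal(nrow(tbl), 2L)
})

test_that("the learning-rate schedule follows the milestone rule", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(10, cfg), 1e-4)
  expect_equal(lr_at_epoch(19, cfg), 1e-4)
  expect_equal(lr_at_epoch(20, cfg), 1e-5)
  expect_equal(lr_at_epoch(25, cfg), 1e-5)
  expect_equal(lr_at_epoch(35, cfg), 1e-6)
  expect_equal(lr_at_epoch(45, cfg), 1e-7)
  expect_error(lr_at_epoch(50, cfg))
  expect_error(train_config(epochs = 30), "milestones")  # default milestones reach 40
  expect_error(train_config(epochs = 50, milestones = c(30, 20)), "milestones")
})
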