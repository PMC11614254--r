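blob <- function(r, c, size = 16) {
  m <- matrix(FALSE, size, size); m[r, c] <- TRUE; m
}

demo_session <- function() {
  s <- new_session("DL-assisted")
  s <- register_scan(s, "scanA", 3, proposals = list(blob(2:4, 2:4), blob(5:7, 5:7), NULL))
  s <- register_scan(s, "scanB", 2, proposals = list(blob(1:2, 1:2), blob(8, 8)))
  s
}

test_that("proposals attach one mask per slice with no events", {
  man <- phantom_store()
  model <- build_model(model_spec(width_multiplier = 0.0625), seed = 1)
  s <- propose(man, model)
  expect_length(s$events, 0)
  expect_setequal(names(s$scans), unique(man$patient_id))
  one <- s$scans[[man$patient_id[1]]]
  expect_equal(one$slice_count, sum(man$patient_id == man$patient_id[1]))
  expect_true(all(vapply(one$proposals, is.matrix, logical(1))))
  expect_true(all(one$status == "proposed"))
})

test_that("accept freezes the proposal and flags it unmodified", {
  s <- demo_session()
  s <- apply_edit(s, edit_event("scanA", 0, "accept", elapsed = 4))
  expect_identical(final_masks(s, "scanA")[[1]], blob(2:4, 2:4))
  expect_true(s$scans$scanA$accepted_clean[1])
  # a later region edit clears the unmodified flag
  s <- apply_edit(s, edit_event("scanA", 0, "erase_region", payload = blob(2, 2), elapsed = 3))
  expect_false(s$scans$scanA$accepted_clean[1])
  expect_identical(final_masks(s, "scanA")[[1]], blob(2:4, 2:4) & !blob(2, 2))
})

test_that("region edits behave as set operations; replace and create install masks", {
  s <- demo_session()
  # add then erase the same region on an empty proposal slice -> empty mask
  s <- apply_edit(s, edit_event("scanB", 1, "replace", payload = blob(8, 8) & FALSE, elapsed = 1))
  s <- apply_edit(s, edit_event("scanB", 1, "add_region", payload = blob(3, 3), elapsed = 2))
  s <- apply_edit(s, edit_event("scanB", 1, "erase_region", payload = blob(3, 3), elapsed = 2))
  expect_false(any(final_masks(s, "scanB")[[2]]))
  # replace overrides whatever was there
  M <- blob(10:12, 3:9)
  s <- apply_edit(s, edit_event("scanA", 1, "replace", payload = M, elapsed = 7))
  expect_identical(final_masks(s, "scanA")[[2]], M)
  # create is only legal on slices without a proposal
  s <- apply_edit(s, edit_event("scanA", 2, "create", payload = M, elapsed = 9))
  expect_identical(final_masks(s, "scanA")[[3]], M)
  expect_error(apply_edit(s, edit_event("scanA", 0, "create", payload = M)),
               "already has a proposal")
  expect_error(apply_edit(s, edit_event("nope", 0, "accept")), "unknown scan")
  expect_error(apply_edit(s, edit_event("scanA", 9, "accept")), "out of range")
  expect_warning(apply_edit(s, edit_event("scanB", 1, "erase_region",
                                          payload = blob(1, 1), elapsed = 1)),
                 "no-op")
  expect_error(edit_event("scanA", 0, "accept", elapsed = -1), "elapsed")
})

test_that("session summaries derive every ratio from the totals", {
  s <- demo_session()
  s <- apply_edit(s, edit_event("scanA", 0, "accept", elapsed = 5))
  s <- apply_edit(s, edit_event("scanA", 1, "accept", elapsed = 2))
  s <- apply_edit(s, edit_event("scanB", 0, "replace", payload = blob(4, 4), elapsed = 14))
  ss <- session_summary(s)
  expect_equal(ss$n_scans, 2)
  expect_equal(ss$total_time_s, 21)
  expect_equal(ss$total_slices, 3) # three non-empty final masks
  expect_equal(ss$time_per_slice_s, 21 / 3)
  expect_equal(ss$avg_time_per_scan_s, 21 / 2)
  expect_equal(ss$avg_slices_per_scan, 3 / 2)
  expect_equal(ss$fraction_unmodified, 2 / 3)
  # single scan, single slice, one 7 s event
  s1 <- register_scan(new_session(), "only", 1, proposals = list(blob(2, 2)))
  s1 <- apply_edit(s1, edit_event("only", 0, "accept", elapsed = 7))
  expect_equal(session_summary(s1)$time_per_slice_s, 7)
})

test_that("fraction_unmodified spans 0 to 1 with all-accept / no-accept sessions", {
  s <- demo_session()
  s <- apply_edit(s, edit_event("scanA", 0, "accept", elapsed = 1))
  s <- apply_edit(s, edit_event("scanA", 1, "accept", elapsed = 1))
  s <- apply_edit(s, edit_event("scanB", 0, "accept", elapsed = 1))
  s <- apply_edit(s, edit_event("scanB", 1, "accept", elapsed = 1))
  expect_equal(session_summary(s)$fraction_unmodified, 1)
  r <- demo_session()
  r <- apply_edit(r, edit_event("scanA", 0, "replace", payload = blob(3, 3), elapsed = 1))
  expect_equal(session_summary(r)$fraction_unmodified, 0)
})

test_that("per-scan elapsed sums to the session total", {
  set.seed(95)
  s <- demo_session()
  times <- c()
  for (i in 1:20) {
    scan <- sample(c("scanA", "scanB"), 1)
    idx <- sample(0:1, 1)
    el <- round(runif(1, 1, 30))
    s <- apply_edit(s, edit_event(scan, idx, "add_region",
                                  payload = blob(sample(16, 1), sample(16, 1)),
                                  elapsed = el))
    times <- c(times, el)
  }
  expect_equal(sum(vapply(s$events, function(e) e$elapsed, numeric(1))), sum(times))
  expect_equal(session_summary(s)$total_time_s, sum(times))
})

test_that("exported sessions replay to bit-identical final masks", {
  set.seed(96)
  for (rep in 1:5) {
    s <- new_session(sprintf("tool%d", rep))
    for (sc in c("s1", "s2")) {
      props <- lapply(1:4, function(i) if (runif(1) < 0.8) random_mask() else NULL)
      s <- register_scan(s, sc, 4, proposals = props)
    }
    for (k in 1:20) {
      sc <- sample(c("s1", "s2"), 1)
      i <- sample(0:3, 1)
      has_prop <- !is.null(s$scans[[sc]]$proposals[[i + 1]])
      action <- if (has_prop) sample(c("accept", "replace", "add_region", "erase_region"), 1)
                else sample(c("create", "replace"), 1)
      if (action == "create" && !is.null(s$scans[[sc]]$proposals[[i + 1]])) action <- "replace"
      payload <- if (action == "accept") NULL else random_mask()
      s <- suppressWarnings(
        apply_edit(s, edit_event(sc, i, action, payload = payload,
                                 elapsed = round(runif(1, 0, 20), 1))))
    }
    dir <- withr::local_tempdir()
    f <- file.path(dir, "log.json")
    export_session(s, f)
    s2 <- import_session(f)
    for (sc in c("s1", "s2"))
      expect_identical(final_masks(s2, sc), final_masks(s, sc))
    expect_equal(unclass(session_summary(s2))[1:7], unclass(session_summary(s))[1:7])
  }
})

test_that("corrupted logs are rejected with context", {
  s <- demo_session()
  s <- apply_edit(s, edit_event("scanA", 0, "accept", elapsed = 5))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "log.json")
  export_session(s, f)
  txt <- readLines(f)
  writeLines(sub('"elapsed": 5', '"elapsed": -5', txt), f)
  expect_error(import_session(f), "negative")
  writeLines("{ not json", f)
  expect_error(import_session(f), "malformed")
})

test_that("speed-up reporting matches published-table arithmetic", {
  ext_dl <- session_summary_from_totals(32, 3223, 1313, tool_tag = "assisted")
  ext_man <- session_summary_from_totals(32, 8486, 926, tool_tag = "manual")
  cmp <- compare_sessions(ext_dl, ext_man)
  expect_equal(cmp$assisted_s_per_slice, 2.5)
  expect_equal(cmp$manual_s_per_slice, 9.2)
  expect_equal(round(cmp$speedup, 2), 3.68)
  # identical summaries give speed-up 1
  expect_equal(compare_sessions(ext_dl, ext_dl)$speedup, 1)
  oul_dl <- session_summary_from_totals(39, 10304, 2402)
  oul_man <- session_summary_from_totals(31, 12287, 884)
  cmp2 <- compare_sessions(oul_dl, oul_man)
  expect_equal(round(cmp2$speedup, 2), 3.23)
  rep <- speedup_report(list(external = list(assisted = ext_dl, manual = ext_man),
                             oulu = list(assisted = oul_dl, manual = oul_man)))
  expect_equal(round(rep$pooled_speedup, 2), 3.15)
  expect_equal(rep$mean_of_ratios, (9.2 / 2.5 + 13.9 / 4.3) / 2, tolerance = 1e-9)
  expect_equal(round(rep$mean_of_ratios, 1), 3.5)
})
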