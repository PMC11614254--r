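# Headless model-assisted annotation sessions. A session is an event-sourced
# log: model proposals plus reviewer accept/edit events (with externally
# supplied elapsed times) fully determine the final masks, so replaying an
# exported log reproduces them bit-exactly. Timing is never measured
# internally; it comes from the event records, which keeps summaries
# deterministic.

#' Create an empty annotation session
#'
#' @param tool_tag Free-text tool label recorded with the session (e.g.
#'   "DL-assisted" or "manual").
#' @return Object of class `ctseg_session`.
#' @export
new_session <- function(tool_tag = "DL-assisted") {
  structure(list(tool_tag = tool_tag, scans = list(), events = list()),
            class = "ctseg_session")
}

#' Register a scan with a session
#'
#' @param session A `ctseg_session`.
#' @param scan_id Scan identifier.
#' @param slice_count Number of axial slices.
#' @param proposals Optional list of proposed masks (logical matrices or
#'   `NULL`), length `slice_count`.
#' @return The updated session.
#' @export
register_scan <- function(session, scan_id, slice_count, proposals = NULL) {
  stopifnot(inherits(session, "ctseg_session"), slice_count >= 1)
  if (scan_id %in% names(session$scans))
    stop("scan ", scan_id, " already registered", call. = FALSE)
  if (is.null(proposals)) proposals <- vector("list", slice_count)
  stopifnot(length(proposals) == slice_count)
  session$scans[[scan_id]] <- list(
    scan_id = scan_id, slice_count = as.integer(slice_count),
    proposals = proposals,
    finals = vector("list", slice_count),
    status = rep("proposed", slice_count),
    accepted_clean = rep(FALSE, slice_count)
  )
  session
}

#' Propose masks for every scan of a manifest
#'
#' Runs the model over each scan in the manifest and attaches one proposed
#' mask per slice to a new (or supplied) session; every slice starts in the
#' "proposed" state with no events logged.
#'
#' @param manifest Manifest tibble (see [convert_volume()]).
#' @param model A `ctseg_model`.
#' @param session Session to attach to (default a fresh one).
#' @param threshold Probability threshold for [predict_mask()].
#' @return The session with proposals attached.
#' @export
propose <- function(manifest, model, session = new_session(), threshold = 0.5) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  data <- load_manifest_data(manifest)
  preds <- predict_mask(model, data$images, threshold = threshold)
  for (pid in unique(manifest$patient_id)) {
    i <- which(manifest$patient_id == pid)
    session <- register_scan(session, pid, length(i), proposals = preds[i])
  }
  session
}

#' Construct a reviewer edit event
#'
#' @param scan_id Scan identifier.
#' @param slice_index 0-based slice index.
#' @param action One of `"accept"`, `"replace"`, `"add_region"`,
#'   `"erase_region"`, `"create"`.
#' @param payload Logical mask matrix (required for all actions except
#'   `accept`); for region actions it is the pixel set to union/subtract.
#' @param elapsed Reviewer time spent, in seconds (>= 0).
#' @return Object of class `ctseg_edit`.
#' @export
edit_event <- function(scan_id, slice_index, action, payload = NULL, elapsed = 0) {
  action <- match.arg(action, c("accept", "replace", "add_region", "erase_region", "create"))
  if (!is.numeric(elapsed) || elapsed < 0)
    stop("`elapsed` must be a non-negative number of seconds", call. = FALSE)
  if (action != "accept") {
    if (is.null(payload)) stop("action '", action, "' requires a mask payload", call. = FALSE)
    if (is.numeric(payload)) payload <- payload > 0
    stopifnot(is.logical(payload), is.matrix(payload))
  }
  structure(list(scan_id = scan_id, slice_index = as.integer(slice_index),
                 action = action, payload = payload, elapsed = as.numeric(elapsed)),
            class = "ctseg_edit")
}

#' Apply a reviewer edit to a session
#'
#' `accept` freezes the proposal as the final mask and flags the slice as
#' accepted without revision; `replace` substitutes the payload; `add_region`
#' and `erase_region` take set union/difference with the current final mask
#' (starting from the proposal, or an empty mask when there is none);
#' `create` installs a mask on a slice with no proposal. Any edit after an
#' accept clears the slice's unmodified flag. Erasing from an empty mask
#' warns and is a no-op. Events are append-only.
#'
#' @param session A `ctseg_session`.
#' @param event A [edit_event()].
#' @return The updated session.
#' @export
apply_edit <- function(session, event) {
  stopifnot(inherits(session, "ctseg_session"), inherits(event, "ctseg_edit"))
  sc <- session$scans[[event$scan_id]]
  if (is.null(sc)) stop("unknown scan ", event$scan_id, call. = FALSE)
  i <- event$slice_index + 1L
  if (i < 1L || i > sc$slice_count)
    stop("slice index ", event$slice_index, " out of range for scan ",
         event$scan_id, call. = FALSE)
  current <- sc$finals[[i]]
  if (is.null(current)) current <- sc$proposals[[i]]
  if (!is.null(event$payload) && !is.null(current) &&
      !identical(dim(event$payload), dim(current)))
    stop("payload shape does not match slice shape", call. = FALSE)

  switch(event$action,
    accept = {
      if (is.null(sc$proposals[[i]]))
        stop("cannot accept: slice has no proposal", call. = FALSE)
      sc$finals[[i]] <- sc$proposals[[i]]
      sc$status[i] <- "accepted"
      sc$accepted_clean[i] <- TRUE
    },
    replace = {
      sc$finals[[i]] <- event$payload
      sc$status[i] <- "edited"
      sc$accepted_clean[i] <- FALSE
    },
    add_region = {
      base <- if (is.null(current)) event$payload & FALSE else current
      sc$finals[[i]] <- base | event$payload
      sc$status[i] <- "edited"
      sc$accepted_clean[i] <- FALSE
    },
    erase_region = {
      if (is.null(current) || !any(current)) {
        warning("erase_region on an empty mask: no-op", call. = FALSE)
        sc$finals[[i]] <- if (is.null(current)) event$payload & FALSE else current
      } else {
        sc$finals[[i]] <- current & !event$payload
      }
      sc$status[i] <- "edited"
      sc$accepted_clean[i] <- FALSE
    },
    create = {
      if (!is.null(sc$proposals[[i]]))
        stop("cannot create: slice already has a proposal (use replace)", call. = FALSE)
      sc$finals[[i]] <- event$payload
      sc$status[i] <- "created"
      sc$accepted_clean[i] <- FALSE
    }
  )
  session$scans[[event$scan_id]] <- sc
  session$events[[length(session$events) + 1L]] <- event
  session
}

#' Final masks of a scan
#'
#' @param session A `ctseg_session`.
#' @param scan_id Scan identifier.
#' @return List of logical matrices (`NULL` where no final mask exists).
#' @export
final_masks <- function(session, scan_id) {
  sc <- session$scans[[scan_id]]
  if (is.null(sc)) stop("unknown scan ", scan_id, call. = FALSE)
  sc$finals
}

#' Summarize an annotation session
#'
#' Totals and throughput ratios: `time_per_slice_s = total_time_s /
#' total_slices`, `avg_time_per_scan_s = total_time_s / n_scans`,
#' `avg_slices_per_scan = total_slices / n_scans`. `total_slices` counts
#' annotated slices (non-empty final mask), matching how annotation workloads
#' are reported; `fraction_unmodified` is the share of those slices whose mask
#' is an unrevised model proposal. Ratios are stored exactly; rounding happens
#' at reporting time ([summary_table()]).
#'
#' @param session A `ctseg_session` with at least one annotated slice.
#' @return Object of class `ctseg_session_summary`.
#' @export
session_summary <- function(session) {
  stopifnot(inherits(session, "ctseg_session"))
  if (length(session$scans) == 0L) stop("session has no scans", call. = FALSE)
  total_time <- sum(vapply(session$events, function(e) e$elapsed, numeric(1)))
  annotated <- unlist(lapply(session$scans, function(sc)
    vapply(sc$finals, function(m) !is.null(m) && any(m), logical(1))))
  clean <- unlist(lapply(session$scans, function(sc) sc$accepted_clean))
  total_slices <- sum(annotated)
  if (total_slices == 0L) stop("session has no annotated slices", call. = FALSE)
  session_summary_from_totals(
    n_scans = length(session$scans),
    total_time_s = total_time,
    total_slices = total_slices,
    fraction_unmodified = sum(clean & annotated) / total_slices,
    tool_tag = session$tool_tag
  )
}

#' Build a session summary from recorded totals
#'
#' Ratio fields are always derived from the totals, never stored
#' independently.
#'
#' @param n_scans,total_time_s,total_slices Recorded totals.
#' @param fraction_unmodified Share of annotated slices accepted without
#'   revision (`NA` when unknown, e.g. for a purely manual tool).
#' @param tool_tag Tool label.
#' @return Object of class `ctseg_session_summary` with fields `n_scans`,
#'   `total_time_s`, `total_slices`, `time_per_slice_s`, `avg_time_per_scan_s`,
#'   `avg_slices_per_scan`, `fraction_unmodified`, `tool_tag`.
#' @export
session_summary_from_totals <- function(n_scans, total_time_s, total_slices,
                                        fraction_unmodified = NA_real_,
                                        tool_tag = "") {
  stopifnot(n_scans >= 1, total_slices >= 1, total_time_s >= 0)
  if (!is.na(fraction_unmodified) &&
      (fraction_unmodified < 0 || fraction_unmodified > 1))
    stop("`fraction_unmodified` must be in [0, 1]", call. = FALSE)
  structure(list(
    n_scans = n_scans, total_time_s = total_time_s, total_slices = total_slices,
    time_per_slice_s = total_time_s / total_slices,
    avg_time_per_scan_s = total_time_s / n_scans,
    avg_slices_per_scan = total_slices / n_scans,
    fraction_unmodified = fraction_unmodified, tool_tag = tool_tag
  ), class = "ctseg_session_summary")
}

round_report <- function(x, digits = 1) round_half_away(x * 10^digits) / 10^digits

#' @export
print.ctseg_session_summary <- function(x, ...) {
  cat(sprintf("<session summary> %s: %d scans, %g s over %d slices (%.1f s/slice)\n",
              x$tool_tag, x$n_scans, x$total_time_s, x$total_slices,
              round_report(x$time_per_slice_s)))
  invisible(x)
}

#' Report a session summary with the standard row labels
#'
#' @param summary A `ctseg_session_summary`.
#' @param digits Decimal places for the ratio rows (rounded half away from
#'   zero; default 1).
#' @return Tibble with columns `quantity` and `value`.
#' @export
summary_table <- function(summary, digits = 1) {
  stopifnot(inherits(summary, "ctseg_session_summary"))
  tibble::tibble(
    quantity = c("Number of scans", "Total time (seconds)", "Total slices",
                 "Time per slice (seconds)", "Average time per scan (seconds)",
                 "Average number of slices in a scan"),
    value = c(summary$n_scans, summary$total_time_s, summary$total_slices,
              round_report(summary$time_per_slice_s, digits),
              round_report(summary$avg_time_per_scan_s, digits),
              round_report(summary$avg_slices_per_scan, digits))
  )
}

#' Per-slice annotation speed-up of one tool over another
#'
#' Ratio of manual to assisted time per slice. By default both rates are first
#' rounded to reporting precision (1 decimal), matching how the ratio is read
#' off published summary tables; `digits = NULL` uses the exact stored rates.
#'
#' @param assisted,manual `ctseg_session_summary` objects.
#' @param digits Rounding applied to each rate before division (default 1;
#'   `NULL` for exact).
#' @return One-row tibble: both rates and `speedup`.
#' @export
compare_sessions <- function(assisted, manual, digits = 1) {
  stopifnot(inherits(assisted, "ctseg_session_summary"),
            inherits(manual, "ctseg_session_summary"))
  a <- assisted$time_per_slice_s; m <- manual$time_per_slice_s
  if (!is.null(digits)) {
    a <- round_report(a, digits); m <- round_report(m, digits)
  }
  if (a == 0) stop("assisted time per slice is zero: speed-up undefined", call. = FALSE)
  tibble::tibble(assisted_s_per_slice = a, manual_s_per_slice = m,
                 speedup = m / a)
}

#' Multi-dataset speed-up report
#'
#' For each (assisted, manual) summary pair, the per-slice speed-up; plus two
#' aggregations that answer "how much faster on average" differently: the
#' pooled ratio (total manual time over total manual slices, divided by the
#' same for the assisted tool) and the unweighted mean of the per-dataset
#' ratios. The two can differ noticeably when datasets have different sizes,
#' so both are always reported.
#'
#' @param pairs Named list; each element a list with `assisted` and `manual`
#'   `ctseg_session_summary` objects.
#' @param digits Reporting precision for the per-dataset rates (see
#'   [compare_sessions()]).
#' @return List with `per_dataset` (tibble), `pooled_speedup` and
#'   `mean_of_ratios`.
#' @export
speedup_report <- function(pairs, digits = 1) {
  per <- dplyr::bind_rows(purrr::imap(pairs, function(p, nm)
    dplyr::mutate(compare_sessions(p$assisted, p$manual, digits = digits),
                  dataset = nm, .before = 1L)))
  tot <- function(get) sum(purrr::map_dbl(pairs, get))
  pooled <- (tot(~.x$manual$total_time_s) / tot(~.x$manual$total_slices)) /
    (tot(~.x$assisted$total_time_s) / tot(~.x$assisted$total_slices))
  list(per_dataset = per, pooled_speedup = pooled,
       mean_of_ratios = mean(per$speedup))
}

# ---- export / import ---------------------------------------------------------

#' Export / import a session log
#'
#' The session is written as a JSON log with every mask (proposals and event
#' payloads) stored as a binary PNG referenced by relative path, so the log
#' round-trips losslessly: importing replays the event log through
#' [apply_edit()], reproducing the final masks bit-exactly.
#'
#' @param session A `ctseg_session`.
#' @param path JSON file path; masks go to `<path-sans-ext>_masks/`.
#' @return `export_session()`: `path` invisibly; `import_session()`: the
#'   reconstructed session.
#' @export
export_session <- function(session, path) {
  stopifnot(inherits(session, "ctseg_session"))
  mask_dir_rel <- paste0(sub("\\.json$", "", basename(path)), "_masks")
  mask_dir <- file.path(dirname(path), mask_dir_rel)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  save_mask <- function(m, name) {
    rel <- file.path(mask_dir_rel, paste0(name, ".png"))
    write_mask_png(m, file.path(dirname(path), rel))
    rel
  }
  scans <- purrr::imap(session$scans, function(sc, sid) {
    props <- purrr::imap(sc$proposals, function(m, i) {
      if (is.null(m)) NULL else save_mask(m, sprintf("%s_prop_%04d", sid, i - 1L))
    })
    list(scan_id = sid, slice_count = sc$slice_count, proposals = props)
  })
  events <- purrr::imap(session$events, function(e, k) {
    list(scan_id = e$scan_id, slice_index = e$slice_index, action = e$action,
         elapsed = e$elapsed,
         payload = if (is.null(e$payload)) NULL
                   else save_mask(e$payload, sprintf("event_%05d", k)))
  })
  jsonlite::write_json(
    list(tool_tag = session$tool_tag, scans = unname(scans), events = unname(events)),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname export_session
#' @export
import_session <- function(path) {
  log <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed session log ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  for (k in seq_along(log$events)) {
    e <- log$events[[k]]
    if (is.null(e$elapsed) || e$elapsed < 0)
      stop("invalid session log: event ", k, " has negative or missing elapsed time",
           call. = FALSE)
  }
  root <- dirname(path)
  session <- new_session(log$tool_tag %||% "")
  for (sc in log$scans) {
    props <- purrr::map(sc$proposals, function(p)
      if (is.null(p)) NULL else read_mask_png(file.path(root, p)))
    session <- register_scan(session, sc$scan_id, sc$slice_count, proposals = props)
  }
  for (e in log$events) {
    payload <- if (is.null(e$payload)) NULL else read_mask_png(file.path(root, e$payload))
    session <- apply_edit(session, edit_event(e$scan_id, e$slice_index, e$action,
                                              payload = payload, elapsed = e$elapsed))
  }
  session
}
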