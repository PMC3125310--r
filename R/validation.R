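# Model-vs-ambulance driving-time validation: load logged trips, filter by
# departure time windows, compare model minutes with logged ambulance
# minutes, and summarize deviations overall and per identical
# origin-destination pair.

#' Load an ambulance trip log from CSV
#'
#' Expects columns `origin,destination,depart_time,model_min,ambulance_min`.
#' `depart_time` is an optional `HH:MM` clock time (ambulance paper logs
#' record minutes only); `model_min` and `ambulance_min` are whole,
#' nonnegative minutes.
#'
#' @param path CSV file path.
#' @return a `trip_log` data frame. An empty file (header only) yields an
#'   empty log.
#' @export
load_trip_log <- function(path) {
  if (!file.exists(path)) stop("trip log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  need <- c("origin", "destination", "depart_time", "model_min", "ambulance_min")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("trip log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  model <- suppressWarnings(as.numeric(df$model_min))
  amb <- suppressWarnings(as.numeric(df$ambulance_min))
  bad <- which((nzchar(df$model_min) & (is.na(model) | model < 0)) |
                 (nzchar(df$ambulance_min) & (is.na(amb) | amb < 0)))
  if (length(bad) > 0) {
    stop("negative or malformed time(s) in trip log row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dep <- tryCatch(parse_clock(df$depart_time), error = function(e) {
    stop("trip log depart_time: ", conditionMessage(e), call. = FALSE)
  })
  log <- data.frame(origin = df$origin, destination = df$destination,
                    depart_time = ifelse(nzchar(df$depart_time), df$depart_time,
                                         NA_character_),
                    depart_min = dep,
                    model_min = model, ambulance_min = amb,
                    stringsAsFactors = FALSE)
  class(log) <- c("trip_log", "data.frame")
  log
}

#' The validation time windows used for ambulance comparison
#'
#' Trips are compared only when they depart in low-congestion windows —
#' overnight (7 pm to 7 am) and early afternoon (12 to 3 pm) — so that the
#' free-flow model is matched against trips driven in near-free-flow
#' traffic. Windows are closed at the start and open at the end.
#'
#' @return a list of `c(start, end)` clock-time pairs.
#' @export
validation_windows <- function() {
  list(c("19:00", "07:00"), c("12:00", "15:00"))
}

#' Filter trips by departure time windows
#'
#' Keeps records whose departure time falls inside any of the given clock
#' windows; windows wrapping past midnight (start later than end) are
#' supported. Each window is closed at its start and open at its end, so a
#' 19:00 departure is inside `c("19:00", "07:00")` but a 07:00 departure is
#' not. Records lacking a departure time are kept only when `windows` is
#' empty (in which case the filter is the identity).
#'
#' @param records a `trip_log`.
#' @param windows list of `c(start, end)` `HH:MM` pairs;
#'   default [validation_windows()].
#' @return the filtered `trip_log`.
#' @export
filter_by_time_windows <- function(records, windows = validation_windows()) {
  stopifnot(inherits(records, "trip_log"))
  if (length(windows) == 0) return(records)
  dep <- records$depart_min
  keep <- rep(FALSE, nrow(records))
  for (w in windows) {
    a <- parse_clock(w[1])
    b <- parse_clock(w[2])
    if (is.na(a) || is.na(b)) stop("malformed window", call. = FALSE)
    inw <- if (a <= b) dep >= a & dep < b else dep >= a | dep < b
    keep <- keep | (!is.na(dep) & inw)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trip_log", "data.frame")
  out
}

#' Summarize model-vs-ambulance deviations
#'
#' Per-trip deviation is defined as model minus ambulance minutes (positive
#' means the model overestimates). The summary reports the deviation mean
#' and median, the range of logged ambulance times, and for every group of
#' trips sharing an exact origin-destination label pair: trip count,
#' whether the model time is a single constant within the group (it should
#' be — the model is deterministic for a fixed OD), and the ambulance
#' min/max/spread, which quantifies real-trip variability the free-flow
#' model cannot express.
#'
#' @param records a non-empty `trip_log` with both times present.
#' @return a `validation_summary`: `n_trips`, `deviations`, `mean_dev`,
#'   `median_dev`, `min_ambulance`, `max_ambulance`, `per_od_groups`.
#' @export
summarize_deviation <- function(records) {
  stopifnot(inherits(records, "trip_log"))
  if (nrow(records) == 0) stop("empty trip log", call. = FALSE)
  if (anyNA(records$model_min) || anyNA(records$ambulance_min)) {
    stop("trip log has missing model or ambulance times", call. = FALSE)
  }
  dev <- records$model_min - records$ambulance_min
  key <- paste(records$origin, records$destination, sep = " -> ")
  groups <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    data.frame(
      od = key[idx[1]],
      origin = records$origin[idx[1]], destination = records$destination[idx[1]],
      n = length(idx),
      model_constant = length(unique(records$model_min[idx])) == 1L,
      model_min = records$model_min[idx[1]],
      amb_min = min(records$ambulance_min[idx]),
      amb_max = max(records$ambulance_min[idx]),
      amb_spread = max(records$ambulance_min[idx]) - min(records$ambulance_min[idx]),
      stringsAsFactors = FALSE
    )
  })
  per_od <- do.call(rbind, groups)
  per_od <- per_od[order(per_od$od), , drop = FALSE]
  rownames(per_od) <- NULL
  out <- list(n_trips = nrow(records), deviations = dev,
              mean_dev = mean(dev), median_dev = stats::median(dev),
              min_ambulance = min(records$ambulance_min),
              max_ambulance = max(records$ambulance_min),
              per_od_groups = per_od)
  class(out) <- "validation_summary"
  out
}

#' Recompute model times for logged trips from the driving-time table
#'
#' Maps each trip's origin label to a network point (snapped to its nearest
#' part) and each destination label to a hospital, replacing `model_min`
#' with the rounded table lookup while preserving the original in
#' `model_min_orig`. Model minutes are rounded half up, the convention
#' under which they are comparable with minute-logged ambulance times.
#'
#' @param records a `trip_log`.
#' @param table a `driving_time_table`.
#' @param dlayer the `discretized_layer` the table was built on.
#' @param origin_points named list (or data frame with `label,x,y`) mapping
#'   each origin label to a point.
#' @param dest_hospitals named character vector mapping each destination
#'   label to a `hospital_id` in the table.
#' @return the `trip_log` with `model_min` recomputed and `model_min_orig`
#'   added. Unmapped labels are an error listing every missing label.
#' @export
compare_to_model <- function(records, table, dlayer, origin_points,
                             dest_hospitals) {
  stopifnot(inherits(records, "trip_log"),
            inherits(table, "driving_time_table"))
  if (is.data.frame(origin_points)) {
    origin_points <- stats::setNames(
      lapply(seq_len(nrow(origin_points)),
             function(i) c(origin_points$x[i], origin_points$y[i])),
      origin_points$label)
  }
  missing_o <- setdiff(unique(records$origin), names(origin_points))
  missing_d <- setdiff(unique(records$destination), names(dest_hospitals))
  if (length(missing_o) + length(missing_d) > 0) {
    stop("unmapped trip label(s): ",
         paste(c(missing_o, missing_d), collapse = ", "), call. = FALSE)
  }
  origin_dseg <- vapply(origin_points,
                        function(p) snap_point_full(p, dlayer)$dseg_id, "")
  records$model_min_orig <- records$model_min
  for (i in seq_len(nrow(records))) {
    records$model_min[i] <- lookup_time(table,
                                        origin_dseg[[records$origin[i]]],
                                        dest_hospitals[[records$destination[i]]],
                                        rounding = TRUE)
  }
  records
}

#' Write paired model/ambulance times for external plotting
#'
#' Emits a scatter-ready CSV (`model_min,ambulance_min,origin,destination`)
#' of the paired times, the data behind a model-vs-observed deviation
#' scatter plot.
#'
#' @param records a `trip_log`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_paired_times <- function(records, path) {
  stopifnot(inherits(records, "trip_log"))
  utils::write.csv(records[, c("model_min", "ambulance_min", "origin",
                               "destination")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Validation: %d trips\n", x$n_trips))
  cat(sprintf("  deviation (model - ambulance): mean %.2f min, median %.1f min\n",
              x$mean_dev, x$median_dev))
  cat(sprintf("  ambulance times: %g-%g min\n", x$min_ambulance, x$max_ambulance))
  cat(sprintf("  %d identical-OD group(s)\n", nrow(x$per_od_groups)))
  invisible(x)
}

#' Export a validation summary as JSON
#'
#' @param summary a `validation_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_summary <- function(summary, path) {
  stopifnot(inherits(summary, "validation_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
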