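# Decision-support core: rank evacuation destinations for an MCI location
# and allocate patients under capacity constraints.

#' Query hospitals for an MCI location
#'
#' Snaps the incident location to its nearest discretized part, looks up
#' the precomputed driving time to every included hospital, and returns the
#' ranked results table the decision maker sees: one row per hospital with
#' its trauma level, current capacity and driving time in whole minutes,
#' sorted by driving time (unreachable hospitals last). Non-trauma
#' hospitals (level 9) are included: they are the fallback when the trauma
#' centres are overloaded.
#'
#' @param location numeric (x, y) in the network CRS; an off-network point
#'   still snaps to the nearest part.
#' @param reference free-text incident reference location (e.g. a station
#'   name), carried into reports.
#' @param registry a snapped `hospital_registry`.
#' @param table a `driving_time_table` built for `dlayer` and `registry`.
#' @param dlayer the `discretized_layer` the table was built on.
#' @return an `mci_query_result`: `$incident` (x, y, dseg_id, reference)
#'   and `$rows` (hospital_id, name, trauma_level, capacity,
#'   driving_time_min, reachable).
#' @export
query_mci <- function(location, reference = "", registry, table, dlayer) {
  stopifnot(inherits(registry, "hospital_registry"),
            inherits(table, "driving_time_table"))
  inc <- registry[registry$included, , drop = FALSE]
  if (nrow(inc) == 0) stop("no included hospitals", call. = FALSE)
  s <- snap_point_full(location, dlayer)
  sub <- table$entries[table$entries$dseg_id == s$dseg_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("snapped part ", s$dseg_id, " not in table", call. = FALSE)
  i <- match(inc$hospital_id, sub$hospital_id)
  if (anyNA(i)) {
    stop("hospital(s) missing from table: ",
         paste(inc$hospital_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  rows <- data.frame(
    hospital_id = inc$hospital_id, name = inc$name,
    trauma_level = inc$trauma_level, capacity = inc$capacity,
    driving_time_min = ifelse(sub$reachable[i],
                              as.numeric(seconds_to_minutes(sub$seconds[i])),
                              NA_real_),
    reachable = sub$reachable[i],
    stringsAsFactors = FALSE
  )
  ord <- order(!rows$reachable, rows$driving_time_min, rows$hospital_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  res <- list(incident = list(x = location[1], y = location[2],
                              dseg_id = s$dseg_id, reference = reference),
              rows = rows)
  class(res) <- "mci_query_result"
  res
}

#' Allocate patients to hospitals
#'
#' Greedy sequential policy within trauma-priority tiers: each patient in
#' turn goes to the reachable hospital with the shortest driving time that
#' still has residual capacity, searching tiers in priority order —
#' major trauma centres (levels 1-2), then secondary trauma centres
#' (levels 3-4), then non-trauma hospitals (level 9). So a nearby level-1
#' centre fills first, overflow spills to the next-nearest centre in the
#' same tier, and non-trauma hospitals receive patients only when every
#' trauma centre is full. Patients beyond total system capacity are
#' reported as unassigned, never silently dropped. Ties are broken by
#' hospital id, making plans deterministic.
#'
#' @param result an `mci_query_result`.
#' @param n_critical number of critically injured patients to evacuate.
#' @param registry the `hospital_registry` holding current capacities
#'   (defaults to the capacities captured in `result`).
#' @param tiers list of trauma-level groups in priority order; the default
#'   is `list(c(1, 2), c(3, 4), 9)`.
#' @return an `allocation_plan`: `$assignments` (patient_index,
#'   hospital_id, driving_time_min), `$residual_capacities` (named
#'   integer), `$unassigned` (count).
#' @export
allocate_patients <- function(result, n_critical, registry = NULL,
                              tiers = list(c(1, 2), c(3, 4), 9)) {
  stopifnot(inherits(result, "mci_query_result"),
            n_critical >= 0, n_critical == floor(n_critical))
  rows <- result$rows
  if (!is.null(registry)) {
    stopifnot(inherits(registry, "hospital_registry"))
    j <- match(rows$hospital_id, registry$hospital_id)
    if (anyNA(j)) stop("query result hospital(s) missing from registry", call. = FALSE)
    rows$capacity <- registry$capacity[j]
  }
  cand <- rows[rows$reachable, , drop = FALSE]
  cand$tier <- rep(NA_integer_, nrow(cand))
  for (t in seq_along(tiers)) {
    cand$tier[cand$trauma_level %in% tiers[[t]]] <- t
  }
  cand <- cand[!is.na(cand$tier), , drop = FALSE]
  cand <- cand[order(cand$tier, cand$driving_time_min, cand$hospital_id), , drop = FALSE]
  residual <- as.integer(cand$capacity)
  assigned_to <- integer(0)
  n_critical <- as.integer(n_critical)
  for (pat in seq_len(n_critical)) {
    i <- which(residual > 0)
    if (length(i) == 0) break
    i <- i[1]  # cand is sorted tier-first, time-second, id-third
    assigned_to <- c(assigned_to, i)
    residual[i] <- residual[i] - 1L
  }
  assignments <- data.frame(
    patient_index = seq_along(assigned_to),
    hospital_id = cand$hospital_id[assigned_to],
    driving_time_min = cand$driving_time_min[assigned_to],
    stringsAsFactors = FALSE
  )
  res_cap <- stats::setNames(as.integer(rows$capacity), rows$hospital_id)
  res_cap[cand$hospital_id] <- residual
  plan <- list(assignments = assignments,
               residual_capacities = res_cap,
               unassigned = n_critical - length(assigned_to),
               n_critical = n_critical)
  class(plan) <- "allocation_plan"
  plan
}

#' Serialize a query result or allocation plan
#'
#' Deterministic text output in one of three formats: `"table"` (aligned,
#' human-readable), `"json"` (re-parses to identical values) or `"csv"`
#' (fixed columns: query results `hospital_id,name,trauma_level,capacity,
#' driving_time_min,reachable`; plans `patient_index,hospital_id,
#' driving_time_min`). Driving times are whole minutes throughout.
#'
#' @param x an `mci_query_result` or `allocation_plan`.
#' @param format `"table"`, `"json"` or `"csv"`.
#' @return a character vector of output lines.
#' @export
report <- function(x, format = c("table", "json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "mci_query_result")) {
    df <- x$rows
    header <- sprintf("MCI at (%.1f, %.1f)%s - snapped to %s",
                      x$incident$x, x$incident$y,
                      if (nzchar(x$incident$reference))
                        paste0(" [", x$incident$reference, "]") else "",
                      x$incident$dseg_id)
  } else if (inherits(x, "allocation_plan")) {
    df <- x$assignments
    header <- sprintf("Allocation of %d critical patient(s); unassigned: %d",
                      x$n_critical, x$unassigned)
  } else {
    stop("report() expects an mci_query_result or allocation_plan", call. = FALSE)
  }
  switch(format,
    json = {
      obj <- if (inherits(x, "mci_query_result")) {
        list(kind = "mci_query_result", incident = x$incident, rows = df)
      } else {
        list(kind = "allocation_plan", n_critical = x$n_critical,
             unassigned = x$unassigned, assignments = df,
             residual_capacities = as.list(x$residual_capacities))
      }
      strsplit(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, dataframe = "rows",
                                             na = "null", pretty = TRUE)),
               "\n")[[1]]
    },
    csv = {
      con <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
      close(con)
      csv_out
    },
    table = {
      widths <- pmax(nchar(names(df)),
                     if (nrow(df)) apply(df, 2, function(cl) max(nchar(trimws(format(cl, na.encode = TRUE))))) else 0)
      fmt_row <- function(vals) {
        paste(mapply(function(v, w) formatC(trimws(format(v)), width = w),
                     vals, widths), collapse = "  ")
      }
      lines <- c(header, fmt_row(names(df)))
      for (i in seq_len(nrow(df))) lines <- c(lines, fmt_row(df[i, ]))
      lines
    }
  )
}

#' Read a saved query result back from JSON
#'
#' Inverse of `report(x, "json")` for query results, so an allocation can
#' be run later on a saved result.
#'
#' @param path JSON file written from `report(result, "json")`.
#' @return an `mci_query_result`.
#' @export
read_query_result <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "mci_query_result")) {
    stop("not a saved query result: ", path, call. = FALSE)
  }
  rows <- as.data.frame(obj$rows, stringsAsFactors = FALSE)
  rows$driving_time_min <- as.numeric(rows$driving_time_min)
  res <- list(incident = obj$incident, rows = rows)
  class(res) <- "mci_query_result"
  res
}

#' @export
print.mci_query_result <- function(x, ...) {
  writeLines(report(x, "table"))
  invisible(x)
}

#' @export
print.allocation_plan <- function(x, ...) {
  writeLines(report(x, "table"))
  invisible(x)
}
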