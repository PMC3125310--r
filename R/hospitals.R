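# Hospital registry: location at the emergency-room entrance, Canadian
# trauma-centre designation (levels 1-4; 9 marks a non-trauma hospital),
# and capacity = number of critically injured patients the hospital can
# accept in the current incident. Capacity and inclusion are session-
# editable so the registry can be updated as patients are evacuated.

TRAUMA_LEVELS <- c(1L, 2L, 3L, 4L, 9L)

#' Load the hospital registry from CSV
#'
#' Expects columns `id,name,x,y,trauma_level,capacity` and optionally
#' `services` (free-text treatment specializations such as
#' `"ICU;neurosurgery"`; displayed, never used by the ranking). Coordinates
#' are in the same projected planar CRS as the road network, geocoded as
#' close to the main emergency-room access as possible. Trauma level must
#' be one of 1-4 (trauma centres) or 9 (non-trauma); capacity must be a
#' nonnegative integer.
#'
#' @param path CSV file path.
#' @return a `hospital_registry` data frame with columns `hospital_id`,
#'   `name`, `x`, `y`, `trauma_level`, `capacity`, `services`, `included`
#'   (all `TRUE` on load), `snapped_dseg`, `snap_arc_m` (NA until
#'   [snap_hospitals()]).
#' @export
load_hospitals <- function(path) {
  if (!file.exists(path)) stop("hospital file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  need <- c("id", "name", "x", "y", "trauma_level", "capacity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("hospital CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("hospital CSV has no rows", call. = FALSE)
  lev <- suppressWarnings(as.integer(df$trauma_level))
  bad <- which(is.na(lev) | !lev %in% TRAUMA_LEVELS)
  if (length(bad) > 0) {
    stop("invalid trauma_level (allowed: 1,2,3,4,9) in row(s) ",
         paste(bad, collapse = ", "), " (id ",
         paste(df$id[bad], collapse = ", "), ")", call. = FALSE)
  }
  cap <- suppressWarnings(as.numeric(df$capacity))
  bad <- which(is.na(cap) | cap < 0 | cap != floor(cap))
  if (length(bad) > 0) {
    stop("capacity must be a nonnegative integer; bad row(s) ",
         paste(bad, collapse = ", "), " (id ",
         paste(df$id[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate hospital id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  reg <- data.frame(
    hospital_id = df$id, name = df$name,
    x = as.numeric(df$x), y = as.numeric(df$y),
    trauma_level = lev, capacity = as.integer(cap),
    services = if ("services" %in% names(df)) df$services else NA_character_,
    included = TRUE, snapped_dseg = NA_character_, snap_arc_m = NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(reg$x)) || any(!is.finite(reg$y))) {
    stop("non-numeric hospital coordinates", call. = FALSE)
  }
  class(reg) <- c("hospital_registry", "data.frame")
  reg
}

#' Write a hospital registry to CSV
#'
#' Inverse of [load_hospitals()]; derived columns (`included`,
#' `snapped_dseg`, `snap_arc_m`) are not written. A header comment records
#' that capacity means the number of critically injured patients the
#' hospital can accept in the current incident.
#'
#' @param registry a `hospital_registry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hospitals <- function(registry, path) {
  stopifnot(inherits(registry, "hospital_registry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# capacity = critically injured patients the hospital can accept in the current MCI",
    "# trauma_level: 1-4 Canadian trauma-centre designation; 9 = non-trauma hospital"
  ), con)
  out <- registry[, c("hospital_id", "name", "x", "y", "trauma_level",
                      "capacity", "services")]
  names(out)[1] <- "id"
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Snap hospitals onto the discretized network
#'
#' Assigns every hospital the nearest discretized part by perpendicular
#' Euclidean distance (same rule and tie-break as [snap_point_to_dseg()]),
#' recording both the part id and the arc-length position of the projected
#' ER-entrance point along it. The residual from that point to the part's
#' endpoints is what a trip traverses last, with no impedance charged at
#' the destination itself.
#'
#' @param registry a `hospital_registry`.
#' @param dlayer a `discretized_layer`.
#' @return the registry with `snapped_dseg` and `snap_arc_m` filled in.
#' @export
snap_hospitals <- function(registry, dlayer) {
  stopifnot(inherits(registry, "hospital_registry"))
  for (i in seq_len(nrow(registry))) {
    s <- snap_point_full(c(registry$x[i], registry$y[i]), dlayer)
    registry$snapped_dseg[i] <- s$dseg_id
    registry$snap_arc_m[i] <- s$arc_m
  }
  registry
}

find_hospital <- function(registry, hospital_id) {
  i <- match(hospital_id, registry$hospital_id)
  if (is.na(i)) stop("unknown hospital_id: ", hospital_id, call. = FALSE)
  i
}

#' Update a hospital's capacity
#'
#' Capacity can be edited before a query (to reflect the hospital's actual
#' surge capacity) and is decremented by [allocate_patients()] as patients
#' are assigned. It can never go below zero.
#'
#' @param registry a `hospital_registry`.
#' @param hospital_id hospital id.
#' @param new_capacity nonnegative integer.
#' @return the updated registry.
#' @export
set_capacity <- function(registry, hospital_id, new_capacity) {
  i <- find_hospital(registry, hospital_id)
  if (!is.finite(new_capacity) || new_capacity < 0 ||
      new_capacity != floor(new_capacity)) {
    stop("capacity must be a nonnegative integer", call. = FALSE)
  }
  registry$capacity[i] <- as.integer(new_capacity)
  registry
}

#' Include or exclude a hospital from the analysis
#'
#' Excluded hospitals never appear in query results or allocations;
#' excluding one does not change the driving times reported for others.
#'
#' @param registry a `hospital_registry`.
#' @param hospital_id hospital id.
#' @param flag logical.
#' @return the updated registry.
#' @export
set_included <- function(registry, hospital_id, flag) {
  i <- find_hospital(registry, hospital_id)
  registry$included[i] <- isTRUE(flag)
  registry
}
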