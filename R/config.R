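#' Travel-time model configuration
#'
#' Bundles the tunable parameters of the driving-time model:
#'
#' * `max_segment_length_m` — discretization cap: no road segment used as a
#'   travel-time origin may be longer than this (default 200 m). Segments at
#'   or below the cap are kept unchanged; longer ones are subdivided into
#'   equal parts.
#' * `stop_sign_delay_s` / `traffic_light_delay_s` — fixed impedance charged
#'   when a route enters a controlled intersection (defaults 5 s and 10 s,
#'   values elicited from experienced paramedics for urban driving). The
#'   delay is never charged at the trip's final destination.
#' * `vehicle_speed_factor` — dimensionless multiplier on the posted speed
#'   limit, so ambulance driving (lights and sirens) can be modelled as
#'   faster than a regular vehicle; default 1.0 (drive at the limit).
#' * `excluded_road_classes` — road classes dropped from the network before
#'   any computation (default back roads and logging roads, which carry no
#'   ambulance traffic and inflate the database).
#'
#' @param max_segment_length_m positive length in metres.
#' @param stop_sign_delay_s nonnegative seconds.
#' @param traffic_light_delay_s nonnegative seconds.
#' @param vehicle_speed_factor positive multiplier on posted speeds.
#' @param excluded_road_classes character vector of road-class labels.
#' @return an object of class `mci_config`.
#' @export
#' @examples
#' cfg <- mci_config()
#' cfg$max_segment_length_m
mci_config <- function(max_segment_length_m = 200,
                       stop_sign_delay_s = 5,
                       traffic_light_delay_s = 10,
                       vehicle_speed_factor = 1.0,
                       excluded_road_classes = c("back_road", "logging_road")) {
  cfg <- list(
    max_segment_length_m = as.numeric(max_segment_length_m),
    stop_sign_delay_s = as.numeric(stop_sign_delay_s),
    traffic_light_delay_s = as.numeric(traffic_light_delay_s),
    vehicle_speed_factor = as.numeric(vehicle_speed_factor),
    excluded_road_classes = as.character(excluded_road_classes)
  )
  class(cfg) <- "mci_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "mci_config"))
  if (!is.finite(cfg$max_segment_length_m) || cfg$max_segment_length_m <= 0) {
    stop("max_segment_length_m must be > 0", call. = FALSE)
  }
  if (cfg$stop_sign_delay_s < 0 || cfg$traffic_light_delay_s < 0) {
    stop("impedance delays must be >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$vehicle_speed_factor) || cfg$vehicle_speed_factor <= 0) {
    stop("vehicle_speed_factor must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a model configuration from file
#'
#' Accepts either a JSON object or a flat `key=value` file whose keys mirror
#' the [mci_config()] arguments; unspecified keys keep their defaults.
#' `excluded_road_classes` in `key=value` form is comma-separated.
#'
#' @param path file path.
#' @return an `mci_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  vals <- if (grepl("^\\s*\\{", joined)) {
    jsonlite::fromJSON(joined, simplifyVector = TRUE)
  } else {
    lines <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
    v <- lapply(kv, function(p) trimws(p[2]))
    names(v) <- vapply(kv, function(p) trimws(p[1]), "")
    v
  }
  args <- list()
  num_keys <- c("max_segment_length_m", "stop_sign_delay_s",
                "traffic_light_delay_s", "vehicle_speed_factor")
  for (k in num_keys) if (!is.null(vals[[k]])) args[[k]] <- as.numeric(vals[[k]])
  if (!is.null(vals[["excluded_road_classes"]])) {
    ex <- vals[["excluded_road_classes"]]
    if (is.character(ex) && length(ex) == 1L) {
      ex <- trimws(strsplit(ex, ",", fixed = TRUE)[[1]])
    }
    args[["excluded_road_classes"]] <- ex[nzchar(ex)]
  }
  do.call(mci_config, args)
}

#' @export
print.mci_config <- function(x, ...) {
  cat("MCI travel-time model configuration\n")
  cat(sprintf("  max segment length : %g m\n", x$max_segment_length_m))
  cat(sprintf("  stop sign delay    : %g s\n", x$stop_sign_delay_s))
  cat(sprintf("  traffic light delay: %g s\n", x$traffic_light_delay_s))
  cat(sprintf("  vehicle speed factor: %g\n", x$vehicle_speed_factor))
  cat(sprintf("  excluded road classes: %s\n",
              paste(x$excluded_road_classes, collapse = ", ")))
  invisible(x)
}
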