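# Road network ingestion and per-segment travel times.
#
# A road network is a planar graph: intersections (nodes, each carrying an
# intersection control: none / stop_sign / traffic_light) joined by road
# segments (polylines with a posted speed limit, a road class and an
# optional one-way flag). Coordinates are projected planar metres;
# geographic input must be projected before loading.

CONTROL_LEVELS <- c("none", "stop_sign", "traffic_light")

# GeoJSON dialect uses short control labels.
control_from_geojson <- c(none = "none", stop = "stop_sign", light = "traffic_light")
control_to_geojson <- c(none = "none", stop_sign = "stop", traffic_light = "light")

new_road_network <- function(nodes, segments, geometry, crs_note = "projected planar metres") {
  net <- list(nodes = nodes, segments = segments, geometry = geometry,
              crs_note = crs_note)
  class(net) <- "road_network"
  net
}

validate_network <- function(net) {
  stopifnot(inherits(net, "road_network"))
  seg <- net$segments
  if (anyDuplicated(seg$segment_id)) {
    stop("duplicate segment ids: ",
         paste(unique(seg$segment_id[duplicated(seg$segment_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(net$nodes$node_id)) {
    stop("duplicate node ids", call. = FALSE)
  }
  missing_nodes <- setdiff(c(seg$from_node, seg$to_node), net$nodes$node_id)
  if (length(missing_nodes) > 0) {
    stop("dangling node reference(s): ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  }
  if (any(!net$nodes$control %in% CONTROL_LEVELS)) {
    stop("invalid intersection control value(s)", call. = FALSE)
  }
  bad_speed <- seg$segment_id[!is.finite(seg$speed_kmh) | seg$speed_kmh <= 0]
  if (length(bad_speed) > 0) {
    stop("nonpositive or missing speed limit on segment(s): ",
         paste(bad_speed, collapse = ", "), call. = FALSE)
  }
  # declared length must match the polyline arc length
  for (i in seq_len(nrow(seg))) {
    L <- polyline_length(net$geometry[[seg$segment_id[i]]])
    if (L <= 0) stop("zero-length segment: ", seg$segment_id[i], call. = FALSE)
    if (abs(L - seg$length_m[i]) > 1e-6 * max(L, 1)) {
      stop("length_m does not match polyline arc length for segment ",
           seg$segment_id[i], call. = FALSE)
    }
  }
  invisible(net)
}

#' Load a road network from GeoJSON
#'
#' Reads a FeatureCollection in the package's road dialect: `LineString`
#' features are road segments and must carry properties `segment_id`,
#' `speed_kmh`, `road_class` and optionally `one_way` (default `FALSE`);
#' `Point` features declare intersection controls and carry `node_id` and
#' `control` (one of `none`, `stop`, `light`). Point features must coincide
#' (within 1e-6 m) with a segment endpoint. Endpoints without a Point
#' feature become uncontrolled intersections with generated ids.
#'
#' @param path GeoJSON file path.
#' @param config an [mci_config()]; retained for interface symmetry
#'   (validation does not depend on it).
#' @return a `road_network` object: `$nodes` (node_id, x, y, control),
#'   `$segments` (segment_id, from_node, to_node, length_m, speed_kmh,
#'   road_class, one_way), `$geometry` (named list of coordinate matrices),
#'   `$crs_note`.
#' @export
load_network <- function(path, config = mci_config()) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  lines <- Filter(function(f) identical(f$geometry$type, "LineString"), gj$features)
  points <- Filter(function(f) identical(f$geometry$type, "Point"), gj$features)
  if (length(lines) == 0) stop("no LineString features in ", path, call. = FALSE)

  geometry <- list()
  seg_rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- lines[[i]]
    pr <- f$properties
    sid <- as.character(pr$segment_id %||% sprintf("feature %d", i))
    if (is.null(pr$speed_kmh)) {
      stop("missing speed limit (speed_kmh) on feature ", sid, call. = FALSE)
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(c2) as.numeric(unlist(c2))))
    if (nrow(coords) < 2L) stop("degenerate LineString on feature ", sid, call. = FALSE)
    geometry[[sid]] <- coords
    seg_rows[[i]] <- data.frame(
      segment_id = sid,
      speed_kmh = as.numeric(pr$speed_kmh),
      road_class = as.character(pr$road_class %||% "unknown"),
      one_way = isTRUE(pr$one_way),
      stringsAsFactors = FALSE
    )
  }
  segments <- do.call(rbind, seg_rows)

  # resolve endpoints to nodes by coordinate identity (1e-6 m grid)
  key_of <- function(x, y) sprintf("%.6f|%.6f", x, y)
  ends <- lapply(segments$segment_id, function(sid) {
    g <- geometry[[sid]]
    list(from = g[1, ], to = g[nrow(g), ])
  })
  all_pts <- do.call(rbind, lapply(ends, function(e) rbind(e$from, e$to)))
  keys <- key_of(all_pts[, 1], all_pts[, 2])
  uk <- unique(keys)
  node_xy <- all_pts[match(uk, keys), , drop = FALSE]
  node_id <- sprintf("N%04d", seq_along(uk))
  control <- rep("none", length(uk))

  if (length(points) > 0) {
    for (f in points) {
      pr <- f$properties
      xy <- as.numeric(unlist(f$geometry$coordinates))
      k <- key_of(xy[1], xy[2])
      j <- match(k, uk)
      if (is.na(j)) {
        stop("dangling node reference: control point ",
             as.character(pr$node_id %||% "?"),
             " does not coincide with any segment endpoint", call. = FALSE)
      }
      if (!is.null(pr$node_id)) node_id[j] <- as.character(pr$node_id)
      ctl <- as.character(pr$control %||% "none")
      if (!ctl %in% names(control_from_geojson)) {
        stop("unknown control '", ctl, "' on node ", node_id[j], call. = FALSE)
      }
      control[j] <- unname(control_from_geojson[ctl])
    }
  }

  nodes <- data.frame(node_id = node_id, x = node_xy[, 1], y = node_xy[, 2],
                      control = control, stringsAsFactors = FALSE)
  segments$from_node <- node_id[match(keys[seq(1, length(keys), by = 2)], uk)]
  segments$to_node <- node_id[match(keys[seq(2, length(keys), by = 2)], uk)]
  segments$length_m <- vapply(segments$segment_id,
                              function(s) polyline_length(geometry[[s]]), 0)
  segments <- segments[, c("segment_id", "from_node", "to_node", "length_m",
                           "speed_kmh", "road_class", "one_way")]
  rownames(segments) <- NULL

  net <- new_road_network(nodes, segments, geometry,
                          crs_note = as.character(gj$crs_note %||% "projected planar metres"))
  validate_network(net)
  net
}

#' Write a road network to GeoJSON
#'
#' Inverse of [load_network()]: emits one `LineString` feature per segment
#' and one `Point` feature per intersection (so controls round-trip).
#'
#' @param network a `road_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "road_network"))
  feats <- vector("list", nrow(network$segments) + nrow(network$nodes))
  k <- 0L
  for (i in seq_len(nrow(network$segments))) {
    s <- network$segments[i, ]
    g <- network$geometry[[s$segment_id]]
    k <- k + 1L
    feats[[k]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(g)),
                                           function(j) c(g[j, 1], g[j, 2]))),
      properties = list(segment_id = s$segment_id, speed_kmh = s$speed_kmh,
                        road_class = s$road_class, one_way = s$one_way)
    )
  }
  for (i in seq_len(nrow(network$nodes))) {
    n <- network$nodes[i, ]
    k <- k + 1L
    feats[[k]] <- list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(n$x, n$y)),
      properties = list(node_id = n$node_id,
                        control = unname(control_to_geojson[n$control]))
    )
  }
  fc <- list(type = "FeatureCollection", crs_note = network$crs_note,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Drop excluded road classes
#'
#' Removes every segment whose `road_class` is in
#' `config$excluded_road_classes` (by default back roads and logging roads,
#' which carry no ambulance traffic), together with intersections left
#' without any incident segment. Idempotent; an empty result is permitted.
#'
#' @param network a `road_network`.
#' @param config an [mci_config()].
#' @return the filtered `road_network`.
#' @export
filter_roads <- function(network, config = mci_config()) {
  stopifnot(inherits(network, "road_network"))
  keep <- !(network$segments$road_class %in% config$excluded_road_classes)
  seg <- network$segments[keep, , drop = FALSE]
  rownames(seg) <- NULL
  used <- unique(c(seg$from_node, seg$to_node))
  nodes <- network$nodes[network$nodes$node_id %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  new_road_network(nodes, seg, network$geometry[seg$segment_id],
                   crs_note = network$crs_note)
}

#' Traversal time of one road segment
#'
#' Kinematic time (length over effective speed) plus the impedance of the
#' intersection being entered at the downstream end of the traversal:
#' nothing for an uncontrolled node, `stop_sign_delay_s` for a stop sign,
#' `traffic_light_delay_s` for a traffic light. Effective speed is the
#' posted limit times `vehicle_speed_factor`. The caller passes `"none"`
#' as `downstream_control` when the traversal ends at the trip's final
#' destination, where no impedance is charged.
#'
#' @param segment a list or one-row data frame with `length_m` and
#'   `speed_kmh` (alias `speed_limit_kmh` accepted).
#' @param downstream_control `"none"`, `"stop_sign"` or `"traffic_light"`.
#' @param config an [mci_config()].
#' @return traversal time in seconds.
#' @export
#' @examples
#' seg <- list(length_m = 200, speed_kmh = 36)
#' segment_travel_time(seg, "none")          # 20 s
#' segment_travel_time(seg, "traffic_light") # 30 s
segment_travel_time <- function(segment, downstream_control = "none",
                                config = mci_config()) {
  speed <- segment$speed_kmh %||% segment$speed_limit_kmh
  if (is.null(speed) || !is.finite(speed) || speed <= 0) {
    stop("segment speed limit must be > 0", call. = FALSE)
  }
  if (!downstream_control %in% CONTROL_LEVELS) {
    stop("unknown downstream_control: ", downstream_control, call. = FALSE)
  }
  v_ms <- speed / 3.6 * config$vehicle_speed_factor
  delay <- switch(downstream_control,
                  none = 0,
                  stop_sign = config$stop_sign_delay_s,
                  traffic_light = config$traffic_light_delay_s)
  segment$length_m / v_ms + delay
}

control_delay <- function(control, config) {
  d <- c(none = 0, stop_sign = config$stop_sign_delay_s,
         traffic_light = config$traffic_light_delay_s)
  unname(d[control])
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("Road network: %d segments, %d intersections (%s)\n",
              nrow(x$segments), nrow(x$nodes), x$crs_note))
  ctl <- table(factor(x$nodes$control, levels = CONTROL_LEVELS))
  cat(sprintf("  controls: %d none, %d stop signs, %d traffic lights\n",
              ctl[["none"]], ctl[["stop_sign"]], ctl[["traffic_light"]]))
  cat(sprintf("  total length: %.1f km\n", sum(x$segments$length_m) / 1000))
  invisible(x)
}
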