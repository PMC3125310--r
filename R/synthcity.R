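# Seeded synthetic grid-city generator. Grid topology is chosen because
# closed-form shortest times exist on a uniform grid, which makes every
# downstream module testable against hand calculations with no external
# road data. Generated files use exactly the GeoJSON/CSV dialects the
# loaders validate.

#' Specify a synthetic grid city
#'
#' Defaults describe a mid-size suburban study area: a 10 x 10 grid of
#' 150 m blocks, urban speed limits of 30/50/60 km/h, stop signs at 30% and
#' traffic lights at 20% of intersections, 15% of street edges replaced by
#' longer winding segments (> 200 m, so discretization is exercised), and
#' six hospitals with a trauma-level mix dominated by non-trauma sites, as
#' in a real inclusive trauma system.
#'
#' @param rows,cols grid dimensions (>= 2).
#' @param spacing_m block edge length in metres.
#' @param speed_set_kmh candidate posted speed limits.
#' @param p_stop,p_light per-intersection control probabilities
#'   (`p_stop + p_light <= 1`).
#' @param long_segment_fraction fraction of edges replaced by single
#'   winding polylines of 1.8-3.2 block lengths.
#' @param n_hospitals number of hospitals (<= number of intersections).
#' @param trauma_level_mix named probability weights over levels
#'   `1,2,3,4,9`.
#' @param seed integer; every random draw in the generator flows from it.
#' @return a `city_spec` list.
#' @export
city_spec <- function(rows = 10, cols = 10, spacing_m = 150,
                      speed_set_kmh = c(30, 50, 60),
                      p_stop = 0.3, p_light = 0.2,
                      long_segment_fraction = 0.15,
                      n_hospitals = 6,
                      trauma_level_mix = c(`1` = 0.15, `2` = 0.15, `3` = 0.2,
                                           `4` = 0.2, `9` = 0.3),
                      seed = 1L) {
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               spacing_m = as.numeric(spacing_m),
               speed_set_kmh = as.numeric(speed_set_kmh),
               p_stop = as.numeric(p_stop), p_light = as.numeric(p_light),
               long_segment_fraction = as.numeric(long_segment_fraction),
               n_hospitals = as.integer(n_hospitals),
               trauma_level_mix = trauma_level_mix,
               seed = as.integer(seed))
  if (spec$rows < 2 || spec$cols < 2) stop("grid dimensions must be >= 2", call. = FALSE)
  if (spec$p_stop < 0 || spec$p_light < 0 || spec$p_stop + spec$p_light > 1) {
    stop("control probabilities must be in [0,1] with p_stop + p_light <= 1",
         call. = FALSE)
  }
  if (spec$long_segment_fraction < 0 || spec$long_segment_fraction > 1) {
    stop("long_segment_fraction must be in [0,1]", call. = FALSE)
  }
  if (spec$n_hospitals > spec$rows * spec$cols) {
    stop("n_hospitals exceeds number of intersections", call. = FALSE)
  }
  if (!all(names(spec$trauma_level_mix) %in% as.character(TRAUMA_LEVELS))) {
    stop("trauma_level_mix names must be in {1,2,3,4,9}", call. = FALSE)
  }
  class(spec) <- "city_spec"
  spec
}

grid_node_id <- function(r, c) sprintf("N%03d_%03d", r, c)

# Capacity conventions by trauma level: tertiary centres absorb the most
# critical patients in a surge; non-trauma sites the fewest.
sample_capacity <- function(level) {
  switch(as.character(level),
         `1` = sample(10:15, 1), `2` = sample(8:12, 1),
         `3` = sample(4:8, 1), `4` = sample(4:8, 1),
         sample(3:6, 1))
}

#' Generate a synthetic grid city
#'
#' Writes a road-network GeoJSON and a hospital CSV that pass
#' [load_network()] / [load_hospitals()] validation. The grid is fully
#' connected and bidirectional. A sampled fraction of edges is replaced by
#' a dog-leg polyline of the requested longer arc length (same endpoints,
#' so topology is unchanged). Hospitals are placed at distinct random
#' intersections and then offset onto an adjacent street edge, 8 m off the
#' centreline, mimicking geocoding at the ER entrance rather than the
#' hospital centroid. Byte-identical outputs for the same spec and seed.
#'
#' @param spec a [city_spec()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the two outputs.
#' @return list with `network_path` and `hospitals_path`.
#' @export
generate_city <- function(spec = city_spec(), dir = tempdir(),
                          basename = "city") {
  stopifnot(inherits(spec, "city_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    nodes <- expand.grid(r = seq_len(spec$rows), c = seq_len(spec$cols))
    nodes <- nodes[order(nodes$r, nodes$c), ]
    node_id <- grid_node_id(nodes$r, nodes$c)
    x <- (nodes$c - 1) * spec$spacing_m
    y <- (nodes$r - 1) * spec$spacing_m
    u <- stats::runif(nrow(nodes))
    control <- ifelse(u < spec$p_stop, "stop_sign",
                      ifelse(u < spec$p_stop + spec$p_light, "traffic_light",
                             "none"))
    node_df <- data.frame(node_id = node_id, x = x, y = y, control = control,
                          stringsAsFactors = FALSE)

    # horizontal then vertical edges, row-major: deterministic ordering
    edges <- list()
    for (r in seq_len(spec$rows)) for (c in seq_len(spec$cols - 1L)) {
      edges[[length(edges) + 1L]] <- c(grid_node_id(r, c), grid_node_id(r, c + 1L))
    }
    for (r in seq_len(spec$rows - 1L)) for (c in seq_len(spec$cols)) {
      edges[[length(edges) + 1L]] <- c(grid_node_id(r, c), grid_node_id(r + 1L, c))
    }
    n_e <- length(edges)
    speeds <- spec$speed_set_kmh[sample.int(length(spec$speed_set_kmh), n_e,
                                            replace = TRUE)]
    n_long <- round(spec$long_segment_fraction * n_e)
    long_idx <- if (n_long > 0) sample.int(n_e, n_long) else integer(0)
    stretch <- stats::runif(n_e, 1.8, 3.2)  # arc-length multiplier for long edges

    xy <- function(id) {
      i <- match(id, node_df$node_id)
      c(node_df$x[i], node_df$y[i])
    }
    geometry <- list()
    seg_rows <- vector("list", n_e)
    for (i in seq_len(n_e)) {
      a <- xy(edges[[i]][1]); b <- xy(edges[[i]][2])
      sid <- sprintf("E%04d", i)
      if (i %in% long_idx) {
        # dog-leg through an offset midpoint: arc length = stretch * chord
        target <- stretch[i] * spec$spacing_m
        d <- sqrt(sum((b - a)^2))
        h <- sqrt((target / 2)^2 - (d / 2)^2)
        mid <- (a + b) / 2
        perp <- c(-(b - a)[2], (b - a)[1]) / d
        geometry[[sid]] <- rbind(a, mid + h * perp, b)
      } else {
        geometry[[sid]] <- rbind(a, b)
      }
      seg_rows[[i]] <- data.frame(segment_id = sid, from_node = edges[[i]][1],
                                  to_node = edges[[i]][2],
                                  length_m = polyline_length(geometry[[sid]]),
                                  speed_kmh = speeds[i], road_class = "street",
                                  one_way = FALSE, stringsAsFactors = FALSE)
    }
    seg_df <- do.call(rbind, seg_rows)
    net <- new_road_network(node_df, seg_df, geometry,
                            crs_note = "synthetic planar grid, metres")
    validate_network(net)

    # hospitals: random distinct intersections, offset onto an adjacent edge
    h_nodes <- sample(node_df$node_id, spec$n_hospitals)
    mix <- spec$trauma_level_mix / sum(spec$trauma_level_mix)
    levels_h <- as.integer(sample(names(mix), spec$n_hospitals, replace = TRUE,
                                  prob = mix))
    h_rows <- vector("list", spec$n_hospitals)
    for (k in seq_len(spec$n_hospitals)) {
      nid <- h_nodes[k]
      adj <- which(seg_df$from_node == nid | seg_df$to_node == nid)
      e <- adj[sample.int(length(adj), 1)]
      g <- geometry[[seg_df$segment_id[e]]]
      if (seg_df$to_node[e] == nid) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
      L <- seg_df$length_m[e]
      arc <- stats::runif(1, 0.2, 0.45) * L
      pt <- point_at(g, arc)
      p2 <- point_at(g, min(arc + 1, L))
      dirv <- p2 - pt
      dirv <- dirv / sqrt(sum(dirv^2))
      perp <- c(-dirv[2], dirv[1])
      er <- pt + 8 * perp  # ER entrance set back 8 m from the centreline
      h_rows[[k]] <- data.frame(
        hospital_id = sprintf("H%02d", k),
        name = sprintf("General Hospital %02d", k),
        x = er[1], y = er[2], trauma_level = levels_h[k],
        capacity = sample_capacity(levels_h[k]),
        services = if (levels_h[k] %in% 1:2) "ICU;neurosurgery;orthopedics;plastic_surgery"
                   else if (levels_h[k] %in% 3:4) "ICU;orthopedics" else "",
        stringsAsFactors = FALSE)
    }
    reg <- do.call(rbind, h_rows)
    reg$included <- TRUE
    reg$snapped_dseg <- NA_character_
    reg$snap_arc_m <- NA_real_
    class(reg) <- c("hospital_registry", "data.frame")

    network_path <- file.path(dir, paste0(basename, ".geojson"))
    hospitals_path <- file.path(dir, paste0(basename, "_hospitals.csv"))
    write_network(net, network_path)
    write_hospitals(reg, hospitals_path)
    list(network_path = network_path, hospitals_path = hospitals_path)
  })
}

#' Generate a synthetic ambulance trip log
#'
#' Emulates the structure of a logged ambulance dataset: each trip's
#' "ambulance" time is the rounded model time plus integer-rounded Gaussian
#' noise (standard deviation `noise_sd_min` minutes), floored at 1 minute;
#' a small `outlier_fraction` of trips receives noise inflated by
#' `outlier_k` (the occasional trip delayed by traffic or rerouting).
#' Only origin-hospital pairs whose rounded model time is at least
#' `1 + 3 * noise_sd_min` minutes are sampled (minimum 1), emulating
#' logged critical transfers, which run well above the one-minute floor;
#' this keeps the floor from truncating the noise distribution, so
#' deviations are unbiased by construction. If no pair is that long the
#' threshold falls back to 1 minute with a warning. Departure times are
#' uniform over the day so time-window filtering has something to do.
#' Deterministic by seed.
#'
#' @param dlayer a `discretized_layer`.
#' @param table a `driving_time_table` built on `dlayer`.
#' @param hospitals a snapped `hospital_registry`.
#' @param n_trips number of trips.
#' @param noise_sd_min noise standard deviation in minutes.
#' @param outlier_fraction fraction of trips with inflated noise.
#' @param outlier_k noise multiplier for outlier trips.
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return a `trip_log` data frame (also written to `path` if given).
#' @export
generate_trip_log <- function(dlayer, table, hospitals, n_trips = 100,
                              noise_sd_min = 2, outlier_fraction = 0.02,
                              outlier_k = 5, seed = 1L, path = NULL) {
  stopifnot(inherits(table, "driving_time_table"),
            inherits(hospitals, "hospital_registry"))
  e <- table$entries
  minutes <- seconds_to_minutes(e$seconds)
  min_model <- max(1, ceiling(1 + 3 * noise_sd_min))
  ok <- e[e$reachable & minutes >= min_model, , drop = FALSE]
  if (nrow(ok) == 0) {
    warning("no origin-hospital pairs with model time >= ", min_model,
            " min; falling back to >= 1 min (the 1-minute floor may bias ",
            "deviations)", call. = FALSE)
    ok <- e[e$reachable & minutes >= 1, , drop = FALSE]
  }
  if (nrow(ok) == 0) stop("no origin-hospital pairs with model time >= 1 min",
                          call. = FALSE)
  log <- with_seed(seed, {
    pick <- sample.int(nrow(ok), n_trips, replace = TRUE)
    model <- as.numeric(seconds_to_minutes(ok$seconds[pick]))
    noise <- stats::rnorm(n_trips, 0, noise_sd_min)
    out <- stats::runif(n_trips) < outlier_fraction
    noise[out] <- noise[out] * outlier_k
    amb <- pmax(1, model + round_half_up(noise))
    dep <- sprintf("%02d:%02d", sample(0:23, n_trips, replace = TRUE),
                   sample(0:59, n_trips, replace = TRUE))
    data.frame(origin = ok$dseg_id[pick], destination = ok$hospital_id[pick],
               depart_time = dep, depart_min = parse_clock(dep),
               model_min = model, ambulance_min = amb,
               stringsAsFactors = FALSE)
  })
  class(log) <- c("trip_log", "data.frame")
  if (!is.null(path)) {
    utils::write.csv(log[, c("origin", "destination", "depart_time",
                             "model_min", "ambulance_min")],
                     path, row.names = FALSE, quote = TRUE)
  }
  log
}

#' Build the full model for a generated (or real) city
#'
#' Convenience pipeline: load network, drop excluded road classes,
#' discretize, load and snap hospitals, precompute the driving-time table.
#'
#' @param network_path road network GeoJSON.
#' @param hospitals_path hospital CSV.
#' @param config an [mci_config()].
#' @return list with `network`, `dlayer`, `hospitals`, `table`.
#' @export
build_city_model <- function(network_path, hospitals_path,
                             config = mci_config()) {
  net <- load_network(network_path, config)
  net <- filter_roads(net, config)
  dl <- discretize_network(net, config)
  reg <- load_hospitals(hospitals_path)
  reg <- snap_hospitals(reg, dl)
  tbl <- precompute_od(dl, reg, config)
  list(network = net, dlayer = dl, hospitals = reg, table = tbl)
}
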