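# Segment discretization: cap segment lengths so every travel-time origin
# (a segment centroid) is at most half the cap away from any point on its
# segment. Segments at or below the cap are kept unchanged; longer segments
# are subdivided into ceiling(L / cap) equal-arc-length parts.

#' Split one road segment to the length cap
#'
#' A segment of length `L <= max_segment_length_m` yields a single part
#' identical to its parent. A longer segment yields
#' `ceiling(L / max_segment_length_m)` parts of equal arc length whose
#' polylines concatenate to the parent polyline. Part ids are formed
#' deterministically from the parent id and the part index, so tables built
#' on the discretized layer are stable across rebuilds.
#'
#' @param segment a list with `segment_id`, `polyline` (coordinate matrix)
#'   and optionally `length_m`.
#' @param config an [mci_config()].
#' @return list of parts, each a list with `dseg_id`, `parent_segment_id`,
#'   `part_index`, `polyline`, `length_m` and `centroid` (point at half the
#'   part's arc length).
#' @export
split_segment <- function(segment, config = mci_config()) {
  poly <- segment$polyline
  stopifnot(is.matrix(poly), nrow(poly) >= 2)
  L <- polyline_length(poly)
  if (!is.null(segment$length_m) &&
      abs(L - segment$length_m) > 1e-6 * max(L, 1)) {
    stop("length_m does not match polyline arc length for segment ",
         segment$segment_id, call. = FALSE)
  }
  cap <- config$max_segment_length_m
  k <- if (L <= cap) 1L else as.integer(ceiling(L / cap - 1e-12))
  cuts <- L * seq(0, k) / k
  parts <- vector("list", k)
  for (i in seq_len(k)) {
    sub <- if (k == 1L) poly else polyline_cut(poly, cuts[i], cuts[i + 1L])
    plen <- polyline_length(sub)
    parts[[i]] <- list(
      dseg_id = dseg_id_of(segment$segment_id, i),
      parent_segment_id = segment$segment_id,
      part_index = i,
      polyline = sub,
      length_m = plen,
      centroid = point_at(sub, plen / 2)
    )
  }
  parts
}

dseg_id_of <- function(parent, index) sprintf("%s#%03d", parent, index)

#' Centroid of a discretized part
#'
#' The point at half the arc length along the part's polyline (on the line
#' itself, not the chord midpoint of the endpoints). Centroids are the
#' travel-time origins of the precomputed driving-time table.
#'
#' @param dseg a part as returned by [split_segment()], or any list with a
#'   `polyline` matrix.
#' @return numeric length-2 point (x, y).
#' @export
centroid_of <- function(dseg) {
  poly <- dseg$polyline
  point_at(poly, polyline_length(poly) / 2)
}

#' Discretize a whole network
#'
#' Applies [split_segment()] to every segment and assembles the discretized
#' layer used by the origin-destination precomputation: a parts table, the
#' full node set (parent intersections plus uncontrolled internal nodes at
#' split points), part polylines, and the one-to-many parent-segment index,
#' so a part id always resolves back to the road segment a user clicks.
#'
#' @param network a (filtered) `road_network`.
#' @param config an [mci_config()].
#' @return a `discretized_layer`: `$parts` (dseg_id, parent_segment_id,
#'   part_index, from_node, to_node, length_m, speed_kmh, road_class,
#'   one_way, cx, cy), `$nodes`, `$geometry` (named list of part polylines),
#'   `$index` (parent_segment_id -> dseg_id), `$config`.
#' @export
discretize_network <- function(network, config = mci_config()) {
  stopifnot(inherits(network, "road_network"))
  seg <- network$segments
  part_rows <- list()
  geometry <- list()
  extra_nodes <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    parts <- split_segment(list(segment_id = s$segment_id,
                                polyline = network$geometry[[s$segment_id]],
                                length_m = s$length_m),
                           config)
    k <- length(parts)
    # internal nodes at the split points (uncontrolled)
    inner_ids <- if (k > 1L) sprintf("%s@%02d", s$segment_id, seq_len(k - 1L)) else character(0)
    node_chain <- c(s$from_node, inner_ids, s$to_node)
    for (j in seq_len(k)) {
      p <- parts[[j]]
      geometry[[p$dseg_id]] <- p$polyline
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        dseg_id = p$dseg_id, parent_segment_id = s$segment_id,
        part_index = j, from_node = node_chain[j], to_node = node_chain[j + 1L],
        length_m = p$length_m, speed_kmh = s$speed_kmh,
        road_class = s$road_class, one_way = s$one_way,
        cx = p$centroid[1], cy = p$centroid[2],
        stringsAsFactors = FALSE
      )
    }
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        pt <- parts[[j]]$polyline
        end <- pt[nrow(pt), ]
        extra_nodes[[length(extra_nodes) + 1L]] <- data.frame(
          node_id = inner_ids[j], x = end[1], y = end[2], control = "none",
          stringsAsFactors = FALSE)
      }
    }
  }
  parts_df <- do.call(rbind, part_rows)
  rownames(parts_df) <- NULL
  nodes <- rbind(network$nodes, do.call(rbind, extra_nodes))
  rownames(nodes) <- NULL
  if (anyDuplicated(parts_df$dseg_id)) stop("internal: duplicate dseg ids", call. = FALSE)
  dl <- list(parts = parts_df, nodes = nodes, geometry = geometry,
             index = parts_df[, c("parent_segment_id", "dseg_id", "part_index")],
             config = config, crs_note = network$crs_note)
  class(dl) <- "discretized_layer"
  dl$edges <- dlayer_edge_table(dl)
  dl
}

# Flat table of polyline edges across all parts, for vectorized snapping.
dlayer_edge_table <- function(dl) {
  rows <- lapply(dl$parts$dseg_id, function(id) {
    g <- dl$geometry[[id]]
    n <- nrow(g)
    cl <- polyline_cumlen(g)
    data.frame(dseg_id = id,
               x1 = g[-n, 1], y1 = g[-n, 2], x2 = g[-1, 1], y2 = g[-1, 2],
               s0 = cl[-n], elen = diff(cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the discretized layer to GeoJSON
#'
#' Same dialect as the input network; each part is a `LineString` feature
#' with properties `dseg_id`, `parent_segment_id`, `part_index`,
#' `speed_kmh`, `road_class`, `one_way`.
#'
#' @param dlayer a `discretized_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_discretized <- function(dlayer, path) {
  stopifnot(inherits(dlayer, "discretized_layer"))
  feats <- lapply(seq_len(nrow(dlayer$parts)), function(i) {
    p <- dlayer$parts[i, ]
    g <- dlayer$geometry[[p$dseg_id]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(j) c(g[j, 1], g[j, 2]))),
         properties = list(dseg_id = p$dseg_id,
                           parent_segment_id = p$parent_segment_id,
                           part_index = p$part_index,
                           speed_kmh = p$speed_kmh, road_class = p$road_class,
                           one_way = p$one_way))
  })
  fc <- list(type = "FeatureCollection", crs_note = dlayer$crs_note,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.discretized_layer <- function(x, ...) {
  cat(sprintf("Discretized layer: %d parts from %d segments (cap %g m)\n",
              nrow(x$parts), length(unique(x$parts$parent_segment_id)),
              x$config$max_segment_length_m))
  cat(sprintf("  part lengths: %.1f-%.1f m\n",
              min(x$parts$length_m), max(x$parts$length_m)))
  invisible(x)
}
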