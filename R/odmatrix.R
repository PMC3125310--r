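# Precomputed origin-destination driving times: the core lookup structure.
#
# Travel model conventions (shared by the precomputation, the single-pair
# check and the brute-force test oracle):
#   * a trip starts at the CENTROID of its origin part and first traverses
#     the residual half of that part, in either direction unless the part
#     is one-way; no impedance is charged at the origin point itself;
#   * traversing a full part costs length / (speed_limit *
#     vehicle_speed_factor); entering a controlled intersection costs its
#     impedance (5 s stop sign / 10 s traffic light by default);
#   * the trip ends at the hospital's snapped ER-entrance point on its
#     part, reached by the residual from whichever endpoint the route
#     enters; no impedance is ever charged at the final destination.

build_time_graph <- function(dlayer, config) {
  p <- dlayer$parts
  delay <- control_delay(dlayer$nodes$control, config)
  names(delay) <- dlayer$nodes$node_id
  v_ms <- p$speed_kmh / 3.6 * config$vehicle_speed_factor
  kin <- p$length_m / v_ms
  ef <- data.frame(from = p$from_node, to = p$to_node,
                   weight = kin + delay[p$to_node],
                   stringsAsFactors = FALSE)
  rev_ok <- !p$one_way
  er <- data.frame(from = p$to_node[rev_ok], to = p$from_node[rev_ok],
                   weight = kin[rev_ok] + delay[p$from_node[rev_ok]],
                   stringsAsFactors = FALSE)
  edges <- rbind(ef, er)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = dlayer$nodes["node_id"])
  list(graph = g, delay = delay, kin = kin, v_ms = v_ms)
}

# Destination entry options for a hospital snapped at arc position arc_m on
# part `row` (a one-row slice of dlayer$parts): node, residual metres.
hospital_entries <- function(row, arc_m) {
  ent <- data.frame(node = row$from_node, resid_m = arc_m,
                    stringsAsFactors = FALSE)
  if (!row$one_way) {
    ent <- rbind(ent, data.frame(node = row$to_node,
                                 resid_m = row$length_m - arc_m))
  }
  ent
}

# Shortest time from every node to the hospital point, given D: a matrix of
# node->entry-node distances (rows = entry nodes) from igraph, honouring the
# no-impedance-at-destination rule when the snapped point sits exactly on a
# node.
node_to_hospital_times <- function(D, entries, v_dest, delay, node_ids) {
  best <- rep(Inf, length(node_ids))
  names(best) <- node_ids
  exact <- character(0)
  for (j in seq_len(nrow(entries))) {
    w <- entries$node[j]
    r <- entries$resid_m[j]
    t_end <- r / v_dest
    adj <- if (r < 1e-9) delay[[w]] else 0  # drop the charge at a final node
    cand <- D[j, node_ids] + t_end - adj
    cand[w] <- t_end
    best <- pmin(best, cand)
    if (r < 1e-9) exact <- c(exact, w)
  }
  list(times = best, exact_nodes = exact)
}

#' Precompute the driving-time table
#'
#' Computes, for every discretized-part centroid and every hospital, the
#' shortest driving time under the package's travel model, by a
#' single-source Dijkstra search from each hospital over the reversed
#' travel direction (hospitals are few, centroids many). Disconnected
#' centroids are flagged unreachable rather than erroring. The table
#' carries a config snapshot and a network fingerprint so a stale table
#' cannot silently be used against a different network.
#'
#' @param dlayer a `discretized_layer`.
#' @param hospitals a `hospital_registry` that has been through
#'   [snap_hospitals()]; all hospitals in the registry are tabulated
#'   (inclusion is a query-time filter).
#' @param config the [mci_config()] the layer was built with.
#' @return a `driving_time_table`: `$entries` (dseg_id, hospital_id,
#'   seconds, reachable) and `$meta` (config, fingerprint, hospital ids).
#' @export
precompute_od <- function(dlayer, hospitals, config = dlayer$config) {
  stopifnot(inherits(dlayer, "discretized_layer"),
            inherits(hospitals, "hospital_registry"))
  if (any(is.na(hospitals$snapped_dseg))) {
    stop("hospital(s) not snapped to the network: ",
         paste(hospitals$hospital_id[is.na(hospitals$snapped_dseg)],
               collapse = ", "), " (run snap_hospitals first)", call. = FALSE)
  }
  bad <- setdiff(hospitals$snapped_dseg, dlayer$parts$dseg_id)
  if (length(bad) > 0) {
    stop("hospital snapped to unknown part(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gb <- build_time_graph(dlayer, config)
  p <- dlayer$parts
  node_ids <- dlayer$nodes$node_id
  half_t <- p$length_m / 2 / gb$v_ms
  out <- vector("list", nrow(hospitals))
  for (h in seq_len(nrow(hospitals))) {
    hid <- hospitals$hospital_id[h]
    hrow <- p[match(hospitals$snapped_dseg[h], p$dseg_id), ]
    arc <- hospitals$snap_arc_m[h]
    entries <- hospital_entries(hrow, arc)
    D <- igraph::distances(gb$graph, v = entries$node, mode = "in",
                           algorithm = "dijkstra")
    nh <- node_to_hospital_times(D, entries, gb$v_ms[match(hrow$dseg_id, p$dseg_id)],
                                 gb$delay, node_ids)
    TH <- nh$times
    charge <- gb$delay
    charge[nh$exact_nodes] <- 0
    # departure via the forward endpoint (always) and backward (if two-way)
    t_fwd <- half_t + charge[p$to_node] + TH[p$to_node]
    t_bwd <- ifelse(p$one_way, Inf,
                    half_t + charge[p$from_node] + TH[p$from_node])
    sec <- pmin(t_fwd, t_bwd)
    # same-part direct travel from the centroid to the snapped point
    i_same <- match(hrow$dseg_id, p$dseg_id)
    direct_ok <- !p$one_way[i_same] || arc >= p$length_m[i_same] / 2 - 1e-9
    if (direct_ok) {
      direct <- abs(p$length_m[i_same] / 2 - arc) / gb$v_ms[i_same]
      sec[i_same] <- min(sec[i_same], direct)
    }
    out[[h]] <- data.frame(dseg_id = p$dseg_id, hospital_id = hid,
                           seconds = ifelse(is.finite(sec), sec, NA_real_),
                           reachable = is.finite(sec),
                           stringsAsFactors = FALSE)
  }
  entries_df <- do.call(rbind, out)
  rownames(entries_df) <- NULL
  tbl <- list(entries = entries_df,
              meta = list(config = unclass(config),
                          fingerprint = dlayer_fingerprint(dlayer),
                          hospitals = hospitals$hospital_id,
                          n_parts = nrow(p)))
  class(tbl) <- "driving_time_table"
  tbl
}

#' Shortest driving time for a single origin-destination pair
#'
#' Computes one centroid-to-hospital time with a fresh forward shortest-path
#' run, without consulting any precomputed table. Used to cross-check table
#' entries; the two must agree.
#'
#' @param dlayer a `discretized_layer`.
#' @param dseg_id origin part id (trip starts at its centroid).
#' @param hospital one row of a snapped `hospital_registry`.
#' @param config the [mci_config()].
#' @return seconds (Inf if unreachable).
#' @export
od_time_single <- function(dlayer, dseg_id, hospital, config = dlayer$config) {
  p <- dlayer$parts
  io <- match(dseg_id, p$dseg_id)
  if (is.na(io)) stop("unknown dseg_id: ", dseg_id, call. = FALSE)
  ih <- match(hospital$snapped_dseg, p$dseg_id)
  if (is.na(ih)) stop("hospital not snapped to this layer", call. = FALSE)
  gb <- build_time_graph(dlayer, config)
  arc <- hospital$snap_arc_m
  entries <- hospital_entries(p[ih, ], arc)
  dep <- data.frame(node = p$to_node[io], stringsAsFactors = FALSE)
  if (!p$one_way[io]) dep <- rbind(dep, data.frame(node = p$from_node[io]))
  D <- igraph::distances(gb$graph, v = dep$node, to = entries$node,
                         mode = "out", algorithm = "dijkstra")
  exact <- entries$node[entries$resid_m < 1e-9]
  half_t <- p$length_m[io] / 2 / gb$v_ms[io]
  best <- Inf
  for (a in seq_len(nrow(dep))) {
    e <- dep$node[a]
    charge_e <- if (e %in% exact) 0 else gb$delay[[e]]
    for (b in seq_len(nrow(entries))) {
      w <- entries$node[b]
      r <- entries$resid_m[b]
      d_ew <- if (e == w) 0 else D[a, b] - if (r < 1e-9) gb$delay[[w]] else 0
      best <- min(best, half_t + charge_e + d_ew + r / gb$v_ms[ih])
    }
  }
  if (io == ih) {
    direct_ok <- !p$one_way[io] || arc >= p$length_m[io] / 2 - 1e-9
    if (direct_ok) best <- min(best, abs(p$length_m[io] / 2 - arc) / gb$v_ms[io])
  }
  best
}

#' Look up a precomputed driving time
#'
#' Constant-time retrieval from the table. With `rounding = TRUE` the time
#' is returned in whole minutes, rounded half up, the convention under
#' which model times are compared with ambulance log minutes.
#'
#' @param table a `driving_time_table`.
#' @param dseg_id origin part id.
#' @param hospital_id destination hospital id.
#' @param rounding return whole minutes instead of seconds.
#' @return seconds (or minutes); `NA` for a pair flagged unreachable.
#'   Unknown ids are an error.
#' @export
#' @examples
#' \dontrun{
#' lookup_time(tbl, "E0001#001", "H1", rounding = TRUE)
#' }
lookup_time <- function(table, dseg_id, hospital_id, rounding = FALSE) {
  stopifnot(inherits(table, "driving_time_table"))
  e <- table$entries
  i <- which(e$dseg_id == dseg_id & e$hospital_id == hospital_id)
  if (length(i) == 0) {
    if (!dseg_id %in% e$dseg_id) stop("unknown dseg_id: ", dseg_id, call. = FALSE)
    stop("unknown hospital_id: ", hospital_id, call. = FALSE)
  }
  if (!e$reachable[i[1]]) return(NA_real_)
  s <- e$seconds[i[1]]
  if (rounding) as.numeric(seconds_to_minutes(s)) else s
}

snap_point_full <- function(point, dlayer) {
  stopifnot(inherits(dlayer, "discretized_layer"))
  ed <- dlayer$edges
  if (is.null(ed) || nrow(ed) == 0) stop("empty discretized layer", call. = FALSE)
  pd <- point_edges_dist(point[1], point[2], ed$x1, ed$y1, ed$x2, ed$y2)
  dmin <- min(pd$dist)
  cand <- which(pd$dist <= dmin + 1e-9)
  # tie-break: lowest dseg_id, then lowest arc position
  ord <- order(ed$dseg_id[cand], ed$s0[cand] + pd$t[cand] * ed$elen[cand])
  i <- cand[ord[1]]
  arc <- ed$s0[i] + pd$t[i] * ed$elen[i]
  list(dseg_id = ed$dseg_id[i], arc_m = arc,
       x = ed$x1[i] + pd$t[i] * (ed$x2[i] - ed$x1[i]),
       y = ed$y1[i] + pd$t[i] * (ed$y2[i] - ed$y1[i]),
       dist_m = pd$dist[i])
}

#' Snap a point to its nearest discretized part
#'
#' Returns the part whose polyline minimizes the perpendicular Euclidean
#' distance to the point; exact ties are broken by the lowest `dseg_id`.
#' This is how a clicked MCI location (or a geocoded ER entrance) is mapped
#' into the precomputed table.
#'
#' @param point numeric length-2 (x, y), projected metres.
#' @param dlayer a `discretized_layer`.
#' @return the `dseg_id` (character), with the snapped position
#'   (`arc_m`, `x`, `y`, `dist_m`) attached as attributes.
#' @export
snap_point_to_dseg <- function(point, dlayer) {
  s <- snap_point_full(point, dlayer)
  structure(s$dseg_id, arc_m = s$arc_m, x = s$x, y = s$y, dist_m = s$dist_m)
}

#' Save / load a driving-time table
#'
#' The table is persisted as a diff-able CSV
#' (`dseg_id,hospital_id,seconds,reachable`) with a JSON metadata sidecar
#' (`<path>.meta.json`) holding the config snapshot and network
#' fingerprint. `load_table()` refuses a table whose fingerprint does not
#' match the supplied layer unless `force = TRUE`.
#'
#' @param table a `driving_time_table`.
#' @param path CSV path.
#' @return `path` invisibly (`save_table`); a `driving_time_table`
#'   (`load_table`).
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "driving_time_table"))
  e <- table$entries
  e$seconds <- sprintf("%.9f", e$seconds)
  e$seconds[!table$entries$reachable] <- ""
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(table$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_table
#' @param dlayer optional `discretized_layer` to check the fingerprint
#'   against.
#' @param force load despite a fingerprint mismatch.
#' @export
load_table <- function(path, dlayer = NULL, force = FALSE) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("table metadata sidecar missing: ", meta_path,
                                    call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dseg_id = "character",
                                       hospital_id = "character",
                                       seconds = "character",
                                       reachable = "logical"))
  need <- c("dseg_id", "hospital_id", "seconds", "reachable")
  if (!all(need %in% names(df))) stop("corrupt table file: ", path, call. = FALSE)
  df$seconds <- suppressWarnings(as.numeric(df$seconds))
  if (any(df$reachable & (is.na(df$seconds) | df$seconds < 0))) {
    stop("corrupt table file (bad seconds): ", path, call. = FALSE)
  }
  if (!is.null(dlayer)) {
    fp <- dlayer_fingerprint(dlayer)
    if (!identical(fp, meta$fingerprint) && !force) {
      stop("driving-time table fingerprint mismatch: table was built for a ",
           "different network (use force = TRUE to override)", call. = FALSE)
    }
  }
  tbl <- list(entries = df[, need], meta = meta)
  class(tbl) <- "driving_time_table"
  tbl
}

#' @export
print.driving_time_table <- function(x, ...) {
  e <- x$entries
  cat(sprintf("Driving-time table: %d parts x %d hospitals (%d unreachable pairs)\n",
              length(unique(e$dseg_id)), length(unique(e$hospital_id)),
              sum(!e$reachable)))
  if (any(e$reachable)) {
    cat(sprintf("  times: %.0f-%.0f s\n", min(e$seconds[e$reachable]),
                max(e$seconds[e$reachable])))
  }
  invisible(x)
}
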