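# Independent brute-force oracle for centroid-to-hospital driving times:
# exhaustive enumeration of all simple node paths, summing kinematic times
# and intersection impedances under the same conventions the package
# documents (origin = part centroid, no impedance at the origin point or
# the final destination). Shares no code with the Dijkstra-based
# implementation.

oracle_od_time <- function(dlayer, hospital, origin_dseg,
                           config = dlayer$config) {
  p <- dlayer$parts
  delay <- mcidss:::control_delay(dlayer$nodes$control, config)
  names(delay) <- dlayer$nodes$node_id
  v <- p$speed_kmh / 3.6 * config$vehicle_speed_factor
  kin <- p$length_m / v
  edges <- rbind(
    data.frame(from = p$from_node, to = p$to_node, kin = kin,
               stringsAsFactors = FALSE),
    data.frame(from = p$to_node[!p$one_way], to = p$from_node[!p$one_way],
               kin = kin[!p$one_way], stringsAsFactors = FALSE))
  io <- match(origin_dseg, p$dseg_id)
  ih <- match(hospital$snapped_dseg, p$dseg_id)
  arc <- hospital$snap_arc_m
  entries <- data.frame(node = p$from_node[ih], r = arc,
                        stringsAsFactors = FALSE)
  if (!p$one_way[ih]) {
    entries <- rbind(entries, data.frame(node = p$to_node[ih],
                                         r = p$length_m[ih] - arc))
  }
  exact <- entries$node[entries$r < 1e-9]
  deps <- p$to_node[io]
  if (!p$one_way[io]) deps <- c(deps, p$from_node[io])
  half <- p$length_m[io] / 2 / v[io]
  best <- Inf
  for (e in unique(deps)) {
    charge_e <- if (e %in% exact) 0 else delay[[e]]
    dfs <- function(node, visited, cost) {
      for (j in seq_len(nrow(entries))) {
        if (node == entries$node[j]) {
          # an arrival via an edge already paid delay(node); refund it when
          # the hospital sits exactly on this node (final destination)
          adj <- if (entries$r[j] < 1e-9 && cost > 0) delay[[node]] else 0
          best <<- min(best,
                       half + charge_e + cost - adj + entries$r[j] / v[ih])
        }
      }
      nxt <- which(edges$from == node & !(edges$to %in% visited))
      for (k in nxt) {
        nb <- edges$to[k]
        dfs(nb, c(visited, nb), cost + edges$kin[k] + delay[[nb]])
      }
    }
    dfs(e, e, 0)
  }
  if (io == ih && (!p$one_way[io] || arc >= p$length_m[io] / 2 - 1e-9)) {
    best <- min(best, abs(p$length_m[io] / 2 - arc) / v[io])
  }
  best
}

# Brute-force nearest part: scan every polyline edge of every part.
oracle_snap <- function(point, dlayer) {
  p <- dlayer$parts
  best_d <- Inf
  best_id <- NULL
  for (id in sort(p$dseg_id)) {
    g <- dlayer$geometry[[id]]
    for (i in seq_len(nrow(g) - 1L)) {
      a <- g[i, ]; b <- g[i + 1L, ]
      ab <- b - a
      t <- sum((point - a) * ab) / sum(ab * ab)
      t <- min(max(t, 0), 1)
      d <- sqrt(sum((point - (a + t * ab))^2))
      if (d < best_d - 1e-9) {
        best_d <- d
        best_id <- id
      }
    }
  }
  best_id
}
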