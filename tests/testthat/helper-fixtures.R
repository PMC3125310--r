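# Fixture builders: small GeoJSON networks written in code, plus seeded
# random mini-networks used by the oracle comparisons.

gj_line <- function(segment_id, coords, speed_kmh, road_class = "street",
                    one_way = FALSE) {
  list(type = "Feature",
       geometry = list(type = "LineString",
                       coordinates = lapply(seq_len(nrow(coords)),
                                            function(i) c(coords[i, 1], coords[i, 2]))),
       properties = list(segment_id = segment_id, speed_kmh = speed_kmh,
                         road_class = road_class, one_way = one_way))
}

gj_point <- function(node_id, xy, control = "none") {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = c(xy[1], xy[2])),
       properties = list(node_id = node_id, control = control))
}

write_gj <- function(features, path = tempfile(fileext = ".geojson")) {
  fc <- list(type = "FeatureCollection", crs_note = "test planar metres",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  path
}

# A two-segment elbow: A(0,0) - B(500,0) - C(500,400).
toy_elbow_path <- function(speed_kmh = 36, control_b = "none") {
  write_gj(list(
    gj_line("AB", rbind(c(0, 0), c(500, 0)), speed_kmh),
    gj_line("BC", rbind(c(500, 0), c(500, 400)), speed_kmh),
    gj_point("A", c(0, 0), "none"),
    gj_point("B", c(500, 0), control_b),
    gj_point("C", c(500, 400), "none")
  ))
}

hospital_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Registry row for a hospital placed exactly on a part at a given arc
# fraction (built through the CSV loader + snapping, like real input).
place_hospital_on_part <- function(dlayer, dseg_id, frac, hospital_id = "H1",
                                   trauma_level = 1, capacity = 10) {
  g <- dlayer$geometry[[dseg_id]]
  L <- dlayer$parts$length_m[match(dseg_id, dlayer$parts$dseg_id)]
  pt <- mcidss:::point_at(g, frac * L)
  path <- hospital_csv(data.frame(id = hospital_id, name = hospital_id,
                                  x = pt[1], y = pt[2],
                                  trauma_level = trauma_level,
                                  capacity = capacity))
  snap_hospitals(load_hospitals(path), dlayer)
}

# Seeded random mini-network: <= 8 intersections, spanning tree plus a few
# extra edges (some one-way), random speeds and controls. Returns the
# discretized layer plus a hospital snapped to a random interior point.
random_mini_city <- function(seed, config = mci_config()) {
  set.seed(seed)
  n <- sample(4:8, 1)
  repeat {
    xy <- cbind(runif(n, 0, 600), runif(n, 0, 600))
    if (min(dist(xy)) > 30) break
  }
  controls <- sample(c("none", "stop", "light"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
  edges <- lapply(2:n, function(i) c(sample(i - 1L, 1), i))  # spanning tree
  n_extra <- sample(0:3, 1)
  tried <- 0
  while (n_extra > 0 && tried < 20) {
    tried <- tried + 1
    cand <- sort(sample(n, 2))
    if (!any(vapply(edges, function(e) all(sort(e) == cand), TRUE))) {
      edges[[length(edges) + 1L]] <- cand
      n_extra <- n_extra - 1
    }
  }
  n_tree <- n - 1L
  feats <- list()
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    ow <- i > n_tree && runif(1) < 0.3  # tree stays two-way: connectivity
    feats[[length(feats) + 1L]] <- gj_line(
      sprintf("E%02d", i), rbind(xy[e[1], ], xy[e[2], ]),
      speed_kmh = sample(c(30, 40, 50, 60), 1), one_way = ow)
  }
  for (j in seq_len(n)) {
    feats[[length(feats) + 1L]] <- gj_point(sprintf("P%02d", j), xy[j, ],
                                            controls[j])
  }
  net <- load_network(write_gj(feats), config)
  dl <- discretize_network(net, config)
  hp <- sample(nrow(dl$parts), 1)
  hosp <- place_hospital_on_part(dl, dl$parts$dseg_id[hp],
                                 frac = runif(1, 0.15, 0.85))
  list(dlayer = dl, hospital = hosp, config = config)
}

# Closed-form shortest time on a uniform grid city with zero controls:
# residual half of the origin part, Manhattan node-to-node distance, and
# the destination residual, all at one speed.
grid_expected_seconds <- function(dlayer, hospital, spacing, speed_kmh,
                                  factor = 1) {
  v <- speed_kmh / 3.6 * factor
  rc <- function(id) as.numeric(strsplit(sub("^N", "", id), "_")[[1]])
  steps <- function(a, b) sum(abs(rc(a) - rc(b)))
  p <- dlayer$parts
  ih <- match(hospital$snapped_dseg, p$dseg_id)
  arc <- hospital$snap_arc_m
  entries <- rbind(
    data.frame(node = p$from_node[ih], r = arc),
    data.frame(node = p$to_node[ih], r = p$length_m[ih] - arc))
  vapply(seq_len(nrow(p)), function(i) {
    best <- Inf
    for (e in c(p$from_node[i], p$to_node[i])) {
      for (j in seq_len(nrow(entries))) {
        best <- min(best, (p$length_m[i] / 2 +
                             spacing * steps(e, entries$node[j]) +
                             entries$r[j]) / v)
      }
    }
    if (i == ih) best <- min(best, abs(p$length_m[i] / 2 - arc) / v)
    best
  }, 0)
}
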