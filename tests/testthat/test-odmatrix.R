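test_that("single segment: centroid to a hospital at one end is half the kinematic time", {
  net <- load_network(write_gj(list(
    gj_line("S1", rbind(c(0, 0), c(180, 0)), 36),   # 10 m/s
    gj_point("A", c(0, 0), "light")                 # control at the far end
  )))
  dl <- discretize_network(net, mci_config())
  hosp <- place_hospital_on_part(dl, "S1#001", frac = 1)  # at the 180 m end
  tbl <- precompute_od(dl, hosp, mci_config())
  # 90 m at 10 m/s; destination is a node, but no impedance at the trip end
  expect_equal(lookup_time(tbl, "S1#001", "H1"), 9)
})

test_that("a hand-built graph with a stop sign on the fast route matches the path-enumeration oracle", {
  # two routes from the left end to the right end: a short leg through a
  # stop-signed junction vs a longer uncontrolled detour
  feats <- list(
    gj_line("fast1", rbind(c(0, 0), c(150, 0)), 60),
    gj_line("fast2", rbind(c(150, 0), c(300, 0)), 60),
    gj_line("slow1", rbind(c(0, 0), c(150, 120)), 50),
    gj_line("slow2", rbind(c(150, 120), c(300, 0)), 50),
    gj_point("J", c(150, 0), "stop"),
    gj_point("K", c(150, 120), "none")
  )
  dl <- discretize_network(load_network(write_gj(feats)), mci_config())
  hosp <- place_hospital_on_part(dl, "fast2#001", frac = 0.8)
  tbl <- precompute_od(dl, hosp, mci_config())
  for (id in dl$parts$dseg_id) {
    expect_equal(lookup_time(tbl, id, "H1"),
                 oracle_od_time(dl, hosp[1, ], id), tolerance = 1e-9)
  }
})

test_that("precomputed times equal the oracle on seeded random mini networks", {
  for (seed in 1:25) {
    mc <- random_mini_city(seed)
    tbl <- precompute_od(mc$dlayer, mc$hospital, mc$config)
    for (id in mc$dlayer$parts$dseg_id) {
      got <- lookup_time(tbl, id, "H1")
      want <- oracle_od_time(mc$dlayer, mc$hospital[1, ], id)
      if (is.na(got)) {
        expect_false(is.finite(want))
      } else {
        expect_equal(got, want, tolerance = 1e-9,
                     label = sprintf("seed %d origin %s", seed, id))
      }
    }
  }
})

test_that("table lookups agree with fresh single-pair shortest-path runs", {
  paths <- generate_city(city_spec(rows = 8, cols = 8, seed = 21,
                                   long_segment_fraction = 0.2),
                         dir = withr::local_tempdir())
  m <- build_city_model(paths$network_path, paths$hospitals_path)
  set.seed(100)
  for (i in 1:100) {
    id <- sample(m$dlayer$parts$dseg_id, 1)
    h <- m$hospitals[sample(nrow(m$hospitals), 1), ]
    expect_equal(lookup_time(m$table, id, h$hospital_id),
                 od_time_single(m$dlayer, id, h), tolerance = 1e-9)
  }
})

test_that("lookup_time rounds half up to minutes and rejects unknown ids", {
  entries <- data.frame(dseg_id = c("d1", "d2", "d3"),
                        hospital_id = "H1",
                        seconds = c(780, 770, NA),
                        reachable = c(TRUE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  tbl <- structure(list(entries = entries, meta = list()),
                   class = "driving_time_table")
  expect_equal(lookup_time(tbl, "d1", "H1", rounding = TRUE), 13)
  expect_equal(lookup_time(tbl, "d2", "H1", rounding = TRUE), 13)  # 12.83 -> 13
  expect_equal(lookup_time(tbl, "d2", "H1"), 770)
  expect_true(is.na(lookup_time(tbl, "d3", "H1")))  # unreachable, not an error
  expect_error(lookup_time(tbl, "nope", "H1"), "unknown dseg_id")
  expect_error(lookup_time(tbl, "d1", "H9"), "unknown hospital_id")
  expect_equal(seconds_to_minutes(750), 13)  # half rounds up
})

test_that("snapping picks the nearest part, breaking ties by lowest id", {
  feats <- list(
    gj_line("A1", rbind(c(0, 0), c(100, 0)), 50),
    gj_line("B1", rbind(c(0, 40), c(100, 40)), 50)
  )
  dl <- discretize_network(load_network(write_gj(feats)), mci_config())
  on_line <- snap_point_to_dseg(c(30, 0), dl)
  expect_equal(as.character(on_line), "A1#001")
  expect_equal(attr(on_line, "dist_m"), 0)
  expect_equal(attr(on_line, "arc_m"), 30)
  # equidistant between the two parallel parts: lowest dseg_id wins
  expect_equal(as.character(snap_point_to_dseg(c(50, 20), dl)), "A1#001")
})

test_that("snapping matches an exhaustive distance scan on random points", {
  paths <- generate_city(city_spec(rows = 5, cols = 5, seed = 13,
                                   long_segment_fraction = 0.25),
                         dir = withr::local_tempdir())
  dl <- discretize_network(load_network(paths$network_path), mci_config())
  set.seed(77)
  for (i in 1:40) {
    pt <- runif(2, -50, 5 * 150 + 50)
    expect_equal(as.character(snap_point_to_dseg(pt, dl)),
                 oracle_snap(pt, dl))
  }
})

test_that("tables round-trip through CSV + metadata and refuse a mismatched network", {
  paths <- generate_city(city_spec(rows = 4, cols = 4, seed = 31),
                         dir = withr::local_tempdir())
  m <- build_city_model(paths$network_path, paths$hospitals_path)
  f <- tempfile(fileext = ".csv")
  save_table(m$table, f)
  back <- load_table(f, dlayer = m$dlayer)
  expect_equal(back$entries$seconds, m$table$entries$seconds, tolerance = 1e-9)
  expect_equal(back$entries$reachable, m$table$entries$reachable)
  expect_equal(back$meta$fingerprint, m$table$meta$fingerprint)

  other <- generate_city(city_spec(rows = 5, cols = 4, seed = 32),
                         dir = withr::local_tempdir())
  dl2 <- discretize_network(load_network(other$network_path), mci_config())
  expect_error(load_table(f, dlayer = dl2), "fingerprint mismatch")
  expect_s3_class(load_table(f, dlayer = dl2, force = TRUE),
                  "driving_time_table")
})

test_that("unreachable centroids are flagged, not errors", {
  # island segment disconnected from the hospital's component
  feats <- list(
    gj_line("M1", rbind(c(0, 0), c(150, 0)), 50),
    gj_line("ISL", rbind(c(1000, 1000), c(1100, 1000)), 50)
  )
  dl <- discretize_network(load_network(write_gj(feats)), mci_config())
  hosp <- place_hospital_on_part(dl, "M1#001", frac = 0.5)
  tbl <- precompute_od(dl, hosp, mci_config())
  expect_true(is.na(lookup_time(tbl, "ISL#001", "H1")))
  expect_false(tbl$entries$reachable[tbl$entries$dseg_id == "ISL#001"])
  # and persistence keeps the flag
  f <- tempfile(fileext = ".csv")
  save_table(tbl, f)
  expect_true(is.na(lookup_time(load_table(f), "ISL#001", "H1")))
})

test_that("adding a light never shortens entries; faster vehicles never lengthen them", {
  spec <- city_spec(rows = 6, cols = 6, seed = 41, p_stop = 0.2, p_light = 0.1)
  paths <- generate_city(spec, dir = withr::local_tempdir())
  m <- build_city_model(paths$network_path, paths$hospitals_path)
  base <- m$table$entries$seconds

  # upgrade one uncontrolled intersection to a traffic light
  net2 <- load_network(paths$network_path)
  free <- which(net2$nodes$control == "none")
  net2$nodes$control[free[1]] <- "traffic_light"
  dl2 <- discretize_network(net2, mci_config())
  reg2 <- snap_hospitals(load_hospitals(paths$hospitals_path), dl2)
  with_light <- precompute_od(dl2, reg2, mci_config())$entries$seconds
  expect_true(all(with_light >= base - 1e-9, na.rm = TRUE))

  # ambulance driving faster than posted limits
  fast_cfg <- mci_config(vehicle_speed_factor = 1.3)
  reg3 <- snap_hospitals(load_hospitals(paths$hospitals_path), m$dlayer)
  fast <- precompute_od(m$dlayer, reg3, fast_cfg)$entries$seconds
  expect_true(all(fast <= base + 1e-9, na.rm = TRUE))
})

test_that("precompute requires snapped hospitals", {
  paths <- generate_city(city_spec(rows = 3, cols = 3, seed = 51),
                         dir = withr::local_tempdir())
  net <- load_network(paths$network_path)
  dl <- discretize_network(net, mci_config())
  reg <- load_hospitals(paths$hospitals_path)  # not snapped
  expect_error(precompute_od(dl, reg, mci_config()), "not snapped")
})
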