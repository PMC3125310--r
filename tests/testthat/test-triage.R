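# A straight 10-block corridor with hospitals at increasing distance from
# the west end, built through the real loaders.
corridor_model <- function(levels = c(1, 1, 9), capacities = c(6, 10, 5),
                           at_parts = c(2, 5, 9)) {
  feats <- lapply(1:10, function(i) {
    gj_line(sprintf("E%02d", i),
            rbind(c((i - 1) * 150, 0), c(i * 150, 0)), 36)
  })
  dl <- discretize_network(load_network(write_gj(feats)), mci_config())
  pts <- t(vapply(at_parts, function(k) {
    mcidss:::point_at(dl$geometry[[sprintf("E%02d#001", k)]], 75)
  }, c(0, 0)))
  reg <- load_hospitals(hospital_csv(data.frame(
    id = sprintf("H%d", seq_along(levels)), name = sprintf("Hosp %d", seq_along(levels)),
    x = pts[, 1], y = pts[, 2] , trauma_level = levels, capacity = capacities)))
  reg <- snap_hospitals(reg, dl)
  tbl <- precompute_od(dl, reg, mci_config())
  list(dlayer = dl, hospitals = reg, table = tbl)
}

fake_result <- function(rows) {
  structure(list(incident = list(x = 0, y = 0, dseg_id = "E01#001",
                                 reference = "synthetic"),
                 rows = rows),
            class = "mci_query_result")
}

test_that("query results are ranked by driving time with excluded hospitals absent", {
  m <- corridor_model()
  res <- query_mci(c(10, 0), "west end", m$hospitals, m$table, m$dlayer)
  expect_equal(res$rows$hospital_id, c("H1", "H2", "H3"))
  expect_true(all(diff(res$rows$driving_time_min) >= 0))
  # reported minutes equal the rounded table lookups for the snapped part
  for (i in seq_len(nrow(res$rows))) {
    expect_equal(res$rows$driving_time_min[i],
                 lookup_time(m$table, res$incident$dseg_id,
                             res$rows$hospital_id[i], rounding = TRUE))
  }
  reg2 <- set_included(m$hospitals, "H2", FALSE)
  res2 <- query_mci(c(10, 0), "west end", reg2, m$table, m$dlayer)
  expect_false("H2" %in% res2$rows$hospital_id)
  # exclusion does not change the other hospitals' times
  expect_equal(res2$rows$driving_time_min,
               res$rows$driving_time_min[res$rows$hospital_id != "H2"])
  reg3 <- m$hospitals
  reg3$included <- FALSE
  expect_error(query_mci(c(10, 0), "", reg3, m$table, m$dlayer),
               "no included hospitals")
})

test_that("allocation follows the greedy nearest-with-capacity policy within tiers", {
  m <- corridor_model(levels = c(1, 1, 9), capacities = c(6, 10, 5))
  res <- query_mci(c(10, 0), "", m$hospitals, m$table, m$dlayer)

  # nearest level-1 hospital can take everyone
  few <- allocate_patients(res, 5, m$hospitals)
  expect_equal(few$assignments$hospital_id, rep("H1", 5))
  expect_equal(few$unassigned, 0)

  # ten critical patients: 6 to the nearest level-1, overflow 4 to the next
  ten <- allocate_patients(res, 10, m$hospitals)
  expect_equal(as.vector(table(ten$assignments$hospital_id)[c("H1", "H2")]),
               c(6, 4))
  expect_equal(ten$unassigned, 0)
  expect_false("H3" %in% ten$assignments$hospital_id)  # non-trauma untouched
  expect_equal(unname(ten$residual_capacities[c("H1", "H2", "H3")]),
               c(0L, 6L, 5L))

  # all trauma capacity exhausted: the level-9 fallback is used
  reg0 <- set_capacity(set_capacity(m$hospitals, "H1", 0), "H2", 0)
  fallback <- allocate_patients(res, 3, reg0)
  expect_equal(fallback$assignments$hospital_id, rep("H3", 3))

  # demand beyond total system capacity is reported, not dropped
  over <- allocate_patients(res, 30, m$hospitals)
  expect_equal(nrow(over$assignments) + over$unassigned, 30)
  expect_equal(over$unassigned, 30 - (6 + 10 + 5))
})

test_that("allocation invariants hold over random scenarios", {
  set.seed(2024)
  for (trial in 1:200) {
    n_h <- sample(2:8, 1)
    rows <- data.frame(
      hospital_id = sprintf("H%02d", 1:n_h),
      name = sprintf("Hosp %d", 1:n_h),
      trauma_level = sample(c(1, 2, 3, 4, 9), n_h, replace = TRUE),
      capacity = sample(0:8, n_h, replace = TRUE),
      driving_time_min = sample(0:40, n_h, replace = TRUE),
      reachable = runif(n_h) > 0.1,
      stringsAsFactors = FALSE)
    rows <- rows[order(!rows$reachable, rows$driving_time_min), ]
    res <- fake_result(rows)
    n <- sample(0:25, 1)
    plan <- allocate_patients(res, n)

    counts <- table(plan$assignments$hospital_id)
    caps <- stats::setNames(rows$capacity, rows$hospital_id)
    expect_true(all(counts <= caps[names(counts)]))               # capacity
    expect_equal(nrow(plan$assignments) + plan$unassigned, n)     # conservation
    expect_true(all(plan$residual_capacities >= 0))
    # tier respect: level 9 only used once all reachable trauma capacity is gone
    if (any(rows$trauma_level == 9 & rows$hospital_id %in% names(counts))) {
      used9 <- names(counts)[counts > 0 &
                               rows$trauma_level[match(names(counts), rows$hospital_id)] == 9]
      if (length(used9) > 0) {
        trauma <- rows$reachable & rows$trauma_level != 9
        expect_equal(sum(plan$residual_capacities[rows$hospital_id[trauma]]), 0)
      }
    }
    # raising any capacity never increases the unassigned count
    i <- sample(n_h, 1)
    rows2 <- rows
    rows2$capacity[i] <- rows2$capacity[i] + 3L
    plan2 <- allocate_patients(fake_result(rows2), n)
    expect_lte(plan2$unassigned, plan$unassigned)
    # determinism
    plan3 <- allocate_patients(res, n)
    expect_identical(plan3$assignments, plan$assignments)
  }
})

test_that("reports serialize deterministically in all three formats", {
  m <- corridor_model()
  res <- query_mci(c(10, 0), "corridor", m$hospitals, m$table, m$dlayer)
  plan <- allocate_patients(res, 4, m$hospitals)

  tab <- report(res, "table")
  expect_match(tab[1], "corridor")
  expect_equal(length(tab), 2 + nrow(res$rows))

  js <- report(res, "json")
  parsed <- jsonlite::fromJSON(paste(js, collapse = "\n"))
  expect_equal(parsed$rows$driving_time_min, res$rows$driving_time_min)
  expect_equal(parsed$rows$hospital_id, res$rows$hospital_id)

  cs <- report(plan, "csv")
  expect_equal(cs[1], "\"patient_index\",\"hospital_id\",\"driving_time_min\"")
  expect_equal(length(cs), 1 + nrow(plan$assignments))

  # empty plan: header-only csv
  none <- allocate_patients(res, 0, m$hospitals)
  expect_equal(length(report(none, "csv")), 1)

  expect_error(report(res, "xml"))

  # json round-trips into an identical query result
  f <- tempfile(fileext = ".json")
  writeLines(report(res, "json"), f)
  back <- read_query_result(f)
  expect_equal(back$rows, res$rows)
  expect_equal(back$incident$dseg_id, res$incident$dseg_id)
})

test_that("allocation handles a fully unreachable or empty candidate set", {
  rows <- data.frame(hospital_id = c("H1", "H2"), name = c("A", "B"),
                     trauma_level = c(1, 9), capacity = c(5, 5),
                     driving_time_min = c(NA_real_, NA_real_),
                     reachable = c(FALSE, FALSE), stringsAsFactors = FALSE)
  plan <- allocate_patients(fake_result(rows), 4)
  expect_equal(nrow(plan$assignments), 0)
  expect_equal(plan$unassigned, 4)
  expect_equal(unname(plan$residual_capacities), c(5L, 5L))
})
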