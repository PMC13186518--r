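test_that("generated cohorts have the configured shape and round-trip via CSV", {
  cfg <- cohort_config(n_participants = 5, n_days = 3, seed = 101)
  co <- generate_cohort(cfg)
  expect_length(co$epochs, 5)
  for (es in co$epochs) expect_equal(nrow(es), 3 * 2880)
  expect_equal(nrow(co$sleep_logs), 5 * 2)
  expect_equal(nrow(co$outcomes), 5)
  expect_equal(sum(co$outcomes$ptsd_dx), round(5 * 8 / 33))

  dir <- withr::local_tempdir()
  co2 <- generate_cohort(cfg, dir = dir)
  es_back <- read_epoch_csv(file.path(dir, "epochs_p01.csv"))
  expect_equal(es_back$activity, co2$epochs$p01$activity, tolerance = 1e-6)
  logs_back <- read_sleep_logs(file.path(dir, "sleep_logs.csv"))
  expect_equal(logs_back, co2$sleep_logs)
  oc_back <- read_outcomes(file.path(dir, "outcomes.csv"))
  expect_equal(oc_back$pcl31, co2$outcomes$pcl31)
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(n_participants = 4, n_days = 2, seed = 5))
  b <- generate_cohort(cohort_config(n_participants = 4, n_days = 2, seed = 5))
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$epochs$p01$activity, b$epochs$p01$activity)
  c <- generate_cohort(cohort_config(n_participants = 4, n_days = 2, seed = 6))
  expect_false(identical(a$epochs$p01$activity, c$epochs$p01$activity))
})

test_that("planted truth exposes the generative parameters", {
  cfg <- cohort_config(seed = 1, t_peak = 15, delta_acrophase_hours = 1.5)
  tr <- planted_truth(cfg)
  expect_equal(tr$control[tr$feature == "acrophase_time"], 15)
  expect_equal(tr$diagnosed[tr$feature == "acrophase_time"], 16.5)
  # schema completeness: every pipeline feature is planted or marked emergent
  expect_setequal(tr$feature, feature_names())
  expect_true(all(tr$emergent | !is.na(tr$control)))
})

test_that("infeasible effect configurations are rejected", {
  expect_error(cohort_config(seed = 1, delta_efficiency = -95),
               "infeasible")
  expect_error(cohort_config(seed = 1, delta_restfulness = -8),
               "infeasible")
  expect_error(cohort_config(seed = 1, n_participants = 3), ">= 4")
  expect_error(cohort_config(n_participants = 8), "seed")
})

test_that("zero effect sizes produce no systematic group differences", {
  # averaged over seeds, the diagnosed-vs-control mean difference of every
  # planted-effect feature stays within 2 pooled standard errors
  feats <- c("restfulness", "waso", "efficiency", "acrophase_time",
             "fragmentation")
  n_seed <- 10
  diffs <- matrix(NA_real_, n_seed, length(feats),
                  dimnames = list(NULL, feats))
  ses <- matrix(NA_real_, n_seed, length(feats), dimnames = list(NULL, feats))
  for (s in seq_len(n_seed)) {
    co <- generate_cohort(cohort_config(
      n_participants = 16, n_days = 4, seed = 300 + s,
      delta_restfulness = 0, delta_waso_minutes = 0, delta_efficiency = 0,
      delta_fragmentation = 0, delta_acrophase_hours = 0))
    rows <- derive_day_features(co$epochs, co$sleep_logs)
    p <- aggregate_person(rows)
    dx <- co$outcomes$ptsd_dx[match(p$participant_id,
                                    co$outcomes$participant_id)]
    for (f in feats) {
      g1 <- p[[f]][dx == 1]; g0 <- p[[f]][dx == 0]
      diffs[s, f] <- mean(g1) - mean(g0)
      ses[s, f] <- sqrt(var(g1) / length(g1) + var(g0) / length(g0))
    }
  }
  z <- colMeans(diffs) / (colMeans(ses) / sqrt(n_seed))
  expect_true(all(abs(z) < 2))
})

test_that("subjective ratings carry the configured person-level correlation", {
  cors <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(n_participants = 33, n_days = 3,
                                        seed = 500 + s))
    p <- co$sleep_logs |>
      dplyr::group_by(participant_id) |>
      dplyr::summarise(q = mean(quality), r = mean(restfulness))
    cor(p$q, p$r)
  })
  expect_gte(mean(cors), 0.8)
  expect_lte(mean(cors), 0.97)
})

test_that("default effect directions are recoverable from the raw outputs", {
  co <- default_cohort()
  rows <- default_cohort_features()
  p <- aggregate_person(rows)
  dx <- co$outcomes$ptsd_dx[match(p$participant_id, co$outcomes$participant_id)]
  tr <- co$truth
  for (f in c("restfulness", "waso", "efficiency", "acrophase_time",
              "fragmentation")) {
    want <- tr$direction[tr$feature == f]
    got <- sign(mean(p[[f]][dx == 1]) - mean(p[[f]][dx == 0]))
    expect_equal(got, want, info = f)
  }
})
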