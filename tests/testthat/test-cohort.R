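test_that("latent samplers respect their ranges, ordering and determinism", {
  set.seed(11)
  ctrl <- sample_breath_nh3("control", 2000)
  expect_true(all(ctrl >= 425 & ctrl <= 1800))
  expect_equal(mean(ctrl), 960, tolerance = 0.05)

  set.seed(12)
  dis <- sample_breath_nh3("disease", 2000)
  expect_true(all(dis >= 820 & dis <= 14700))
  expect_equal(mean(dis), 4880, tolerance = 0.05)

  set.seed(13)
  full <- sample_breath_nh3("candy_full", 2000)
  expect_true(all(full >= 820 & full <= 14700))
  set.seed(13)
  half <- sample_breath_nh3("candy_half", 2000)
  set.seed(13)
  quarter <- sample_breath_nh3("candy_quarter", 2000)
  expect_gt(mean(full), mean(half))
  expect_gt(mean(half), mean(quarter))
  expect_equal(mean(half) / mean(quarter), 2, tolerance = 0.1)

  set.seed(99); d1 <- sample_breath_nh3("control", 10)
  set.seed(99); d2 <- sample_breath_nh3("control", 10)
  expect_identical(d1, d2)

  expect_error(sample_breath_nh3("sick"), class = "pegs_invalid_parameter")
})

test_that("cohort generation is reproducible, paired and range-safe", {
  sp <- cohort_spec(n_subjects = 3, seed = 21, minutes = 2)
  ch1 <- generate_cohort(sp)
  ch2 <- generate_cohort(sp)
  expect_equal(ch1$manifest, ch2$manifest)
  expect_identical(ch1$recordings[["S01_control"]]$traces,
                   ch2$recordings[["S01_control"]]$traces)
  expect_equal(nrow(ch1$manifest), 6)
  expect_equal(length(ch1$recordings), 6)

  # latent values respect the per-condition ranges
  m <- ch1$manifest
  expect_true(all(m$breath_nh3_ppb[m$condition == "control"] >= 425 &
                    m$breath_nh3_ppb[m$condition == "control"] <= 1800))
  expect_true(all(m$breath_nh3_ppb[m$condition == "candy_full"] >= 820 &
                    m$breath_nh3_ppb[m$condition == "candy_full"] <= 14700))

  # paired structure: within-subject latent levels correlate across
  # conditions under the shared-copula design
  spl <- cohort_spec(n_subjects = 40, seed = 33, minutes = 2)
  lat <- with(generate_cohort(spl)$manifest,
              cbind(breath_nh3_ppb[condition == "control"],
                    breath_nh3_ppb[condition == "candy_full"]))
  expect_gt(stats::cor(lat[, 1], lat[, 2], method = "spearman"), 0.2)
})

test_that("cohort datasets round-trip through disk", {
  dir <- withr::local_tempdir()
  sp <- cohort_spec(n_subjects = 2, seed = 8, minutes = 2)
  ch <- generate_cohort(sp, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "channels.csv")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  back <- read_recording(file.path(dir, man$file[1]))
  orig <- ch$recordings[[sprintf("%s_%s", man$subject_id[1], man$condition[1])]]
  expect_equal(back$traces, orig$traces, tolerance = 1e-12)
  expect_equal(back$channels$functionalization, orig$channels$functionalization)
})

test_that("a noise-free subject recording recovers its latent level through calibration", {
  sp <- cohort_spec(n_subjects = 2, seed = 5)
  phys <- physics_params(capture_efficiency = sp$mask_capture_efficiency)
  arr <- function() make_array(params = phys, n_a = 3, n_u = 3)
  runs <- NULL
  # stay in the pre-depletion linear regime of the mask geometry
  for (c0 in c(0.25, 0.5, 0.75, 1.5)) {
    rec <- run_simulation(arr(), breathing_protocol(c0, 15))
    s <- analyze_breath(rec, method = "post_peak")$slope$slope
    runs <- rbind(runs, data.frame(conc = c0, slope = s))
  }
  cal <- build_calibration(runs)
  profile <- list(subject_id = "S01", condition = "control",
                  breath_nh3 = 1000, baseline_multipliers = NULL, seed = 1)
  spq <- cohort_spec(n_subjects = 2, seed = 5,
                     noise = noise_params(0, 0, 0, 0, 0))
  rec <- simulate_subject_recording(profile, spq)
  s <- analyze_breath(rec, method = "post_peak")$slope$slope
  expect_equal(invert_calibration(cal, s), 1, tolerance = 0.1)
})
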