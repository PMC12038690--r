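test_that("chamber protocol has baseline, exposure and recovery at fixed RH", {
  pr <- chamber_protocol("NH3", 5, 10, rh = 65)
  expect_s3_class(pr, "pegs_protocol")
  expect_equal(nrow(pr$segments), 3)
  expect_equal(pr$segments$rh, rep(65, 3))
  expect_equal(pr$segments$nh3, c(0, 5, 0))
  expect_equal(protocol_duration(pr), (2 + 10 + 5) * 60)
  expect_equal(sum(pr$segments$duration) * pr$repeat_count,
               protocol_duration(pr))

  co2 <- chamber_protocol("CO2", 5, 10)
  expect_equal(co2$segments$co2, c(0, 5, 0))
  expect_equal(co2$segments$nh3, c(0, 0, 0))

  expect_error(chamber_protocol("O3", 5, 10), class = "pegs_invalid_parameter")
  expect_error(chamber_protocol("NH3", -1, 10), class = "pegs_invalid_parameter")
  expect_error(chamber_protocol("NH3", 5, 0), class = "pegs_invalid_parameter")
})

test_that("breathing protocol cycles 8 s exhalation / 4 s inhalation", {
  pr <- breathing_protocol(5, 15)
  expect_equal(pr$repeat_count, 75)
  expect_equal(pr$segments$duration, c(8, 4))
  expect_equal(pr$segments$rh, c(90, 50))
  expect_equal(pr$segments$nh3, c(5, 0))   # NH3 only in the exhalation
  expect_equal(protocol_duration(pr), 900)

  # exhaled volume per cycle matches the bench simulator's ~270 mL tidal volume
  exhaled_mL <- pr$segments$flow[1] * pr$segments$duration[1] / 60
  expect_equal(exhaled_mL, 2000 * 8 / 60)
  expect_lt(abs(exhaled_mL - 270), 5)

  expect_error(breathing_protocol(-1, 15), class = "pegs_invalid_parameter")
  expect_error(breathing_protocol(1, 0), class = "pegs_invalid_parameter")
})

test_that("protocol expansion yields the per-step schedule", {
  pr <- breathing_protocol(2, 1)   # 5 cycles of 12 s
  sch <- pegsim:::protocol_schedule(pr, 0.1)
  expect_equal(nrow(sch), 600)
  # first 8 s of each cycle at 90% RH with gas, last 4 s at 50% without
  expect_equal(sch$rh[1], 90)
  expect_equal(sch$nh3[1], 2)
  expect_equal(sch$rh[81], 50)    # t = 8.0 s belongs to the inhalation
  expect_equal(sch$nh3[81], 0)
  expect_equal(sch$rh[121], 90)   # next cycle
  expect_equal(sum(sch$nh3 > 0) / nrow(sch), 2 / 3)
})
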