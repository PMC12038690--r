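test_that("simulation is deterministic under a fixed seed and records it", {
  arr <- make_array(n_a = 1, n_u = 1)
  pr <- breathing_protocol(1, 2)
  r1 <- run_simulation(arr, pr, noise = noise_params(), seed = 99)
  r2 <- run_simulation(arr, pr, noise = noise_params(), seed = 99)
  expect_identical(r1$traces, r2$traces)
  expect_equal(r1$meta$seed, 99L)
  r3 <- run_simulation(arr, pr, noise = noise_params(), seed = 100)
  expect_false(identical(r1$traces, r3$traces))
  # noise-free runs are deterministic outright and leave the ambient RNG alone
  set.seed(1); before <- runif(1)
  set.seed(1)
  n1 <- run_simulation(arr, pr)
  expect_equal(runif(1), before)
  n2 <- run_simulation(arr, pr)
  expect_identical(n1$traces, n2$traces)

  expect_error(run_simulation(list(), pr), class = "pegs_invalid_parameter")
})

test_that("chamber responses reproduce the acid-concentration regimes", {
  p <- physics_params()
  arr <- list(make_sensor("A", 0.01, params = p, ambient_rh = 65, id = "A1"),
              make_sensor("A", 0.001, params = p, ambient_rh = 65, id = "Alow"),
              make_sensor("U", params = p, ambient_rh = 65, id = "U1"))
  rec <- run_simulation(arr, chamber_protocol("NH3", 5, 10))
  expect_true(all(rec$traces > 0))
  g_hi <- rec$traces[, 1]
  t <- rec$time
  exposure <- t > 120 & t <= 720
  # 0.01 M: constant drop during exposure, quasi-linear
  expect_lt(g_hi[sum(t <= 720)], g_hi[sum(t <= 120)])
  fit <- linear_fit(t[exposure & t <= 660] / 60, g_hi[exposure & t <= 660])
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.98)
  # 0.001 M: acid depleted within the first minute of exposure, after which
  # the trace rises slowly like untreated paper
  g_lo <- rec$traces[, 2]
  i_dep <- which(exposure & g_lo == min(g_lo[exposure]))[1]
  expect_lt(t[i_dep], 120 + 60)
  post <- g_lo[exposure & t > t[i_dep]]
  expect_gt(post[length(post)], post[1])
  expect_true(all(diff(post) >= 0))

  # a null exposure yields a flat trace
  flat <- run_simulation(list(make_sensor("U", params = p, ambient_rh = 65)),
                         chamber_protocol("CO2", 0, 10))
  expect_lt(diff(range(flat$traces)) / mean(flat$traces), 1e-6)
})

test_that("clean-breath cycling drives every normalized channel to a rising plateau", {
  rec <- run_simulation(make_array(), breathing_protocol(0, 15))
  nt <- nrow(rec$traces)
  for (j in seq_len(ncol(rec$traces))) {
    s <- rec$traces[, j] / rec$traces[nt, j]
    # rises from its start and levels off: last-3-min mean within 1% of end
    expect_gt(s[nt] / s[1], 1.5)
    expect_lt(abs(mean(s[rec$time > 720]) - 1), 0.01)
  }
})

test_that("untreated and lightly acidified channels carry only the humidity signal", {
  arr <- list(make_sensor("A", 0.001, id = "Alow"), make_sensor("U", id = "U1"))
  r5 <- run_simulation(arr, breathing_protocol(5, 15))
  r0 <- run_simulation(arr, breathing_protocol(0, 15))
  nt <- nrow(r5$traces)
  for (j in 1:2) {
    s5 <- r5$traces[, j] / r5$traces[nt, j]
    s0 <- r0$traces[, j] / r0$traces[nt, j]
    expect_lt(max(abs(s5 - s0) / s0), 0.02)
  }
})

test_that("raw breathing traces oscillate at the 12-second breathing period", {
  rec <- run_simulation(make_array(n_a = 1, n_u = 1),
                        breathing_protocol(0, 6),
                        noise = noise_params(), seed = 5)
  x <- rec$traces[, 2]
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * rec$sample_rate / n
  target_bin <- which.min(abs(freq - 1 / 12))
  neighborhood <- setdiff(seq(target_bin - 8, target_bin + 8), target_bin)
  expect_gt(pw[target_bin], max(pw[neighborhood]))
})
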