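test_that("activation probability matches the concentration transfer law", {
  expect_equal(activation_probability(0, 5), 0)
  expect_equal(activation_probability(0.15), 0.17963, tolerance = 1e-5)
  expect_equal(activation_probability(0.75), 0.62842, tolerance = 1e-5)
  # strictly increasing in concentration and in beta
  cc <- seq(0, 1, by = 0.05)
  expect_true(all(diff(activation_probability(cc)) > 0))
  bb <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(vapply(bb, function(b) activation_probability(0.4, b), numeric(1))) > 0))
  expect_true(all(activation_probability(cc) >= 0 & activation_probability(cc) < 1))
  expect_error(activation_probability(-0.1), class = "flymi_error_invalid_parameter")
  expect_error(activation_probability(0.5, beta = 0), class = "flymi_error_invalid_parameter")
})

test_that("connectomes are Bernoulli(r) matrices, reproducible under a seed", {
  withr::with_seed(3, {
    dens <- replicate(1000, mean(sample_connectome(10, 50, r = 0.3)))
    expect_equal(mean(dens), 0.3, tolerance = 0.01 / 0.3)
  })
  withr::with_seed(4, {
    lo <- mean(replicate(200, mean(sample_connectome(10, 50, r = 0.001))))
    expect_equal(lo, 0.001, tolerance = 0.5) # 3 SE band around a tiny rate
  })
  c1 <- sample_connectome(10, 50, r = 0.3, seed = 8)
  expect_identical(c1, sample_connectome(10, 50, r = 0.3, seed = 8))
  expect_true(all(c1 %in% 0:1))
  expect_identical(dim(c1), c(10L, 50L))
  expect_error(sample_connectome(10, 50, r = 0), class = "flymi_error_invalid_parameter")
  expect_error(sample_connectome(10, 50, r = 1), class = "flymi_error_invalid_parameter")
})

test_that("connectomes round-trip through dense CSV", {
  cn <- sample_connectome(6, 20, r = 0.4, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectome(cn, path)
  expect_identical(unclass(read_connectome(path))[, ], unclass(cn)[, ])
})

test_that("antennal-lobe sampling activates only reached OPNs at the right rate", {
  panel <- draw_odor_panel(1, 0.75, mu = 35, sigma2 = 1e-12, seed = 21)
  al <- sample_al_state(panel[1, ], n_trials = 4000, seed = 22)
  outside <- setdiff(1:50, panel$reachable[[1]])
  expect_true(all(al[, outside] == 0))
  # Binomial mean: 35 reachable x p(0.75) ~ 22.0 actives per trial
  expect_equal(mean(rowSums(al)), 35 * activation_probability(0.75), tolerance = 0.02)
  panel_lo <- panel
  panel_lo$concentration <- 0.15
  al_lo <- sample_al_state(panel_lo[1, ], n_trials = 4000, seed = 23)
  expect_equal(mean(rowSums(al_lo)), 35 * activation_probability(0.15), tolerance = 0.05)
})

test_that("Kenyon cells fire on strictly supra-threshold drive and consume no randomness", {
  # one KC wired to OPNs 1..5, exactly those 5 active
  cn <- structure(matrix(c(rep(1L, 5), rep(0L, 5)), nrow = 1), r = 0.5,
    class = c("flymi_connectome", "matrix", "array")
  )
  al <- c(rep(1L, 5), rep(0L, 5))
  expect_equal(drop(kc_response(cn, al, theta = 5)), 0L)
  expect_equal(drop(kc_response(cn, al, theta = 4)), 1L)
  # all-silent input is all-silent output at any threshold
  cn10 <- sample_connectome(10, 50, r = 0.3, seed = 2)
  expect_true(all(kc_response(cn10, rep(0L, 50), theta = 1) == 0))
  # full connectivity, 10 active OPNs, theta = 9: every cell fires
  full <- structure(matrix(1L, nrow = 4, ncol = 50), r = 0.5,
    class = c("flymi_connectome", "matrix", "array")
  )
  expect_true(all(kc_response(full, c(rep(1L, 10), rep(0L, 40)), theta = 9) == 1))
  # purity: the RNG stream is untouched
  set.seed(1)
  before <- .Random.seed
  kc_response(cn10, matrix(1L, 10, 50), theta = 3)
  expect_identical(before, .Random.seed)
  expect_error(kc_response(cn10, rep(0L, 49), theta = 1), class = "flymi_error_dimension")
})

test_that("inhibition probability decays with activity and strength", {
  expect_equal(inhibition_probability(0, 0.9, activity = "count"), 1)
  expect_equal(inhibition_probability(5, 0.9, activity = "count"), 0.01111, tolerance = 1e-3)
  expect_equal(inhibition_probability(5, 0.1, activity = "count"), 0.60653, tolerance = 1e-5)
  # fraction mode rescales the count by the population size
  expect_equal(
    inhibition_probability(5, 0.9, n_kc = 10),
    inhibition_probability(0.5, 0.9, activity = "count")
  )
  expect_true(all(diff(inhibition_probability(0:10, 0.5, activity = "count")) < 0))
  aa <- seq(0.05, 1.75, by = 0.1)
  p_by_alpha <- vapply(aa, function(a) inhibition_probability(4, a, activity = "count"), numeric(1))
  expect_true(all(diff(p_by_alpha) < 0))
  expect_error(inhibition_probability(3, 0), class = "flymi_error_invalid_parameter")
  expect_error(inhibition_probability(3, 0.5, activity = "fraction"), class = "flymi_error_invalid_parameter")
})

test_that("feedback inhibition deletes spikes at the trial's own rate", {
  # silent input stays silent; huge alpha means vanishing inhibition
  silent <- matrix(0L, 5, 10)
  expect_identical(apply_inhibition(silent, 0.9, seed = 1), silent)
  active <- matrix(rep(c(1L, 0L), each = 5), nrow = 1)
  expect_identical(apply_inhibition(active, 1000, activity = "count", seed = 1), active)

  # a lone spike under weak activity is deleted with probability exp(-0.05);
  # every row is an independent trial of the same one-spike state
  one <- matrix(rep(c(1L, rep(0L, 9)), each = 1e5), nrow = 1e5)
  kept <- rowSums(apply_inhibition(one, 0.05, activity = "count", seed = 31))
  expect_equal(1 - mean(kept), exp(-0.05), tolerance = 0.005 / exp(-0.05))

  # expected surviving popcount is popcount * (1 - p_del), within 3 SE
  state <- matrix(rep(c(rep(1L, 6), rep(0L, 4)), each = 1e4), nrow = 1e4)
  p_del <- inhibition_probability(6, 0.25, activity = "count")
  counts <- rowSums(apply_inhibition(state, 0.25, activity = "count", seed = 32))
  se <- sd(counts) / sqrt(1e4)
  expect_lt(abs(mean(counts) - 6 * (1 - p_del)), 3 * se)
})

test_that("simulate_trial composes the pathway deterministically under a seed", {
  panel <- draw_odor_panel(2, 0.75, seed = 41)
  cn <- sample_connectome(10, 50, r = 0.3, seed = 42)
  s1 <- simulate_trial(panel[1, ], cn, theta = 4, n_trials = 6, alpha = 0.9, seed = 43)
  s2 <- simulate_trial(panel[1, ], cn, theta = 4, n_trials = 6, alpha = 0.9, seed = 43)
  expect_identical(s1, s2)

  # no-inhibition branch is exactly the thresholded feed-forward response
  ff <- simulate_trial(panel[1, ], cn, theta = 4, n_trials = 6, seed = 44)
  al <- sample_al_state(panel[1, ], n_trials = 6, seed = 44)
  expect_identical(ff, kc_response(cn, al, theta = 4))

  # saturating drive makes the response a deterministic function of the odor
  sat <- draw_odor_panel(1, 1.0, seed = 45)
  det <- simulate_trial(sat[1, ], cn, theta = 3, beta = 1e3, n_trials = 20, seed = 46)
  expect_equal(nrow(unique(det)), 1)
  expect_identical(
    det[1, ],
    drop(kc_response(cn, as.integer(1:50 %in% sat$reachable[[1]]), theta = 3))
  )
})
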