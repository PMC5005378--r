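test_that("modulation index matches its closed forms", {
  n <- 12000
  phi <- seq(0, 20 * 2 * pi, length.out = n + 1)[1:n]   # whole cycles
  # uniform phase, constant amplitude: full cancellation
  expect_lt(pac_mi(phi, rep(1, n)), 1e-9)
  # constant phase: mi = mean amplitude
  a <- runif(100, 0.5, 1.5)
  expect_equal(pac_mi(rep(0.7, 100), a), mean(a))
  # a = 1 + cos(phi): brute-force sum equals the analytic integral, 1/2
  expect_equal(pac_mi(phi, 1 + cos(phi)), 0.5, tolerance = 1e-6)
  expect_error(pac_mi(1:3, 1:4), "equal length")
})

test_that("mi invariances: phase wrap, amplitude scaling", {
  set.seed(5)
  phi <- runif(500, -pi, pi); a <- rexp(500)
  expect_equal(pac_mi(phi + 2 * pi * sample(-3:3, 500, TRUE), a),
               pac_mi(phi, a))
  expect_equal(pac_mi(phi, 3.7 * a), 3.7 * pac_mi(phi, a))
  # pacz is invariant to amplitude scaling
  z1 <- pacz(phi, a, seed = 9)
  z2 <- pacz(phi, 5 * a, seed = 9)
  expect_equal(z1, z2, tolerance = 1e-9)
  expect_equal(pacz(phi, a, seed = 9), z1)       # determinism
})

test_that("surrogate z-score separates real coupling from misalignment", {
  n <- 6000
  phi <- fm_phase(n, seed = 3)
  z <- pacz(phi, 1 + cos(phi), n_surrogates = 200, seed = 1)
  expect_gt(z, 5)
  # constant amplitude: flagged undefined
  expect_warning(zc <- pacz(phi, rep(2, n), seed = 1), "degenerate")
  expect_true(is.na(zc))
})

test_that("comodulogram localizes generated theta-gamma coupling", {
  grid_p <- seq(4, 12, 2); grid_a <- seq(22, 50, 4)
  hyp <- new_hypnogram(rep("WAKE", 150), "simulated")
  cm0 <- suppressWarnings(pac_comodulogram(wake_recording(0), hyp, sch24(),
    phase_centers = grid_p, amp_centers = grid_a, seed = 7))
  cm8 <- suppressWarnings(pac_comodulogram(wake_recording(0.8), hyp, sch24(),
    phase_centers = grid_p, amp_centers = grid_a, seed = 7))
  m0 <- cm0$pacz$scotophase; m8 <- cm8$pacz$scotophase
  # kappa = 0: null-like medians everywhere
  expect_lt(max(abs(m0), na.rm = TRUE), 2)
  # kappa = 0.8: argmax at the (8 Hz, gamma) neighborhood
  ix <- which(m8 == max(m8, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(grid_p[ix[1]], 8, tolerance = 2)
  expect_gte(grid_a[ix[2]], 26)
  expect_lte(grid_a[ix[2]], 50)
  expect_gt(max(m8, na.rm = TRUE), 4)
  # a state with no epochs gives an all-missing matrix with a warning
  expect_warning(
    cmr <- comodulogram(filterbank_hilbert(wake_recording(0), centers = c(4, 8, 24)),
                        hyp, sch24(), state = "REM",
                        phase_centers = c(4, 8), amp_centers = 24),
    "no qualifying")
  expect_true(all(is.na(cmr$pacz$scotophase)))
})

test_that("median PACz grows with coupling strength", {
  # monotone trend of the (8 Hz, gamma) cell across kappa, few seeds
  grid_p <- 8; grid_a <- c(34, 38, 42)
  hyp <- new_hypnogram(rep("WAKE", 90), "simulated")
  med_at <- function(kappa, seed) {
    rec <- preprocess(simulate_eeg_emg(hyp, sch24(),
      sim_params(coupling_strength = kappa), seed = seed))
    cm <- suppressWarnings(pac_comodulogram(rec, hyp, sch24(),
      phase_centers = grid_p, amp_centers = grid_a, seed = 11))
    max(cm$pacz$scotophase, na.rm = TRUE)
  }
  kappas <- c(0, 0.4, 0.8)
  vals <- vapply(c(41, 42, 43), function(s)
    vapply(kappas, med_at, numeric(1), seed = s), numeric(3))
  # non-decreasing in kappa for every seed
  expect_true(all(apply(vals, 2, function(v) all(diff(v) > -0.5))))
  expect_true(all(vals[3, ] > vals[1, ]))
})

test_that("cluster comparison is exact under the null and finds known effects", {
  set.seed(77)
  dims <- c(8, 10)
  null_mats <- function() lapply(1:6, function(i)
    matrix(rnorm(prod(dims)), dims[1], dims[2]))
  a <- null_mats()
  # a = b: zero suprathreshold cells
  res0 <- cluster_compare(a, a, n_perm = 200, seed = 1)
  expect_length(res0$clusters, 0)
  # injected effect at a known block
  b <- lapply(null_mats(), function(m) { m[3:4, 5:6] <- m[3:4, 5:6] + 4; m })
  res1 <- cluster_compare(a, b, n_perm = 500, seed = 2)
  sig <- Filter(function(cc) cc$significant, res1$clusters)
  expect_gte(length(sig), 1)
  true_cells <- as.vector(outer(3:4, (5:6 - 1) * dims[1], `+`))
  expect_true(any(vapply(sig, function(cc)
    any(true_cells %in% cc$cells), TRUE)))
  expect_error(cluster_compare(a, a[1:3], n_perm = 100), "paired")
})
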