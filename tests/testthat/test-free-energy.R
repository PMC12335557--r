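# Mean forces, block errors, thermodynamic integration, metadynamics
# reweighting, and profile features.

test_that("mean force is -k times the mean restraint displacement", {
  w <- restraint_window(target = 10, k = 1, series = rep(12, 4000),
                        dt = 1, burn_in = 1000)
  mf <- mean_force(w)
  expect_equal(mf$mean_force, -2)
  expect_equal(mf$se, 0)
  expect_equal(mean_force(restraint_window(5, 1, rep(5, 4000)))$mean_force, 0)
  # burn-in is honoured: pre-burn-in samples do not bias the average
  wb <- restraint_window(0, 2, c(rep(100, 2000), rep(1, 2000)),
                         burn_in = 2000)
  expect_equal(mean_force(wb)$mean_force, -2)
  expect_error(restraint_window(0, 1, rep(0, 100), dt = 1), "too short")
})

test_that("restrained Gaussian sampling matches the closed-form mean", {
  # F = a/2 (N - N0)^2 with restraint (k, N*): mean (a N0 + k N*) / (a + k)
  a <- 0.5; N0 <- 10; k <- 1; tgt <- 4
  closed <- (a * N0 + k * tgt) / (a + k)
  expect_equal(closed, 6)
  oracle <- restrained_mean_oracle(function(x) a / 2 * (x - N0)^2, k, tgt)
  expect_equal(oracle, closed, tolerance = 1e-6)

  w <- sample_restrained_series(function(x) a / 2 * (x - N0)^2, k = k,
                                targets = tgt, n_samples = 12000,
                                seed = 101)[[1]]
  mf <- mean_force(w)
  expect_lt(abs(mf$mean_position - closed), 3 * mf$se / k)
  expect_lt(abs(mf$mean_force - (-2)), 3 * mf$se)
})

test_that("the stiff-spring limit pins the sampled mean to the target", {
  w <- sample_restrained_series(double_well, k = 100, targets = 5,
                                n_samples = 6000, seed = 7,
                                burn_in = 1000)[[1]]
  expect_lt(abs(mean_force(w)$mean_position - 5), 0.1)
})

test_that("block standard errors behave like sigma/sqrt(n) for iid data", {
  expect_equal(block_se(rep(3, 1000), 100), 0)
  set.seed(2)
  x <- rnorm(1e4)
  se <- block_se(x, 100)
  expect_lt(abs(se - 0.01), 0.003)
  expect_error(block_se(rnorm(150), 100), "2 complete blocks")
})

test_that("block errors exceed naive errors under serial correlation", {
  set.seed(14)
  n <- 1e4
  x <- numeric(n)
  for (i in 2:n) x[i] <- 0.9 * x[i - 1] + rnorm(1)
  expect_gt(block_se(x, 100), sd(x) / sqrt(n))
})

test_that("thermodynamic integration accumulates forces and errors", {
  pts <- data.frame(target = 0:10, mean_force = 2, se = 0.3,
                    mean_position = 0:10)
  pr <- integrate_profile(pts, method = "euler")
  expect_equal(pr$F[11], 20)
  expect_equal(pr$se[11], 0.3 * sqrt(10)) # quadrature propagation, s*sqrt(m)
  expect_equal(pr$F[1], 0)

  expect_error(integrate_profile(rbind(pts, pts[1, ])), "duplicate")
  expect_warning(integrate_profile(pts[c(3, 1, 2, 4:11), ]), "not sorted")

  # trapezoid integrates a linear force exactly
  lin <- data.frame(target = seq(0, 20, by = 0.5))
  lin$mean_force <- 0.5 * (lin$target - 10)
  lin$se <- 0
  lin$mean_position <- lin$target
  tr <- integrate_profile(lin, method = "trapezoid")
  tru <- 0.25 * (lin$target - 10)^2 - 0.25 * 100
  expect_equal(tr$F, tru, tolerance = 1e-12)
})

test_that("forward and backward integration differ by a constant", {
  set.seed(31)
  ws <- sample_restrained_series(function(x) 0.25 * (x - 10)^2, k = 1,
                                 targets = seq(0, 20, length.out = 15),
                                 n_samples = 5000, seed = 31,
                                 burn_in = 1000)
  pts <- lapply(ws, mean_force)
  fwd <- integrate_profile(pts, method = "trapezoid",
                           abscissa = "mean_position")
  flip <- rev(lapply(pts, function(p) {
    p$target <- -p$target
    p$mean_position <- -p$mean_position
    p$mean_force <- -p$mean_force
    p
  }))
  bwd <- integrate_profile(flip, method = "trapezoid",
                           abscissa = "mean_position")
  diffs <- fwd$F - rev(bwd$F)
  expect_lt(max(diffs) - min(diffs), 1e-9)
})

test_that("zero-bias reweighting equals the plain histogram exactly", {
  set.seed(6)
  s <- rnorm(4000, 8, 1.5)
  tr <- metad_trace(seq_along(s), s, temperature = 300)
  grid <- seq(min(s) - 0.01, max(s) + 0.01, length.out = 41)
  w <- diff(grid)[1] / 2
  prof <- metad_reweight(tr, grid = grid, n_blocks = 0)
  # independent plain histogram estimator
  kT <- 0.0019872041 * 300
  p <- hist(s, breaks = c(grid[1] - w, grid + w), plot = FALSE)$density
  Fr <- -kT * log(p)
  Fr <- Fr - min(Fr[is.finite(Fr)])
  expect_equal(prof$F, Fr, tolerance = 1e-12)
})

test_that("a converged bias reweights back to the underlying landscape", {
  set.seed(19)
  s <- runif(60000, 0, 16) # flat biased ensemble: V = -F
  tr <- metad_trace(seq_along(s), s, temperature = 300,
                    bias_fn = function(x) -double_well(x))
  prof <- metad_reweight(tr, grid = seq(0, 16, length.out = 81))
  tru <- double_well(prof$grid)
  tru <- tru - min(tru)
  wells <- tru < 2
  expect_lt(max(abs(prof$F - tru)[wells]), 0.5)

  # temperature enters only through the log-weights: recompute directly
  tr2 <- metad_trace(tr$times, tr$s, temperature = 600,
                     bias_fn = tr$bias_fn)
  prof2 <- metad_reweight(tr2, grid = prof$grid, n_blocks = 0)
  kT2 <- 0.0019872041 * 600
  w2 <- exp(-double_well(tr$s) / kT2)
  edges <- c(prof$grid[1] - 0.1, prof$grid + 0.1)
  bin <- findInterval(tr$s, edges, rightmost.closed = TRUE)
  p2 <- vapply(seq_along(prof$grid),
               function(b) sum(w2[bin == b]), numeric(1)) /
    (sum(w2) * diff(edges))
  F2 <- -kT2 * log(p2)
  F2 <- F2 - min(F2[is.finite(F2)])
  expect_equal(prof2$F, F2, tolerance = 1e-9)
})

test_that("hill lists evaluate to the sum of their Gaussians", {
  hills <- data.frame(time = c(1, 2), center = c(0, 3), height = c(1, 2),
                      width = c(1, 2))
  tr <- metad_trace(1:2, c(0, 0), hills = hills)
  s <- c(-1, 0, 3)
  manual <- 1 * exp(-(s - 0)^2 / 2) + 2 * exp(-(s - 3)^2 / 8)
  expect_equal(metad_bias(tr, s), manual)
  expect_equal(metad_bias(tr, s, time = 1), exp(-(s - 0)^2 / 2))
})

test_that("profile features find minima and barriers", {
  g <- seq(0, 16, by = 0.25)
  quad <- free_energy_profile(g, 0.25 * (g - 10)^2 - 5)
  fq <- profile_features(quad)
  expect_equal(nrow(fq$minima), 1L)
  expect_equal(fq$minima$grid, 10)
  expect_equal(nrow(fq$barriers), 0L)

  dw <- free_energy_profile(g, double_well(g))
  fd <- profile_features(dw)
  expect_equal(fd$minima$grid, c(2, 14))
  expect_equal(fd$barriers$height, 3, tolerance = 1e-9)
  expect_equal(fd$barriers$saddle_grid, 8)

  mono <- free_energy_profile(g, 0.3 * g)
  fm <- profile_features(mono)
  expect_equal(fm$minima$grid, 0)
  expect_equal(nrow(fm$barriers), 0L)

  # sub-threshold roughness on the barrier flank is merged away
  rough <- double_well(g)
  rough[g == 5] <- rough[g == 5] - 0.2 # a 0.2 kcal/mol dimple
  fr <- profile_features(free_energy_profile(g, rough), min_barrier = 0.5)
  expect_equal(fr$minima$grid, c(2, 14))
})

test_that("window manifests and hills round-trip through files", {
  ws <- sample_restrained_series(function(x) 0.1 * x^2, k = 2,
                                 targets = c(1, 4), n_samples = 3500,
                                 seed = 3, burn_in = 500)
  dir <- withr::local_tempdir()
  man <- write_windows(ws, dir)
  back <- read_windows(man)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$series, ws[[1]]$series, tolerance = 1e-9)
  expect_equal(back[[2]]$target, 4)
  expect_equal(back[[1]]$k, 2)

  hills <- data.frame(time = 1:3, center = c(0, 1, 2), height = 0.5,
                      width = 1.2)
  hp <- file.path(dir, "hills.tsv")
  write.table(hills, hp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_hills(hp), hills)
})
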