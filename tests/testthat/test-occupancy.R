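# Region counters (sharp and Fermi-smoothed), occupancy statistics, wet/dry
# classification, SF-contact waters, the lipid-density CV, and contacts.

axis_z <- pore_axis_from(c(0, 0, 0), c(0, 0, 1))

test_that("sharp counting respects boundaries and empty selections", {
  dpv <- dpv_region(axis_z)
  fr <- make_test_frame(rbind(
    c(0, 0, -14),      # inside
    c(7, 0, -14),      # on the wall: inside by convention
    c(0, 0, -17),      # on the bottom face: inside
    c(7.2, 0, -14),    # outside radially
    c(0, 0, -11)       # outside axially
  ))
  expect_equal(count_in_region(fr, dpv, NULL), 3L)
  expect_equal(count_in_region(fr, dpv, integer(0)), 0L)
})

test_that("counting is invariant under joint rigid transforms", {
  set.seed(4)
  fr <- make_test_frame(matrix(rnorm(120, sd = 9), ncol = 3))
  regs <- list(dpv_region(axis_z),
               sphere_region(c(1, 2, -3), 6),
               box_region(c(0, 0, -10), c(5, 5, 4)))
  R <- random_rotation(9)
  shift <- c(2, -5, 1)
  frR <- transform_frame(fr, R, shift)
  for (reg in regs) {
    expect_equal(
      count_in_region(frR, transform_region(reg, R, shift), NULL),
      count_in_region(fr, reg, NULL)
    )
  }
})

test_that("Fermi-smoothed box counts have the documented limiting behavior", {
  box3 <- box_region(c(0, 0, 0), c(30, 30, 30), fermi_lambda = 3)
  deep <- make_test_frame(c(0, 0, 0))
  expect_equal(smooth_count(deep, box3, NULL), 1, tolerance = 1e-3)

  on_face <- make_test_frame(c(30, 0, 0))
  expect_equal(smooth_count(on_face, box3, NULL), 0.5, tolerance = 1e-3)

  # sharp limit: lambda = 0 equals the integer count exactly; atoms kept
  # half an angstrom away from the faces so the limit is clean
  set.seed(1)
  pts <- matrix(runif(90, -25, 25), ncol = 3)
  pts[abs(abs(pts) - 20) < 0.5] <- 0
  fr <- make_test_frame(pts)
  box0 <- box_region(c(0, 0, 0), c(20, 20, 20), fermi_lambda = 0)
  expect_identical(smooth_count(fr, box0, NULL),
                   as.numeric(count_in_region(fr, box0, NULL)))
  # and lambda -> 0 converges to it
  for (lam in c(0.1, 0.01)) {
    boxl <- box_region(c(0, 0, 0), c(20, 20, 20), fermi_lambda = lam)
    d <- abs(smooth_count(fr, boxl, NULL) - count_in_region(fr, box0, NULL))
    expect_lt(d, max(lam, 1e-2))
  }
})

test_that("occupancy series tracks scripted lipid entry and water exit", {
  fx <- build_channel_fixture(
    n_frames = 15, n_water_dpv = 12,
    lipid_entry = list(frame = 10, lipid = 1, tail = "unsaturated",
                       n_carbons = 3),
    water_exit = list(frame = 10, n = 11), seed = 21)
  m <- fx$manifest
  occ <- occupancy_series(fx$series, m$selections$water,
                          m$selections$lipid_tails, m$selections$sf,
                          reference = m$selections$reference)
  expect_equal(occ$n_water, m$n_water_dpv)
  expect_equal(occ$n_lipid, m$n_lipid_dpv)
  expect_equal(occ$n_lipid[9:10], c(0, 3))

  # swapping the two selections swaps the columns exactly
  swp <- occupancy_series(fx$series, m$selections$lipid_tails,
                          m$selections$water, m$selections$sf,
                          reference = m$selections$reference)
  expect_identical(swp$n_water, occ$n_lipid)
  expect_identical(swp$n_lipid, occ$n_water)

  expect_error(
    occupancy_series(fx$series, m$selections$water, m$selections$water,
                     m$selections$sf, reference = m$selections$reference),
    "overlap")
})

test_that("occupancy statistics honour the equilibration cutoff", {
  s <- occupancy_series_from(times = 0:3, n_water = c(0, 0, 10, 10),
                             n_lipid = c(5, 5, 0, 0))
  st <- occupancy_stats(s, t_min = 2)
  expect_equal(st$mean_water, 10)
  expect_equal(st$sd_water, 0)
  expect_equal(st$n_used, 2)
  expect_error(occupancy_stats(s, t_min = 3.5), "fewer than 2")

  cst <- occupancy_stats(occupancy_series_from(0:4, rep(7, 5), rep(0, 5)))
  expect_equal(cst$mean_water, 7)
  expect_equal(cst$sd_water, 0)

  # sampling oracle: Gaussian counts recover their mean
  set.seed(8)
  n <- 1e4
  x <- round(rnorm(n, 14, 3))
  stg <- occupancy_stats(occupancy_series_from(seq_len(n), pmax(x, 0),
                                               rep(0, n)))
  expect_lt(abs(stg$mean_water - 14), 3 * 3 / sqrt(n))
})

test_that("the joint negative-log histogram is anchored at zero", {
  set.seed(12)
  wet <- cbind(rnorm(300, 15, 1.2), rnorm(300, 0.5, 0.4))
  dry <- cbind(rnorm(300, 1, 0.6), rnorm(300, 7, 1.2))
  both <- rbind(wet, dry)
  s <- occupancy_series_from(seq_len(nrow(both)), pmax(both[, 1], 0),
                             pmax(both[, 2], 0))
  h <- joint_histogram(s)
  expect_equal(min(h$z[is.finite(h$z)]), 0)
  expect_true(all(h$z >= 0))
  # wet/dry anticorrelation of the underlying counts
  expect_lt(cor(s$n_water, s$n_lipid), 0)
  expect_error(joint_histogram(occupancy_series_from(1:3, c(2, 2, 2),
                                                     c(1, 1, 1))),
               "degenerate")
})

test_that("wet/dry classification thresholds and locates switches", {
  s <- occupancy_series_from(1:4, c(15, 14, 1, 0), c(0, 0, 3, 3))
  st <- wet_dry_classify(s, 5)
  expect_equal(as.character(st), c("wet", "wet", "dry", "dry"))
  expect_equal(attr(st, "switches"), 3L)
  allz <- wet_dry_classify(occupancy_series_from(1:3, c(0, 0, 0), c(0, 0, 0)))
  expect_true(all(allz == "dry"))
})

test_that("SF-contact water counting is inclusive at the cutoff", {
  k <- c(0, 0, 0)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0))
  xyz <- rbind(k, dirs[1:3, ] * 3.0, dirs[4:5, ] * 4.0, c(0, 0, 3.6))
  fr <- make_test_frame(xyz,
                        names = c("K", rep("OH2", 6)),
                        resnames = c("POT", rep("TIP3", 6)))
  ksel <- select_atoms(fr, "name K")
  wsel <- select_atoms(fr, "name OH2")
  expect_equal(sf_contact_waters(fr, ksel, wsel), 4L) # 3 at 3.0 + 1 at 3.6
  expect_equal(sf_contact_waters(fr, ksel, wsel, cutoff = 3.5), 3L)
  expect_equal(sf_contact_waters(fr, ksel, select_atoms(fr, "name NONE")), 0L)
  expect_error(sf_contact_waters(fr, wsel, ksel), "exactly one")
})

test_that("the lipid-density CV matches its sharp and surface limits", {
  sph <- sphere_region(c(0, 0, 0), 7)
  inside <- make_test_frame(matrix(rnorm(30, sd = 1), ncol = 3))
  expect_equal(lipid_density_cv(inside, sph, NULL), 10)
  vol_nm3 <- 4 / 3 * pi * 0.7^3
  expect_equal(lipid_density_cv(inside, sph, NULL, normalize = TRUE),
               10 / vol_nm3)
  surf <- make_test_frame(c(7, 0, 0))
  expect_equal(lipid_density_cv(surf, sph, NULL, smooth = 2), 0.5,
               tolerance = 1e-9)
  set.seed(3)
  fr <- make_test_frame(matrix(runif(60, -10, 10), ncol = 3))
  expect_equal(lipid_density_cv(fr, sph, NULL, smooth = 1e-6),
               lipid_density_cv(fr, sph, NULL, smooth = 0),
               tolerance = 1e-3)
})

test_that("annular lipid contacts require simultaneous proximity", {
  fx <- build_channel_fixture(
    n_frames = 4, n_lipids = 2, contact_lipids = 1,
    lipid_entry = list(frame = 3, lipid = 1, tail = "saturated",
                       n_carbons = 2), seed = 5)
  m <- fx$manifest
  s6 <- paste(sprintf("(%s)", unlist(m$selections$s6)), collapse = " or ")
  fr1 <- get_frame(fx$series, 1)
  ax <- pore_axis(fr1, m$selections$sf, reference = m$selections$reference)
  dpv <- dpv_region(ax)

  rec1 <- annular_lipid_contacts(fr1, m$selections$lipids, m$selections$r329,
                                 m$selections$k392, s6, dpv)
  expect_equal(nrow(rec1), 1L)  # only the contact lipid qualifies
  expect_equal(rec1$resid, 1L)
  expect_false(rec1$penetration)
  expect_lt(rec1$d_phosphate_r329, 6)

  rec3 <- annular_lipid_contacts(get_frame(fx$series, 3),
                                 m$selections$lipids, m$selections$r329,
                                 m$selections$k392, s6, dpv)
  expect_true(rec3$penetration)
  expect_equal(rec3$tail, "saturated") # the scripted tail is the one inside
  expect_equal(nrow(attr(rec3, "tail_xy")[[1]]), 12L)

  expect_error(annular_lipid_contacts(fr1, "resname NONE",
                                      m$selections$r329, m$selections$k392,
                                      s6, dpv), "empty selection")
})
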