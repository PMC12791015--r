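test_that("recenter_to_tag_site applies R(euler) %*% offset per particle", {
  tab <- particle_table(data.frame(x = 100, y = 200, z = 300,
                                   rot = 0, tilt = 0, psi = 0))
  out <- recenter_to_tag_site(tab, c(0, 0, 129))
  expect_equal(unname(particle_positions(out)[1, ]), c(100, 200, 429))

  # rot = 180 about z, offset along x -> flipped
  tab2 <- particle_table(data.frame(x = 0, y = 0, z = 0,
                                    rot = 180, tilt = 0, psi = 0))
  out2 <- recenter_to_tag_site(tab2, c(129, 0, 0))
  expect_equal(unname(particle_positions(out2)[1, ]), c(-129, 0, 0),
               tolerance = 1e-10)

  # displacement norm is |offset| for any orientation
  set.seed(31)
  many <- particle_table(data.frame(
    x = runif(100, -500, 500), y = runif(100, -500, 500),
    z = runif(100, -500, 500),
    rot = runif(100, 0, 360), tilt = runif(100, 0, 180),
    psi = runif(100, 0, 360)))
  rec <- recenter_to_tag_site(many, c(40, -70, 129))
  disp <- particle_positions(rec) - particle_positions(many)
  expect_equal(sqrt(rowSums(disp^2)),
               rep(sqrt(sum(c(40, -70, 129)^2)), 100), tolerance = 1e-9,
               ignore_attr = TRUE)
  # orientations unchanged
  expect_identical(as.data.frame(rec)[, c("rot", "tilt", "psi")],
                   as.data.frame(many)[, c("rot", "tilt", "psi")])
})

test_that("euler_zyz_matrix is a proper ZYZ intrinsic rotation", {
  R <- euler_zyz_matrix(37, 101, -44)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # tilt alone rotates about y: z-axis -> (sin t, 0, cos t)
  expect_equal(as.numeric(euler_zyz_matrix(0, 90, 0) %*% c(0, 0, 1)),
               c(1, 0, 0), tolerance = 1e-12)
  # rot is applied extrinsically last: offset along z is invariant to psi
  expect_equal(as.numeric(euler_zyz_matrix(0, 0, 123) %*% c(0, 0, 5)),
               c(0, 0, 5), tolerance = 1e-12)
})

test_that("min_pairwise_distances equals the brute-force matrix minimum", {
  expect_equal(min_pairwise_distances(matrix(c(0, 0, 0), 1),
                                      rbind(c(30, 40, 0), c(100, 0, 0))),
               5)   # 3-4-5 triangle, in nm
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(min_pairwise_distances(pts, pts), rep(0, 10))

  set.seed(17)
  sites <- matrix(runif(150, 0, 2000), 50, 3)
  golds <- matrix(runif(240, 0, 2000), 80, 3)
  brute <- vapply(seq_len(50), function(i)
    min(vapply(seq_len(80), function(j)
      sqrt(sum((sites[i, ] - golds[j, ])^2)), numeric(1))) / 10,
    numeric(1))
  expect_equal(min_pairwise_distances(sites, golds), brute,
               tolerance = 1e-10)
  expect_error(min_pairwise_distances(sites, matrix(numeric(), 0, 3)),
               "empty|no gold")
})

test_that("WLC end-to-end distance has the right limits", {
  lp <- 4
  # flexible-chain asymptote at L = 100 lp
  expect_equal(wlc_rms_end_to_end(100 * lp, lp), sqrt(2 * lp * 100 * lp),
               tolerance = 0.01)
  # exact value at L = lp: lp * sqrt(2/e)
  expect_equal(wlc_rms_end_to_end(lp, lp), lp * sqrt(2 / exp(1)),
               tolerance = 1e-12)
  # L -> 0 limit is 0 (series: <R^2> -> L^2)
  expect_lt(wlc_rms_end_to_end(1e-4, lp), 1.1e-4)
  expect_error(wlc_rms_end_to_end(-1, lp), "positive")
  expect_error(wlc_rms_end_to_end(10, 0), "positive")
})

test_that("max_tether_distance: adopted cutoff or full extension", {
  expect_equal(max_tether_distance(tether_model()), 100)
  m <- tether_model(n_flexible_residues = 0.001, rigid_extension = 58,
                    max_distance = NULL)
  expect_equal(max_tether_distance(m), 58, tolerance = 0.01)
  m2 <- tether_model(n_flexible_residues = 25, rigid_extension = 58,
                     max_distance = NULL)
  expect_equal(max_tether_distance(m2), 25 * 3.8 + 58)  # 153: beyond cutoff
  expect_error(tether_model(n_flexible_residues = 100, max_distance = 10),
               "max_distance")
})

test_that("classify_bound and labeling_efficiency behave as stated", {
  expect_identical(classify_bound(c(2, 9.9, 10.1), 10),
                   c(TRUE, TRUE, FALSE))
  expect_identical(classify_bound(c(1, 2, 3), 0), rep(FALSE, 3))
  expect_identical(classify_bound(c(1, 2, 3), Inf), rep(TRUE, 3))

  eff <- labeling_efficiency(9567, 13748 - 9567)
  # 9567/13748 = 0.69588...; the reported 0.695 truncates the 3rd decimal
  expect_equal(eff$efficiency, 9567 / 13748)
  expect_equal(floor(eff$efficiency * 1e3) / 1e3, 0.695)
  expect_equal(labeling_efficiency(0, 5)$efficiency, 0)
  expect_equal(labeling_efficiency(5, 0)$efficiency, 1)
  expect_error(labeling_efficiency(0, 0), "denominator")
  # scale-free
  expect_equal(labeling_efficiency(30, 70)$efficiency,
               labeling_efficiency(3000, 7000)$efficiency)
})

test_that("distance_summary reports sample mean/SD (n-1)", {
  s <- distance_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  expect_error(distance_summary(5), "at least two")

  set.seed(55)
  draws <- rnorm(1e4, 5.1, 1.9)
  s2 <- distance_summary(draws)
  expect_lt(abs(s2$mean - 5.1), 3 * 1.9 / sqrt(1e4))
  expect_lt(abs(s2$sd - 1.9), 0.06)
})

test_that("efficiency_pipeline composes distances, classification, counts", {
  set.seed(77)
  sites <- matrix(runif(60, 0, 5000), 20, 3)
  # golds exactly at the sites
  res <- efficiency_pipeline(sites, sites, cutoff_nm = 10)
  expect_equal(res$efficiency$efficiency, 1)
  expect_equal(res$unbound_gold_fraction, 0)
  expect_equal(res$summary$mean, 0, tolerance = 1e-5)

  # golds far from every site
  far <- sites + 5000
  res2 <- efficiency_pipeline(sites, far, cutoff_nm = 10)
  expect_equal(res2$efficiency$efficiency, 0)
  expect_equal(res2$unbound_gold_fraction, 1)
  expect_null(res2$summary)

  # half the sites have a gold 30 Å away
  golds <- sites[1:10, ] + matrix(rep(c(30, 0, 0), each = 10), 10, 3)
  res3 <- efficiency_pipeline(sites, golds, cutoff_nm = 10)
  expect_equal(res3$efficiency$n_labeled, 10L)
  expect_equal(res3$efficiency$efficiency, 0.5)
  expect_equal(res3$summary$mean, 3)   # nm
})

test_that("exclusive assignment stops one gold labeling two sites", {
  sites <- rbind(c(0, 0, 0), c(40, 0, 0))
  gold <- matrix(c(20, 0, 0), 1)
  shared <- efficiency_pipeline(sites, gold, cutoff_nm = 10)
  expect_equal(shared$efficiency$n_labeled, 2L)
  excl <- efficiency_pipeline(sites, gold, cutoff_nm = 10, exclusive = TRUE)
  expect_equal(excl$efficiency$n_labeled, 1L)
})

test_that("efficiency report serializes to JSON and CSV", {
  set.seed(78)
  sites <- matrix(runif(30, 0, 500), 10, 3)
  res <- efficiency_pipeline(sites, sites + 10, cutoff_nm = 10)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_efficiency_report(res, jp, csv_path = cp)
  rep <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(rep$efficiency, res$efficiency$efficiency)
  expect_equal(nrow(read.csv(cp)), 10L)
})
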