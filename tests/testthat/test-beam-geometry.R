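test_that("PTV centroid equals brute-force enumeration", {
  g <- voxel_grid(c(10, 11, 12), spacing = c(2, 3, 4), origin = c(-5, 0, 7))
  m <- array(FALSE, g$shape); m[4, 5, 6] <- TRUE
  expect_equal(ptv_centroid(m, g), g$origin + c(3, 4, 5) * g$spacing,
               ignore_attr = TRUE)

  m2 <- array(FALSE, g$shape); m2[3:6, 2:5, 4:9] <- TRUE
  expect_equal(ptv_centroid(m2, g),
               g$origin + c(mean(2:5), mean(1:4), mean(3:8)) * g$spacing,
               ignore_attr = TRUE)

  set.seed(7)
  m3 <- array(FALSE, g$shape)
  m3[sample(prod(g$shape), 50)] <- TRUE
  expect_equal(ptv_centroid(m3, g), colMeans(voxel_centers(g, m3)),
               ignore_attr = TRUE)

  expect_error(ptv_centroid(array(FALSE, g$shape), g), "empty")
})

test_that("BEV projection obeys the similar-triangles closed forms", {
  iso <- c(10, 20, 30)
  # isocenter projects to the origin for any angles
  for (ang in list(c(0, 0), c(300, 10), c(123, 345)))
    expect_equal(as.numeric(bev_project(iso, ang[1], ang[2], iso)), c(0, 0))

  # a point on the isocenter plane is fixed (collimator 0)
  p <- iso + c(7, 0, -3)   # gantry 0: plane through iso is spanned by x and z
  expect_equal(as.numeric(bev_project(p, 0, 0, iso)), c(7, -3))

  # 50 mm upstream with 10 mm lateral offset magnifies by 1000/950
  p2 <- iso + c(10, -50, 0)  # gantry 0: source is anterior (-y), upstream = -y
  expect_equal(as.numeric(bev_project(p2, 0, 0, iso)),
               c(10 * 1000 / 950, 0), tolerance = 1e-12)

  # collimator rotation rotates the in-plane coordinates
  q0 <- bev_project(p, 0, 0, iso)
  q90 <- bev_project(p, 0, 90, iso)
  expect_equal(as.numeric(q90), c(q0[2], -q0[1]), tolerance = 1e-12)

  # a point at the source is rejected
  expect_error(bev_project(iso + 1000 * c(0, -1, 0), 0, 0, iso), "source")
})

test_that("jaw fitting matches a brute-force min/max scan", {
  expect_equal(unname(fit_jaws(matrix(c(3, -2), 1))), c(3, 3, -2, -2))
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(jaw_area(fit_jaws(sq)), 1)
  set.seed(11)
  pts <- cbind(rnorm(200, sd = 40), rnorm(200, sd = 25))
  j <- fit_jaws(pts, margin_mm = 2)
  expect_equal(unname(j), c(min(pts[, 1]) - 2, max(pts[, 1]) + 2,
                            min(pts[, 2]) - 2, max(pts[, 2]) + 2))
  expect_error(fit_jaws(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("angle search is exhaustive, minimal, and wrap-consistent", {
  ph <- coarse_phantom("medium", seed = 2)
  ptv <- get_mask(ph$structures, "PTV")
  iso <- ptv_centroid(ptv, ph$grid)
  s <- search_tangential_angles(ptv, ph$grid, iso)

  expect_equal(nrow(s$trace), 2 * 61 * 61)
  tr1 <- s$trace[s$trace$field == "F1", ]
  expect_equal(nrow(tr1), 3721)

  # the returned pair attains the trace minimum and beats the conventional pair
  expect_equal(s$f1$area, min(tr1$area))
  conv <- tr1$area[tr1$gantry == 300 & tr1$collimator == 0]
  expect_lte(s$f1$area, conv)

  # trace argmin equals the returned pair
  best <- tr1[which.min(tr1$area), ]
  expect_equal(s$f1$area, best$area)

  # collimator wrap: area at 0 equals area at 360 by direct re-evaluation
  pts <- voxel_centers(ph$grid, mask_surface(ptv))
  a0 <- jaw_area(fit_jaws(bev_project(pts, s$f1$gantry, 0, iso)))
  a360 <- jaw_area(fit_jaws(bev_project(pts, s$f1$gantry, 360, iso)))
  expect_equal(a0, a360, tolerance = 1e-12)
})

test_that("opposed-field symmetry holds for a centrally symmetric target", {
  # a mask invariant under a 180-degree rotation about the SI axis through its
  # centre makes the F2 problem the rotated image of the F1 problem, so
  # g2 = g1 + 180 and c2 = -c1 (mod 360)
  g <- voxel_grid(c(40, 40, 20), spacing = c(4, 4, 4))
  cc <- axis_coords(g)
  ctr <- g$origin + (g$shape - 1) * g$spacing / 2
  q <- array(0, g$shape)
  semi <- c(45, 28, 20)
  frame <- rbind(c(cos(0.3), sin(0.3), 0), c(-sin(0.3), cos(0.3), 0), c(0, 0, 1))
  for (a in 1:3) {
    ua <- outer(outer((cc[[1]] - ctr[1]) * frame[a, 1],
                      (cc[[2]] - ctr[2]) * frame[a, 2], `+`),
                (cc[[3]] - ctr[3]) * frame[a, 3], `+`)
    q <- q + (ua / semi[a])^2
  }
  mask <- q <= 1
  s <- search_tangential_angles(mask, g, ptv_centroid(mask, g))
  expect_equal((s$f1$gantry + 180) %% 360, s$f2$gantry %% 360)
  expect_equal((-s$f1$collimator) %% 360, s$f2$collimator %% 360)
  expect_equal(s$f1$area, s$f2$area, tolerance = 1e-9)
})

test_that("six fields follow the fixed angle offsets and the inner-jaw rule", {
  ph <- coarse_phantom("medium", seed = 2)
  ptv <- get_mask(ph$structures, "PTV")
  iso <- ptv_centroid(ptv, ph$grid)
  f1 <- list(gantry = 300, collimator = 10)
  f2 <- list(gantry = 120, collimator = 350)
  fl <- build_fields(f1, f2, ptv, ph$grid, iso)

  expect_named(fl, c("F1", "F2", "F3", "F4", "F5", "F6"))
  expect_equal(fl$F3$gantry_deg, 315)
  expect_equal(fl$F4$gantry_deg, 330)
  expect_equal(fl$F5$gantry_deg, 345)
  expect_equal(fl$F6$gantry_deg, 105)
  for (nm in c("F3", "F4", "F5")) expect_equal(fl[[nm]]$collimator_deg, 10)
  expect_equal(fl$F6$collimator_deg, 350)
  expect_equal(vapply(fl, `[[`, character(1), "role"),
               c(F1 = "major", F2 = "major", F3 = "minor", F4 = "minor",
                 F5 = "minor", F6 = "minor"))

  # modular wrap of minor gantry angles
  fl2 <- suppressWarnings(
    build_fields(list(gantry = 350, collimator = 0), f2, ptv, ph$grid, iso))
  expect_equal(fl2$F3$gantry_deg, 5)

  # the inner X jaw of each minor field sits 15 mm from the isocenter
  # projection, which here trims the deep edge relative to the full PTV fit
  pts <- voxel_centers(ph$grid, mask_surface(ptv))
  for (nm in c("F3", "F4", "F5", "F6")) {
    f <- fl[[nm]]
    full <- fit_jaws(bev_project(pts, f$gantry_deg, f$collimator_deg, iso))
    probe <- bev_project(iso + c(0, 100, 0), f$gantry_deg, f$collimator_deg, iso)
    if (probe[1, 1] >= 0) {
      expect_equal(f$jaws_mm[["X2"]], 15)
      expect_equal(f$jaws_mm[["X1"]], full[["X1"]])
    } else {
      expect_equal(f$jaws_mm[["X1"]], -15)
      expect_equal(f$jaws_mm[["X2"]], full[["X2"]])
    }
    expect_lte(jaw_area(f$jaws_mm), jaw_area(full) + 1e-9)
  }
})
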