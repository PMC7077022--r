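test_that("phantom CTV volumes land in their size class and are deterministic", {
  g <- coarse_grid()
  small <- generate_phantom("small", seed = 1, grid = g)
  large <- generate_phantom("large", seed = 7, grid = g)
  expect_lt(small$provenance$ctv_volume_ml, 300)
  expect_gt(large$provenance$ctv_volume_ml, 600)
  # within +/-10% of the class target
  expect_lt(abs(small$provenance$ctv_volume_ml - 200) / 200, 0.10)
  expect_lt(abs(large$provenance$ctv_volume_ml - 800) / 800, 0.10)

  again <- generate_phantom("small", seed = 1, grid = g)
  for (nm in names(small$structures$masks))
    expect_identical(small$structures$masks[[nm]], again$structures$masks[[nm]])

  expect_error(generate_phantom("huge", seed = 1, grid = g))
})

test_that("phantom masks are pairwise disjoint except CTV inside Body", {
  ph <- coarse_phantom("large", seed = 7)
  m <- ph$structures$masks
  ctv <- m$CTV
  expect_true(all(m$Body[ctv]))          # CTV subset of Body
  oars <- c("LungIpsi", "LungContra", "Heart", "BreastContra")
  for (a in oars) expect_false(any(m[[a]] & ctv))
  for (i in seq_along(oars)) for (j in seq_along(oars)) if (i < j)
    expect_false(any(m[[oars[i]]] & m[[oars[j]]]))
  # all structures live inside the body
  for (a in oars) expect_true(all(m$Body[m[[a]]]))
})

test_that("PTV expansion matches the digitized-ball oracle on a point CTV", {
  g <- voxel_grid(c(15, 15, 15), spacing = c(1, 1, 1))
  ctv <- array(FALSE, g$shape); ctv[8, 8, 8] <- TRUE
  body <- array(TRUE, g$shape)
  ptv <- expand_to_ptv(ctv, body, g, margin_mm = 5, skin_crop_mm = 0)
  # brute-force enumeration of voxel centres within 5 mm
  ctr <- voxel_centers(g, ctv)[1, ]
  d2 <- rowSums(sweep(voxel_centers(g), 2, ctr)^2)
  expect_identical(sum(ptv), sum(d2 <= 25 + 1e-9))
  expect_identical(which(ptv), which(array(d2 <= 25 + 1e-9, g$shape)))
})

test_that("PTV respects the 4 mm skin crop and the identity case", {
  ph <- coarse_phantom("medium", seed = 3)
  g <- ph$grid
  body <- get_mask(ph$structures, "Body")
  ptv <- get_mask(ph$structures, "PTV")
  # distance from every PTV voxel centre to the nearest non-body voxel centre
  out_pts <- voxel_centers(g, !body)
  ptv_pts <- voxel_centers(g, ptv)
  mind <- vapply(seq_len(nrow(ptv_pts)), function(r)
    sqrt(min(colSums((t(out_pts) - ptv_pts[r, ])^2))), numeric(1))
  expect_true(all(mind >= 4 - 1e-9))

  # margin 0 and crop 0 on an interior CTV is the identity
  ctv <- get_mask(ph$structures, "CTV")
  expect_identical(expand_to_ptv(ctv, body, g, margin_mm = 0, skin_crop_mm = 0), ctv)

  expect_error(expand_to_ptv(array(FALSE, g$shape), body, g), "empty")
  expect_error(expand_to_ptv(body, ctv | FALSE, g), "outside")
})

test_that("PTV expansion is monotone in the CTV", {
  g <- voxel_grid(c(12, 12, 12), spacing = c(2, 2, 2))
  body <- array(TRUE, g$shape)
  set.seed(42)
  for (rep in 1:5) {
    a <- array(runif(prod(g$shape)) < 0.08, g$shape)
    a[6, 6, 6] <- TRUE
    b <- a | array(runif(prod(g$shape)) < 0.05, g$shape)
    pa <- expand_to_ptv(a, body, g, margin_mm = 4, skin_crop_mm = 0)
    pb <- expand_to_ptv(b, body, g, margin_mm = 4, skin_crop_mm = 0)
    expect_true(all(pb[pa]))
  }
})

test_that("rings match brute-force set construction and stay disjoint", {
  g <- voxel_grid(c(20, 30, 10), spacing = c(1, 1, 1))
  body <- array(TRUE, g$shape)
  ptv <- array(FALSE, g$shape); ptv[8:13, 5:10, 4:7] <- TRUE
  r <- make_rings(ptv, body, g, ring1_extent_mm = 10, ring2_extent_mm = 20)
  # direct voxelwise oracle: posterior translates by 1..10 and 11..20 voxels
  acc <- function(shifts) {
    out <- array(FALSE, g$shape)
    for (s in shifts) {
      sh <- array(FALSE, g$shape)
      sh[, (1 + s):30, ] <- ptv[, 1:(30 - s), ]
      out <- out | sh
    }
    out
  }
  exp1 <- acc(1:10) & !ptv
  exp2 <- acc(11:20) & !ptv & !exp1
  expect_identical(r$Ring_1, exp1)
  expect_identical(r$Ring_2, exp2)
  expect_false(any(r$Ring_1 & ptv))
  expect_false(any(r$Ring_2 & ptv))
  expect_false(any(r$Ring_1 & r$Ring_2))

  # degenerate: PTV occupying the full posterior extent leaves empty rings
  ptv2 <- array(FALSE, g$shape); ptv2[8:13, 11:30, 4:7] <- TRUE
  r2 <- make_rings(ptv2, body, g, 10, 20)
  expect_identical(sum(r2$Ring_1), 0L)
  expect_identical(sum(r2$Ring_2), 0L)

  expect_error(make_rings(ptv, body, g, 20, 10))
  expect_error(make_rings(ptv, body, g, -5, 20))
})

test_that("phantom volumes are stable under voxel-size refinement", {
  vol_coarse <- coarse_phantom("medium", seed = 5)$provenance$ctv_volume_ml
  fine <- generate_phantom("medium", seed = 5,
                           grid = voxel_grid(c(96, 76, 44), spacing = c(4, 4, 3)))
  expect_lt(abs(fine$provenance$ctv_volume_ml - vol_coarse) / vol_coarse, 0.02)
})

test_that("size classification uses the 300/600 ml cutoffs", {
  expect_identical(classify_ctv_volume(299.9), "small")
  expect_identical(classify_ctv_volume(300), "medium")
  expect_identical(classify_ctv_volume(600), "medium")
  expect_identical(classify_ctv_volume(600.1), "large")
})
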