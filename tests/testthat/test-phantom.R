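test_that("atlas construction places every required region, disjoint and inside the brain", {
  atl <- build_atlas(c(64, 64, 40))
  required <- c("cortex", "middle_frontal", "middle_temporal", "insula",
                "hippocampus", "amygdala", "thalamus", "putamen", "caudate")
  counts <- table(atl$labels)
  for (r in required) {
    labs <- match_regions(atl, r)
    expect_true(length(labs) >= 1)
    for (l in labs) expect_gte(counts[[as.character(l)]], 8)
  }
  # labels are mutually exclusive by construction; check the hippocampus
  # centroid sits inside the brain mask
  hip <- which(array(atl$labels %in% match_regions(atl, "hippocampus"), atl$dims),
               arr.ind = TRUE)
  cen <- round(colMeans(hip))
  expect_true(brain_mask(atl)[cen[1], cen[2], cen[3]])
  # lateral symmetry of paired region sizes
  expect_equal(sum(atl$labels == match_regions(atl, "putamen")[1]),
               sum(atl$labels == match_regions(atl, "putamen")[2]))
  expect_error(build_atlas(c(8, 8, 8)), "too small")
})

test_that("phantom regional means follow the effect map", {
  atl <- build_atlas(c(32, 32, 20))
  hip <- array(atl$labels %in% match_regions(atl, "hippocampus"), atl$dims)
  base <- default_region_means()[["hippocampus"]]

  set.seed(11)
  ctrl <- replicate(100, mean(make_phantom(atl, "control",
                                           c(hippocampus = 0.3))[hip]))
  ad <- replicate(100, mean(make_phantom(atl, "ad", c(hippocampus = 0.3))[hip]))
  # control unaffected; ad mean reduced by the effect, within 3 SE
  se <- sd(ctrl) / sqrt(length(ctrl))
  expect_lt(abs(mean(ctrl) - base), 3 * se)
  se_ad <- sd(ad) / sqrt(length(ad))
  expect_lt(abs(mean(ad) - 0.7 * base), 3 * se_ad)

  # empty effect map: classes share the same generative law
  set.seed(12)
  a <- make_phantom(atl, "control")
  b <- make_phantom(atl, "ad")
  expect_equal(sum(a > 0), sum(b > 0))
})

test_that("degradation model: identity, blur mass preservation, noise scale", {
  atl <- build_atlas(c(32, 32, 20))
  set.seed(5)
  ph <- make_phantom(atl, "control")

  ident <- degrade_volume(ph, scanner_profile("id", 0, 0, 20))
  expect_equal(as.numeric(ident), as.numeric(ph))

  blur <- degrade_volume(ph, scanner_profile("b", 2, 0, 20))
  slice_in <- apply(ph, 3, sum)
  slice_out <- apply(blur, 3, sum)
  expect_lt(max(abs(slice_out - slice_in) / pmax(slice_in, 1)), 0.02)

  set.seed(6)
  noisy <- degrade_volume(ph, scanner_profile("n", 0, 0.1, 20))
  mask <- ph > 0 & noisy > 0  # avoid clipped voxels
  ratio <- sd((noisy - ph)[mask]) / (0.1 * mean(ph[ph > 0]))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("slice decimation re-expands onto the atlas grid", {
  set.seed(9)
  v <- random_volume(c(8, 8, 20))
  dec <- degrade_volume(v, scanner_profile("d", 0, 0, 10))
  expect_equal(dim(dec)[3], 10)
  back <- expand_slices(dec, 20)
  expect_equal(dim(back)[3], 20)
  kept <- round(seq(1, 20, length.out = 10))
  expect_equal(back[, , kept], v[, , kept])
})

test_that("cohort generation is seed-deterministic with correct composition", {
  spec <- cohort_spec(n_control = 6, n_ad = 3, dims = c(16, 16, 12), seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_equal(nrow(m1), 9)
  expect_equal(sum(m1$label == "control"), 6)
  v1 <- read_volume(m1$volume[1]); v2 <- read_volume(m2$volume[1])
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_identical(m1[c("id", "label", "scanner")], m2[c("id", "label", "scanner")])

  spec3 <- cohort_spec(n_control = 6, n_ad = 3, dims = c(16, 16, 12), seed = 43)
  d3 <- withr::local_tempdir()
  m3 <- generate_cohort(spec3, d3)
  v3 <- read_volume(m3$volume[1])
  expect_false(identical(as.numeric(v1), as.numeric(v3)))
})

test_that("degrading with blur then noise matches joint degradation in distribution", {
  atl <- build_atlas(c(24, 24, 16))
  set.seed(31)
  ph <- make_phantom(atl, "control")
  mask <- ph > 0
  joint <- two_step <- NULL
  for (r in 1:30) {
    j <- degrade_volume(ph, scanner_profile("j", 1.5, 0.08, 16))
    b <- degrade_volume(ph, scanner_profile("b", 1.5, 0, 16))
    s <- degrade_volume(b, scanner_profile("s", 0, 0.08 * mean(ph[mask]) / mean(b[b > 0]), 16))
    joint <- rbind(joint, c(mean(j[mask]), sd(j[mask])))
    two_step <- rbind(two_step, c(mean(s[mask]), sd(s[mask])))
  }
  expect_lt(abs(mean(joint[, 1]) - mean(two_step[, 1])) / mean(joint[, 1]), 0.02)
  expect_lt(abs(mean(joint[, 2]) - mean(two_step[, 2])) / mean(joint[, 2]), 0.05)
})
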