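test_that("nested parcellation partitions voxels with exact nesting maps", {
  cfg <- small_cfg(n_voxels = 1000L, n_regions = 10L, n_frsn = 4L, n_crsn = 2L)
  parc <- make_nested_parcellation(cfg, seed = 3)
  expect_equal(length(parc$region), 1000L)
  expect_equal(sort(unique(parc$region)), 1:10)
  expect_equal(sum(tabulate(parc$region)), 1000L)
  # each region maps to exactly one fRSN, each fRSN to one cRSN
  expect_equal(anyDuplicated(parc$labels$label), 0L)
  frsn_of <- tapply(parc$labels$frsn, parc$labels$label, unique)
  expect_true(all(lengths(frsn_of) == 1L))
  crsn_of <- tapply(parc$labels$crsn, parc$labels$frsn, unique)
  expect_true(all(lengths(crsn_of) == 1L))
  expect_equal(length(unique(parc$labels$frsn)), 4L)
  expect_equal(length(unique(parc$labels$crsn)), 2L)
  # regions are contiguous blobs: every region's voxels connect through
  # face-adjacent neighbors
  coords <- arrayInd(parc$mask$idx, parc$mask$dim)
  for (rg in unique(parc$region)) {
    xy <- coords[parc$region == rg, , drop = FALSE]
    n <- nrow(xy)
    if (n == 1L) next
    reached <- logical(n); reached[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      d <- abs(sweep(xy, 2, xy[frontier[1], ]))
      nb <- which(rowSums(d) == 1L & !reached)
      reached[nb] <- TRUE
      frontier <- c(frontier[-1], nb)
    }
    expect_true(all(reached), label = sprintf("region %d contiguous", rg))
  }
})

test_that("meta mask covers the configured fraction within one region's size", {
  cfg <- small_cfg(n_voxels = 1000L, n_regions = 10L, n_frsn = 4L, n_crsn = 2L,
                   meta_frac = 0.30)
  parc <- make_nested_parcellation(cfg, seed = 7)
  max_region <- max(tabulate(parc$region))
  covered <- sum(parc$meta)
  expect_gte(covered, 0.30 * 1000 - max_region)
  expect_lte(covered, 0.30 * 1000 + max_region)
})

test_that("degenerate single-module parcellation collapses all scales", {
  cfg <- small_cfg(n_voxels = 50L, n_regions = 1L, n_frsn = 1L, n_crsn = 1L)
  parc <- make_nested_parcellation(cfg, seed = 1)
  expect_true(all(parc$region == 1L))
  expect_equal(unique(parc$labels$frsn), "F01")
  expect_equal(unique(parc$labels$crsn), "C01")
  expect_error(make_nested_parcellation(
    small_cfg(n_voxels = 5L, n_regions = 10L, n_frsn = 2L, n_crsn = 1L)),
    "fewer voxels")
})

test_that("zero-coefficient, zero-noise generator produces constant ratings", {
  cfg <- small_cfg(n_voxels = 100L, n_regions = 4L, n_frsn = 2L, n_crsn = 1L,
                   b_temp = 0, b_exp = 0, b_social = 0, b_control = 0,
                   b_habit = 0, b_latent = 0, sd_intercept = 0, sd_noise = 0,
                   studies = small_design(1L, 4L, 8L))
  parc <- make_nested_parcellation(cfg, seed = 1)
  sim <- simulate_multistudy(cfg, parc, seed = 1)
  expect_lt(diff(range(sim$datasets[[1]]$meta$rating)), 1e-10)
})

test_that("OLS on generated ratings recovers the configured coefficients", {
  st <- small_design(1L, 40L, 60L)
  cfg <- small_cfg(studies = st, n_voxels = 100L, n_regions = 4L,
                   n_frsn = 2L, n_crsn = 1L)
  parc <- make_nested_parcellation(cfg, seed = 2)
  sim <- simulate_multistudy(cfg, parc, seed = 2)
  ds <- sim$datasets[[1]]
  z <- as.vector(scale(ds$meta$rating))
  temp <- as.vector(scale(ds$meta$temperature))
  hab <- as.vector(scale(ds$meta$trial_index))
  fit <- lm(z ~ temp + expectation + hab + factor(participant_id),
            data = cbind(ds$meta, temp = temp, hab = hab, z = z))
  sm <- summary(fit)$coefficients
  # closed-form oracle for the rating-z SD implied by the configured
  # variance components (temperature, expectation, habituation active):
  b <- cfg$b[c("temperature", "expectation", "habituation")]
  sd_z <- sqrt(sum(b^2) + cfg$b_latent^2 + cfg$sd_intercept^2 + cfg$sd_noise^2)
  truth <- b / sd_z
  for (i in seq_along(truth)) {
    nm <- c("temp", "expectation", "hab")[i]
    expect_lt(abs(sm[nm, "Estimate"] - truth[i]), 3 * sm[nm, "Std. Error"])
  }
})

test_that("LOCAL scenario confines every pattern to the designated region", {
  w <- small_world(seed = 4, scenario = "LOCAL")
  gt <- w$sim$ground_truth
  expect_length(gt$signal_regions, 1L)
  outside <- which(!(w$parc$region %in% gt$signal_regions))
  expect_true(all(gt$patterns[outside, ] == 0))
  expect_true(all(gt$pattern_pain[outside] == 0))
  expect_gt(sum(gt$pattern_pain != 0), 0)
})

test_that("MULTISYSTEM and GLOBAL scenarios satisfy their scope invariants", {
  w <- small_world(seed = 1, scenario = "MULTISYSTEM")
  gt <- w$sim$ground_truth
  expect_gte(length(gt$signal_regions), 3L)
  crsn <- unique(w$parc$labels$crsn[w$parc$labels$label %in% gt$signal_regions])
  expect_gte(length(crsn), 2L)
  cfg_g <- small_cfg(scenario = "GLOBAL", studies = small_design(1L, 4L, 8L))
  parc_g <- make_nested_parcellation(cfg_g, seed = 2)
  sim_g <- simulate_multistudy(cfg_g, parc_g, seed = 2)
  expect_gte(length(sim_g$ground_truth$signal_regions), 6L)  # >= 50% of 12
})

test_that("specificity map generator yields labeled maps with amplitude order", {
  w <- small_world(seed = 1)
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 3, n_per_task = 5L)
  expect_equal(nrow(maps$maps), 18L * 5L)
  expect_equal(nrow(maps$info), 90L)
  expect_equal(sum(maps$info$category == "pain"), 30L)
  # dot-product oracle: projecting onto the true pain pattern orders the
  # modalities by their configured amplitudes
  proj <- as.vector(maps$maps %*% w$sim$ground_truth$pattern_pain)
  mh <- mean(proj[maps$info$modality %in% "heat"])
  mv <- mean(proj[maps$info$modality %in% "visceral"])
  mn <- mean(proj[maps$info$category != "pain"])
  expect_gt(mh, mv)
  expect_gt(mv, mn)
})

test_that("null-amplitude pain maps are exchangeable with non-pain maps", {
  w <- small_world(seed = 1)
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 5, n_per_task = 5L,
                                    pain_amp = c(heat = 0, mechanical = 0,
                                                 visceral = 0))
  proj <- as.vector(maps$maps %*% w$sim$ground_truth$pattern_pain)
  is_pain <- maps$info$category == "pain"
  obs <- mean(proj[is_pain]) - mean(proj[!is_pain])
  set.seed(1)
  null <- replicate(499, {
    sh <- sample(is_pain)
    mean(proj[sh]) - mean(proj[!sh])
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / 500
  expect_gt(p, 0.01)
})
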