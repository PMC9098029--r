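test_that("optimal cut point matches the exhaustive-scan oracle", {
  cp <- optimal_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(cp$threshold, 2.5)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  # perfectly separated
  cp2 <- optimal_cutpoint(c(rnorm(10), rnorm(10) + 100), rep(0:1, each = 10))
  expect_equal(cp2$sensitivity + cp2$specificity, 2)
  # degenerate: identical scores -> chance
  cp3 <- optimal_cutpoint(rep(1, 10), rep(0:1, 5))
  expect_equal(cp3$sensitivity + cp3$specificity, 1)
  expect_error(optimal_cutpoint(1:5, rep(1, 5)), "both classes")
  # random instances against a brute-force scan
  set.seed(13)
  for (i in 1:100) {
    s <- round(rnorm(30), 2)
    lab <- rbinom(30, 1, 0.5)
    if (all(lab == lab[1])) lab[1] <- 1 - lab[1]
    cp <- optimal_cutpoint(s, lab)
    u <- sort(unique(s))
    cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
              u[length(u)] + 1)
    stats <- t(vapply(cand, function(th)
      c(mean(s[lab == 1] >= th), mean(s[lab == 0] < th)), numeric(2)))
    gap <- abs(stats[, 1] - stats[, 2])
    best <- which(gap < min(gap) + 1e-12)
    best <- best[which.max(stats[best, 1] + stats[best, 2])]
    expect_equal(cp$sensitivity, stats[best, 1])
    expect_equal(cp$specificity, stats[best, 2])
    expect_equal(abs(cp$sensitivity - cp$specificity), gap[best],
                 tolerance = 1e-12)
  }
})

test_that("task maps are scored per model with standardization invariance", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg()
  models <- list(FULL = train_final(w$qd, w$spaces$FULL, cfgA, seed = 1),
                 META = train_final(w$qd, w$spaces$META, cfgA, seed = 1))
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 2, n_per_task = 3L)
  tab <- score_task_maps(models, maps)
  expect_equal(nrow(tab), 18L * 3L * 2L)
  expect_equal(sum(tab$model == "FULL"), 54L)
  # adding a constant to a map is removed by standardization
  maps2 <- maps; maps2$maps <- maps$maps + 7
  tab2 <- score_task_maps(models, maps2)
  expect_equal(tab$score, tab2$score, tolerance = 1e-8)
  # zero map scores the model intercept when not standardized
  zero <- list(maps = matrix(0, 1, ncol(maps$maps)), info = maps$info[1, ])
  s0 <- score_task_maps(models["FULL"], zero, standardize = FALSE)
  m <- models$FULL
  expect_equal(s0$score, m$b0 - sum(m$center * m$W), tolerance = 1e-10)
})

test_that("matching models score planted pain maps above non-pain maps", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg()
  models <- list(FULL = train_final(w$qd, w$spaces$FULL, cfgA, seed = 1))
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 3, n_per_task = 8L)
  tab <- score_task_maps(models, maps)
  expect_gt(mean(tab$score[tab$category == "pain"]),
            mean(tab$score[tab$category != "pain"]))
  disc <- pain_discrimination(tab)
  expect_gt(disc$sensitivity + disc$specificity, 1.2)
})

test_that("specificity contrasts estimate pain effects and null out shuffles", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg()
  models <- list(REGION = train_final(w$qd, w$spaces$REGION, cfgA, seed = 1),
                 FULL = train_final(w$qd, w$spaces$FULL, cfgA, seed = 1))
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 4, n_per_task = 15L)
  tab <- score_task_maps(models, maps)
  res <- specificity_contrasts(tab, distributed_models = "FULL")
  ct <- res$contrasts
  expect_gt(ct$estimate[ct$contrast == "pain_vs_nonpain"], 0)
  expect_lt(ct$p[ct$contrast == "pain_vs_nonpain"], 0.05)
  expect_gt(ct$estimate[ct$contrast == "heat_vs_other_pain"], 0)
  # shuffled categories: pain contrast should not reject at alpha ~ 0.05
  set.seed(5)
  rejections <- vapply(1:30, function(i) {
    sh <- tab
    relab <- setNames(sample(tapply(tab$category, tab$task, unique)),
                      unique(tab$task))
    sh$category <- relab[sh$task]
    r <- specificity_contrasts(sh, distributed_models = "FULL")
    r$contrasts$p[r$contrasts$contrast == "pain_vs_nonpain"] < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.2)
})

test_that("zero pain amplitude gives a pain contrast CI covering zero", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg()
  models <- list(FULL = train_final(w$qd, w$spaces$FULL, cfgA, seed = 1))
  maps <- simulate_specificity_maps(w$cfg, w$parc, w$sim$ground_truth,
                                    seed = 6, n_per_task = 8L,
                                    pain_amp = c(heat = 0, mechanical = 0,
                                                 visceral = 0))
  tab <- score_task_maps(models, maps)
  res <- specificity_contrasts(tab, distributed_models = "FULL")
  row <- res$contrasts[res$contrasts$contrast == "pain_vs_nonpain", ]
  ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})
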