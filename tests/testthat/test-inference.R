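test_that("Fisher transform evaluates, clips at the boundary, and inverts", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(1), atanh(1 - 1e-6))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-6))
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z(-r), -fisher_z(r))
})

test_that("participant performance averages repeats before correlating", {
  ps <- data.frame(row = rep(1:4, 2), repeat_ = rep(1:2, each = 4), fold = 1,
                   participant = "p1", study = "S1",
                   observed = rep(c(1, 2, 3, 4), 2),
                   predicted = c(1, 2, 3, 4, 4, 3, 2, 1))
  pf <- participant_performance(ps)
  # repeat-averaged predictions are constant -> undefined r, logged NA
  expect_true(is.na(pf$z))
  ps$predicted <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  pf <- participant_performance(ps)
  expect_equal(pf$r, 1)
  expect_equal(pf$z, atanh(1 - 1e-6))
  expect_equal(pf$n_points, 4L)
})

test_that("Sidak threshold matches its closed form", {
  expect_equal(sidak_alpha(0.05, 1), 0.05)
  expect_equal(sidak_alpha(0.05, 486), 1.0553618e-4, tolerance = 1e-6)
  expect_lt(sidak_alpha(0.05, 32), 0.05 / 31)  # tighter than near-Bonferroni
})

test_that("planned contrasts are pairwise orthogonal and code estimates directly", {
  L <- planned_contrasts()
  G <- L %*% t(L)
  expect_true(all(abs(G[lower.tri(G)]) < 1e-12))
  # coding identity: group means mu recover theta = L mu as coefficients
  mu <- c(REGION = 0.5, FRSN = 0.55, CRSN = 0.6, PATHWAYS = 0.8,
          META = 0.85, FULL = 0.9)
  spaces <- rep(names(mu), each = 4)
  codes <- painscales:::contrast_codes(spaces, L)
  fit <- lm(mu[spaces] ~ ., data = codes)
  expect_equal(unname(coef(fit)[-1]), unname(as.vector(L %*% mu)),
               tolerance = 1e-10)
})

test_that("identical performance columns give a zero contrast estimate", {
  pt <- simulate_performance_table(seed = 21)
  # force CRSN == FRSN exactly: C3 must estimate 0
  z_frsn <- pt$z[pt$space == "FRSN"]
  pt$z[pt$space == "CRSN"] <- z_frsn
  cs <- compare_spaces(pt, full_vs_region = FALSE)
  expect_lt(abs(cs$table$estimate[cs$table$contrast == "C3"]), 1e-8)
  expect_equal(nrow(cs$table), 5L)
  expect_true(all(cs$table$df2 > 0))
})

test_that("planted space differences are detected with correct sign and CI", {
  mu <- setNames(c(0.5, 0.5, 0.5, 0.8, 0.8, 0.8),
                 c("REGION", "FRSN", "CRSN", "PATHWAYS", "META", "FULL"))
  covered <- 0L; detected <- 0L
  n_sim <- 30L
  for (s in seq_len(n_sim)) {
    pt <- simulate_performance_table(space_means = mu, seed = 100 + s)
    cs <- compare_spaces(pt, full_vs_region = FALSE)
    row <- cs$table[cs$table$contrast == "C1", ]
    detected <- detected + (row$p < 0.05 && row$estimate > 0)
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df2) * row$se
    covered <- covered + (0.3 >= ci[1] && 0.3 <= ci[2])
  }
  expect_gte(detected, 0.8 * n_sim)
  expect_gte(covered, 0.8 * n_sim)
})

test_that("module screening controls the family-wise error under the null", {
  n_seeds <- 40L
  m <- 6L
  fams <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    preds <- lapply(seq_len(m), function(j) {
      pid <- rep(sprintf("s%d_p%02d", rep(1:2, each = 8), 1:16), each = 4)
      data.frame(row = rep(1:64), repeat_ = 1L, fold = 1L,
                 participant = pid, study = rep(c("A", "B"), each = 32),
                 observed = rnorm(64), predicted = rnorm(64))
    })
    names(preds) <- paste0("m", seq_len(m))
    any(screen_modules(preds, alpha = 0.05)$significant)
  }, TRUE)
  # family-wise false positive rate <= alpha (binomial 95% upper bound)
  expect_lte(mean(fams), 0.05 + 1.64 * sqrt(0.05 * 0.95 / n_seeds))
})

test_that("Bayes factors support true nulls, reject true effects, and feel replication", {
  mu0 <- setNames(rep(0.5, 6),
                  c("REGION", "FRSN", "CRSN", "PATHWAYS", "META", "FULL"))
  bf_null <- vapply(1:10, function(s)
    as.numeric(bayes_factor_null(simulate_performance_table(space_means = mu0,
                                                            seed = 300 + s),
                                 "C1")), 0)
  expect_gt(mean(bf_null > 10), 0.5)
  mu1 <- mu0 + c(0, 0, 0, 0.5, 0.5, 0.5)
  bf_eff <- vapply(1:10, function(s)
    as.numeric(bayes_factor_null(simulate_performance_table(space_means = mu1,
                                                            seed = 400 + s),
                                 "C1")), 0)
  expect_gte(mean(bf_eff < 1), 0.9)
  # pseudo-replication sanity: duplicating rows changes the BF
  pt <- simulate_performance_table(space_means = mu0, seed = 5)
  b1 <- as.numeric(bayes_factor_null(pt, "C1"))
  pt2 <- rbind(pt, transform(pt, participant = paste0(participant, "_dup")))
  class(pt2) <- class(pt)
  b2 <- as.numeric(bayes_factor_null(pt2, "C1"))
  expect_gt(abs(log(b2 / b1)), 0.1)
})

test_that("calibration intervals cover holdout studies from the same generator", {
  tr <- simulate_performance_table(seed = 31)
  cover <- vapply(1:60, function(s) {
    ho <- simulate_performance_table(n_studies = 2L, seed = 700 + s)
    mean(calibration_check(tr, ho)$covered)
  }, 0)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.995)
  # doubled study-level SD at holdout must undercover
  cover2 <- vapply(1:60, function(s) {
    ho <- simulate_performance_table(n_studies = 2L, sd_study = 0.45,
                                     sd_study_space = 0.3, seed = 900 + s)
    mean(calibration_check(tr, ho)$covered)
  }, 0)
  expect_lt(mean(cover2), mean(cover))
  # zero-variance generator collapses the interval width toward fixed-effect SE
  tr0 <- simulate_performance_table(sd_study = 0, sd_study_space = 0,
                                    sd_participant = 0, sd_noise = 1e-4,
                                    seed = 8)
  cc <- calibration_check(tr0, tr0[tr0$study == "s01", ])
  expect_lt(max(cc$upper - cc$lower), 0.01)
})
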