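test_that("full-rank PCR training predictions equal the OLS oracle", {
  set.seed(11)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- rnorm(50)
  fit <- fit_pcr(X, y, 10L)
  # normal-equation oracle
  Xc <- sweep(X, 2, colMeans(X))
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  oracle <- as.vector(Xc %*% beta) + mean(y)
  expect_lt(max(abs(predict(fit, X) - oracle)), 1e-8)
})

test_that("PCR handles exact fits, k = 0, and rank violations", {
  set.seed(2)
  c1 <- rnorm(30)
  X <- cbind(c1, matrix(0, 30, 4))
  y <- 2 * c1
  fit <- fit_pcr(X, y, 1L)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-10)
  expect_equal(fit$W[2:5], rep(0, 4))    # zero columns get zero weight
  expect_error(fit_pcr(X, y, 0L), "precluded")
  expect_error(fit_pcr(X, y, 3L), "rank")
})

test_that("prediction is affine in the image and zero images score the intercept", {
  set.seed(3)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rnorm(40)
  fit <- fit_pcr(X, y, 5L)
  x1 <- rnorm(15); x2 <- rnorm(15); a <- 0.3
  s <- predict(fit, rbind(x1, x2, a * x1 + (1 - a) * x2))
  expect_equal(s[3], a * s[1] + (1 - a) * s[2], tolerance = 1e-10)
  z <- predict(fit, matrix(0, 1, 15))
  expect_equal(z, fit$b0 - sum(fit$center * fit$W), tolerance = 1e-12)
  expect_equal(predict(fit, X), apply_model(fit, X), tolerance = 1e-12)
  expect_error(apply_model(fit, matrix(0, 2, 14)), "mismatch")
})

test_that("grid dimension optimization finds the oracle minimum", {
  set.seed(5)
  qd <- toy_qdata(n_participants = 20L, V = 25L, snr = 2)
  X <- qd$features; y <- qd$meta$rating
  foldid <- as.integer(factor(qd$meta$participant_id)) %% 5L + 1L
  k <- optimize_dims(X, y, foldid, opt_config("grid"))
  curve <- attr(k, "mse")
  expect_equal(curve[k], min(curve))
  # exhaustive re-fit oracle at a couple of k values
  for (kk in c(1L, 3L)) {
    sse <- 0
    for (f in 1:5) {
      tr <- foldid != f
      m <- fit_pcr(X[tr, ], y[tr], kk)
      sse <- sse + sum((y[!tr] - predict(m, X[!tr, , drop = FALSE]))^2)
    }
    expect_equal(curve[kk], sse / length(y), tolerance = 1e-10)
  }
})

test_that("bayesian dimension search lands within 5% of the grid minimum MSE", {
  set.seed(6)
  worst_ratio <- 0
  for (s in 1:5) {
    qd <- toy_qdata(n_participants = 15L, V = 40L, seed = s, snr = 1.5)
    X <- qd$features; y <- qd$meta$rating
    foldid <- as.integer(factor(qd$meta$participant_id)) %% 5L + 1L
    kb <- optimize_dims(X, y, foldid, opt_config("bayes", n_evals = 12L),
                        seed = s)
    curve <- attr(kb, "mse")
    worst_ratio <- max(worst_ratio, curve[kb] / min(curve))
  }
  expect_lt(worst_ratio, 1.05)
  # pure-noise outcome: still within 5% of grid minimum
  set.seed(7)
  X <- matrix(rnorm(60 * 30), 60, 30); y <- rnorm(60)
  foldid <- rep(1:5, each = 12)
  kb <- optimize_dims(X, y, foldid, opt_config("bayes", n_evals = 12L), seed = 2)
  curve <- attr(kb, "mse")
  expect_lt(curve[kb] / min(curve), 1.05)
  # R = 1 short-circuits
  X1 <- cbind(rnorm(20))
  expect_equal(as.integer(optimize_dims(X1, rnorm(20), rep(1:4, 5),
                                        opt_config("grid"))), 1L)
  expect_error(opt_config("bayes", n_evals = 1L), "n_evals")
})

test_that("module selection recovers a planted single-region signal", {
  w <- small_world(seed = 4, scenario = "LOCAL")
  cfgA <- fast_analysis_cfg()
  truth <- w$sim$ground_truth$signal_regions
  hits <- 0L
  for (s in 1:6) {
    rows <- which(w$qd$meta$study != "S3") # vary the data a little per seed
    sel <- select_module(qd_subset(w$qd, sample(rows)), w$spaces$REGION,
                         cfgA, seed = s)
    hits <- hits + (names(w$spaces$REGION$modules)[sel] == as.character(truth))
  }
  expect_gte(hits, 5L)
  # single-candidate spaces return unconditionally
  one <- model_space("CRSN", "modular", w$spaces$CRSN$modules[1])
  expect_equal(as.integer(select_module(w$qd, one, cfgA, seed = 1)), 1L)
})

test_that("null-data module selection is close to uniform over candidates", {
  n_cand <- 6L
  counts <- integer(n_cand)
  n_rep <- 120L
  for (s in seq_len(n_rep)) {
    qd <- toy_qdata(n_participants = 10L, V = n_cand * 6L, seed = 1000 + s,
                    signal_voxels = integer(0))
    sp <- model_space("REGION", "modular",
                      split(seq_len(n_cand * 6L), rep(seq_len(n_cand), each = 6L)))
    sel <- select_module(qd, sp, fast_analysis_cfg(), seed = s)
    counts[sel] <- counts[sel] + 1L
  }
  # binomial 99.9% bounds for p = 1/6 at n = 120
  p <- 1 / n_cand
  bound <- 3.29 * sqrt(p * (1 - p) * n_rep)
  expect_true(all(abs(counts - n_rep * p) < bound))
})

test_that("the CV scheme never fragments participants and balances studies", {
  w <- small_world(seed = 1)
  sch <- make_cv_scheme(w$qd$meta, repeats = 2L, folds = 5L, seed = 3L)
  for (r in 1:2) {
    foldid <- sch[, r]
    # one fold per participant
    expect_true(all(tapply(foldid, w$qd$meta$participant_id,
                           function(f) length(unique(f))) == 1L))
    # per study, fold participant counts differ by <= 1
    for (s in unique(w$qd$meta$study)) {
      cnt <- table(tapply(foldid[w$qd$meta$study == s],
                          w$qd$meta$participant_id[w$qd$meta$study == s], unique))
      expect_lte(diff(range(cnt)), 1L)
    }
  }
})

test_that("nested CV predicts every row once per repeat and stores choices", {
  qd <- toy_qdata(n_participants = 15L, V = 30L, snr = 1.5)
  sp <- model_space("FULL", "fixed", list(FULL = 1:30))
  ps <- nested_cv_predict(qd, sp, fast_analysis_cfg(), seed = 4)
  expect_equal(nrow(ps), 2L * nrow(qd$features))
  cnt <- table(ps$row, ps$repeat_)
  expect_true(all(cnt == 1L))
  expect_true(all(ps$k >= 1L))
  expect_identical(ps$observed, qd$meta$rating[ps$row])
})

test_that("frozen models reproduce in-sample fits and transfer generatively", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg()
  m <- train_final(w$qd, w$spaces$META, cfgA, seed = 2)
  X <- extract_features(w$qd, m$voxel_set)
  expect_equal(apply_model(m, w$qd), predict(m, X), tolerance = 1e-12)
  # holdout study from the same generator scores positively
  ho_cfg <- w$cfg
  ho_cfg$studies <- small_design(1L, 10L, 24L)
  ho_cfg$studies$study_id <- "HOLD"
  sim_ho <- simulate_multistudy(ho_cfg, w$parc, seed = 1)
  qd_ho <- preprocess_datasets(sim_ho$datasets)
  scores <- apply_model(m, qd_ho)
  z <- vapply(split(seq_len(nrow(qd_ho$meta)), qd_ho$meta$participant_id),
              function(ii) fisher_z(cor(scores[ii], qd_ho$meta$rating[ii])), 0)
  expect_gt(mean(z), 0.2)
})

test_that("multistudy and study-wise drivers produce complete performance tables", {
  w <- small_world(seed = 1)
  cfgA <- fast_analysis_cfg(balance_n = 10L)
  two <- w$spaces[c("CRSN", "META")]
  ms <- decode_multistudy(w$qd, two, cfgA, seed = 5)
  # balanced to 10 participants per study, one row per participant x space
  expect_equal(nrow(ms$performance), 2L * 3L * 10L)
  expect_setequal(unique(ms$performance$space), c("CRSN", "META"))
  expect_true(all(ms$performance$condition == "multistudy"))
  sw <- decode_studywise(w$qd, two["META"], cfgA, seed = 5)
  expect_equal(nrow(sw$performance), 3L * 12L)
  expect_true(all(sw$performance$condition == "studywise"))
  # each study-wise prediction set only contains its own study
  for (s in names(sw$predictions$META))
    expect_setequal(unique(sw$predictions$META[[s]]$study), s)
})
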