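test_that("outlier masking follows the 3-SD two-round rule", {
  tab <- data.frame(f = c(rep(0, 99), 100))
  out <- clean_outliers(tab, "f")
  expect_true(is.na(out$f[100]))
  expect_equal(sum(is.na(out$f)), 1)
  # standard normal: ~0.27% masked in round one
  set.seed(2)
  tab2 <- data.frame(f = rnorm(10000))
  out2 <- clean_outliers(tab2, "f", rounds = 1)
  expect_lt(abs(mean(is.na(out2$f)) - 0.0027), 0.002)
  # constant feature untouched
  tab3 <- clean_outliers(data.frame(f = rep(5, 50)), "f")
  expect_true(all(!is.na(tab3$f)))
})

test_that("age associations recover slopes, curvature and null FDR", {
  set.seed(5)
  n <- 300
  tab <- data.frame(age = runif(n, 3, 17),
                    sex = sample(c("F", "M"), n, TRUE),
                    race = sample(c("a", "b"), n, TRUE))
  tab$lin <- 2 * tab$age + rnorm(n)
  tab$quad <- (tab$age - 10)^2 + rnorm(n)
  tab$null1 <- rnorm(n); tab$null2 <- rnorm(n)
  aa <- fit_age_associations(tab, c("lin", "quad", "null1", "null2"))
  expect_equal(aa$beta[aa$feature == "lin"], 2, tolerance = 0.1)
  expect_lt(aa$fdr_q[aa$feature == "lin"], 0.05)
  expect_lt(aa$delta_bic[aa$feature == "quad"], 0)   # quadratic preferred
  expect_gt(aa$delta_bic[aa$feature == "lin"], 0)
  expect_true(all(aa$fdr_q >= aa$p))
  # BH monotone in p
  o <- order(aa$p)
  expect_true(all(diff(aa$fdr_q[o]) >= -1e-12))
})

test_that("feature pruning drops duplicates and near-duplicates in order", {
  set.seed(6)
  tab <- data.frame(a = rnorm(100))
  tab$b <- tab$a                                  # duplicate
  tab$c <- tab$a + rnorm(100, 0, 0.2)             # r ~ 0.98
  tab$d <- rnorm(100)                             # independent
  kept <- select_features(tab, c("a", "b", "c", "d"))
  expect_equal(kept, c("a", "d"))
  # independent features are all retained
  tab2 <- as.data.frame(matrix(rnorm(200 * 8), 200))
  expect_length(select_features(tab2, names(tab2)), 8)
})

test_that("brain-age model hits the normal-residual oracle on held-out data", {
  co <- simulate_cohort(n = 600, seed = 11)
  pool <- co$table
  set.seed(1)
  idx <- sample(nrow(pool), round(0.7 * nrow(pool)))
  m <- brainage(pool[idx, ], co$features, seed = 5)
  expect_gte(length(m$features), 20)      # pruning keeps an informative set
  held <- predict(m, pool[-idx, ])
  # residual SD 1 yr -> MAE = sqrt(2/pi) ~ 0.80
  expect_equal(attr(held, "mae"), 0.80, tolerance = 0.10)
  expect_lt(abs(attr(held, "me")), 0.1)
  expect_gt(attr(held, "r"), 0.9)
  expect_equal(attr(held, "me"), mean(held$gap))
  expect_gte(attr(held, "mae"), abs(attr(held, "me")))
  # missing feature named in prediction error
  expect_error(predict(m, pool[-idx, setdiff(names(pool), m$features[1])]),
               m$features[1])
})

test_that("pure-noise features cannot predict age", {
  set.seed(9)
  n <- 200
  tab <- data.frame(age = runif(n, 3, 17),
                    sex = sample(c("F", "M"), n, TRUE),
                    race = sample(c("a", "b"), n, TRUE))
  for (j in 1:10) tab[[paste0("f", j)]] <- rnorm(n)
  m <- brainage(tab, paste0("f", 1:10), seed = 2)
  expect_lte(m$cv$r2_mean, 0.05)
})

test_that("prediction is invariant to affine feature rescaling", {
  co <- simulate_cohort(n = 120, seed = 13)
  tab <- co$table
  m1 <- brainage(tab, co$features[1:10], prune = FALSE, seed = 3)
  tab2 <- tab
  tab2[[co$features[1]]] <- 100 + 7 * tab2[[co$features[1]]]
  m2 <- brainage(tab2, co$features[1:10], prune = FALSE, seed = 3)
  p1 <- predict(m1, tab)
  p2 <- predict(m2, tab2)
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-8)
})

test_that("a -2 yr delayed group shows the constructed brain-age gap", {
  co <- simulate_cohort(
    n = 400, seed = 21,
    groups = data.frame(group = "delayed", n = 50, trajectory_offset = -2))
  pool <- co$table[co$table$group == "non-NDD", ]
  grp <- co$table[co$table$group == "delayed", ]
  gap <- gap_group_analysis(pool, list(delayed = grp), co$features,
                            n_rounds = 10, seed = 4)
  expect_equal(gap$groups$me_mean, -2, tolerance = 0.3)
  expect_lt(gap$groups$median_p_me, 0.01)
  # single round: min = max = mean
  g1 <- gap_group_analysis(pool, list(delayed = grp), co$features,
                           n_rounds = 1, seed = 5)
  expect_equal(g1$groups$me_min, g1$groups$me_max)
  expect_equal(g1$groups$me_min, g1$groups$me_mean)
})

test_that("trajectory offset equals evaluating curves at a younger age", {
  co <- simulate_cohort(
    n = 20, seed = 31, subject_noise_sd = 0, feature_noise_frac = 0,
    groups = data.frame(group = "delayed", n = 20, trajectory_offset = -2))
  tab <- co$table
  tru <- co$true_features
  curves <- default_feature_curves()
  for (i in which(tab$group == "delayed")[1:5]) {
    expect_equal(unname(tru[i, "fs_density_c3"]),
                 curves$fs_density_c3(tab$age[i] - 2), tolerance = 1e-9)
    # with zero noise the observed features reproduce the curves
    expect_equal(tab$fs_density_c3[i], unname(tru[i, "fs_density_c3"]),
                 tolerance = 1e-9)
  }
})

test_that("group-difference models recover implanted effects", {
  set.seed(8)
  n <- 400
  tab <- data.frame(age = runif(n, 3, 17),
                    sex = sample(c("F", "M"), n, TRUE),
                    race = sample(c("a", "b"), n, TRUE),
                    grp = rep(c(TRUE, FALSE), c(60, n - 60)))
  tab$f_eff <- rnorm(n) - 1 * tab$grp            # -1 SD main effect
  tab$f_int <- tab$age * ifelse(tab$grp, -0.3, 0.3) + rnorm(n)
  tab$f_null <- rnorm(n)
  gd <- group_difference_models(tab, "grp", c("f_eff", "f_int", "f_null"))
  expect_equal(gd$beta_group[gd$feature == "f_eff"], -1, tolerance = 0.25)
  expect_lt(gd$q_group[gd$feature == "f_eff"], 0.05)
  expect_lt(gd$beta_interaction[gd$feature == "f_int"], 0)
  expect_lt(gd$q_interaction[gd$feature == "f_int"], 0.05)
  expect_gt(gd$p_group[gd$feature == "f_null"], 0.05)
  expect_error(group_difference_models(tab, "f_null_missing", "f_eff"))
})

test_that("similarity profile bottoms out at the shifted age bin", {
  co <- simulate_cohort(
    n = 500, age_range = c(2.5, 17.5), seed = 41,
    groups = data.frame(group = "delayed", n = 60, trajectory_offset = -2))
  comp <- co$table[co$table$group == "non-NDD", ]
  grp <- co$table[co$table$group == "delayed", ]
  ps <- profile_similarity(comp, grp, co$features)
  best <- ps$center[which.min(ps$mean_abs_diff)]
  expect_equal(best, mean(grp$age) - 2, tolerance = 1.6)
  # a random subset is most similar to its own mean-age bin
  set.seed(3)
  sub <- comp[sample(nrow(comp), 60), ]
  ps2 <- profile_similarity(comp, sub, co$features)
  best2 <- ps2$center[which.min(ps2$mean_abs_diff)]
  expect_equal(best2, mean(sub$age), tolerance = 1.6)
  # one constant feature: curve equals |bin mean - group mean| exactly
  comp$k <- comp$age * 0.5
  grp$k <- grp$age * 0.5
  ps3 <- profile_similarity(comp, grp, "k")
  mu <- mean(comp$k); sdv <- stats::sd(comp$k)
  bin1 <- comp$age >= ps3$center[1] - ps3$half_width[1] &
    comp$age < ps3$center[1] + ps3$half_width[1]
  expect_equal(ps3$mean_abs_diff[1],
               abs(mean((comp$k[bin1] - mu) / sdv) -
                     mean((grp$k - mu) / sdv)), tolerance = 1e-9)
})
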