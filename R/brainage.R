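# Statistical layer: per-feature age associations with covariates and
# FDR, quadratic-vs-linear comparison, outlier masking, correlation-based
# feature pruning, the linear brain-age model (classic fit/predict S3
# interface), brain-age-gap group analysis with resampling, group
# difference models, and the age-bin similarity profile.

#' Mask per-feature outliers
#'
#' Per feature and round, values more than `sd` standard deviations from
#' the mean of the currently unmasked values are set to NA; statistics are
#' recomputed between rounds. Constant features (SD 0) are left untouched.
#'
#' @param table data.frame.
#' @param features feature column names.
#' @param sd SD criterion (3).
#' @param rounds passes (2).
#' @return the table with outliers replaced by NA; all-masked features are
#'   flagged in `attr(, "all_masked")`.
#' @export
clean_outliers <- function(table, features, sd = 3, rounds = 2) {
  for (f in features) {
    v <- table[[f]]
    for (r in seq_len(rounds)) {
      m <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) break
      v[abs(v - m) > sd * s] <- NA
    }
    table[[f]] <- v
  }
  attr(table, "all_masked") <- features[vapply(features, function(f)
    all(is.na(table[[f]])), logical(1))]
  table
}

#' Covariate-adjusted age associations per feature
#'
#' For each feature: a linear model `feature ~ age + covariates` (beta and
#' p for age), the unadjusted Pearson correlation with age, a quadratic
#' model adding age^2 (delta AIC/BIC = quadratic minus linear, negative
#' favouring the quadratic fit), and Benjamini-Hochberg q-values across
#' the tested feature set.
#'
#' @param table data.frame with `age`, covariates and features.
#' @param features feature columns.
#' @param covariates covariate columns (default sex, race).
#' @param min_n minimum complete rows per feature (20).
#' @return data.frame: feature, beta, p, pearson_r, quad_beta, delta_aic,
#'   delta_bic, fdr_q.
#' @export
fit_age_associations <- function(table, features,
                                 covariates = c("sex", "race"),
                                 min_n = 20) {
  out <- lapply(features, function(f) {
    d <- table[, c(f, "age", covariates)]
    d <- d[stats::complete.cases(d), ]
    if (nrow(d) < min_n)
      return(data.frame(feature = f, beta = NA_real_, p = NA_real_,
                        pearson_r = NA_real_, quad_beta = NA_real_,
                        delta_aic = NA_real_, delta_bic = NA_real_))
    fm <- stats::as.formula(paste0("`", f, "` ~ age ",
                                   paste0("+ ", covariates, collapse = " ")))
    m1 <- stats::lm(fm, data = d)
    if (any(is.na(stats::coef(m1))))
      stop("rank-deficient design for feature ", f, ": collinear columns ",
           paste(names(stats::coef(m1))[is.na(stats::coef(m1))],
                 collapse = ", "))
    co <- summary(m1)$coefficients
    fm2 <- stats::update(fm, . ~ . + I(age^2))
    m2 <- stats::lm(fm2, data = d)
    co2 <- summary(m2)$coefficients
    data.frame(feature = f,
               beta = co["age", "Estimate"], p = co["age", "Pr(>|t|)"],
               pearson_r = stats::cor(d[[f]], d$age),
               quad_beta = co2["I(age^2)", "Estimate"],
               delta_aic = stats::AIC(m2) - stats::AIC(m1),
               delta_bic = stats::BIC(m2) - stats::BIC(m1))
  })
  res <- do.call(rbind, out)
  res$fdr_q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Prune highly correlated features
#'
#' Greedy pass in the supplied (fixed catalogue) order: a feature is
#' dropped when its absolute Pearson correlation with an already-retained
#' feature exceeds `r_threshold`.
#'
#' @param table training rows.
#' @param features candidate features, in catalogue order.
#' @param r_threshold default 0.9.
#' @return character vector of retained features.
#' @export
select_features <- function(table, features, r_threshold = 0.9) {
  kept <- character(0)
  for (f in features) {
    v <- table[[f]]
    drop <- FALSE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(v, table[[k]],
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > r_threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, f)
  }
  kept
}

# Build the model frame: z-scored features (training parameters), training
# mean imputation for missing values, plus covariates.
.ba_frame <- function(table, features, covariates, zp) {
  X <- as.data.frame(lapply(features, function(f) {
    v <- (table[[f]] - zp$mean[[f]]) / zp$sd[[f]]
    v[is.na(v)] <- 0                     # training-mean imputation
    v
  }))
  names(X) <- make.names(features)
  for (cv in covariates) X[[cv]] <- table[[cv]]
  X$age <- table$age
  X
}

#' Fit the linear brain-age model
#'
#' Ordinary least squares of chronological age on the pruned, z-scored
#' sleep features plus covariates. Features are z-transformed with the
#' training mean and SD (frozen into the model and reused verbatim for any
#' prediction set); missing feature values are imputed at the training
#' mean. Model performance on the training sample is estimated by 10-fold
#' cross-validation (per-fold R^2 and MAE, reported mean and SD).
#'
#' @param train data.frame with `age`, covariates and features.
#' @param features feature columns (pruned internally at |r| > 0.9 unless
#'   `prune = FALSE`).
#' @param covariates covariate columns (default sex, race).
#' @param folds CV folds (10).
#' @param prune apply [select_features()] first.
#' @param seed seed for fold assignment.
#' @return object of class `brainage` with elements `fit` (lm), `features`
#'   (retained), `covariates`, `zparams`, `cv` (r2/mae mean and sd).
#' @export
brainage <- function(train, features, covariates = c("sex", "race"),
                     folds = 10, prune = TRUE, seed = 1) {
  if (prune) features <- select_features(train, features)
  zp <- list(mean = lapply(train[features], mean, na.rm = TRUE),
             sd = lapply(train[features], function(v) {
               s <- stats::sd(v, na.rm = TRUE)
               if (!is.finite(s) || s == 0) 1 else s
             }))
  names(zp$mean) <- features; names(zp$sd) <- features
  df <- .ba_frame(train, features, covariates, zp)
  fit <- stats::lm(age ~ ., data = df)

  cv <- with_seed(substream_seed(seed, 401L), {
    fold <- sample(rep(seq_len(folds), length.out = nrow(df)))
    stats_f <- t(vapply(seq_len(folds), function(k) {
      m <- stats::lm(age ~ ., data = df[fold != k, , drop = FALSE])
      pr <- stats::predict(m, newdata = df[fold == k, , drop = FALSE])
      obs <- df$age[fold == k]
      c(r2 = 1 - sum((obs - pr)^2) / sum((obs - mean(obs))^2),
        mae = mean(abs(obs - pr)))
    }, numeric(2)))
    list(r2_mean = mean(stats_f[, "r2"]), r2_sd = stats::sd(stats_f[, "r2"]),
         mae_mean = mean(stats_f[, "mae"]),
         mae_sd = stats::sd(stats_f[, "mae"]))
  })
  structure(list(fit = fit, features = features, covariates = covariates,
                 zparams = zp, cv = cv, n_train = nrow(df)),
            class = "brainage")
}

#' @export
print.brainage <- function(x, ...) {
  cat(sprintf("<brainage> OLS on %d features + %d covariates (n = %d)\n",
              length(x$features), length(x$covariates), x$n_train))
  cat(sprintf("  10-fold CV: R2 = %.3f (%.3f SD), MAE = %.2f yr (%.2f SD)\n",
              x$cv$r2_mean, x$cv$r2_sd, x$cv$mae_mean, x$cv$mae_sd))
  invisible(x)
}

#' @export
summary.brainage <- function(object, ...) {
  print(object)
  cat("\nRetained features:\n")
  print(object$features)
  invisible(object)
}

#' @export
coef.brainage <- function(object, ...) stats::coef(object$fit)

#' Predict brain age and brain-age gap
#'
#' @param object a fitted `brainage` model.
#' @param newdata data.frame with the model's features and covariates (and
#'   `age` for gap computation).
#' @param ... unused.
#' @return data.frame of class `brainage_result`: subject_id (if present),
#'   age, predicted, gap (= predicted - age), with attributes `r`, `mae`,
#'   `me`.
#' @export
predict.brainage <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("features absent from prediction set: ",
         paste(miss, collapse = ", "))
  df <- .ba_frame(newdata, object$features, object$covariates,
                  object$zparams)
  pred <- stats::predict(object$fit, newdata = df)
  out <- data.frame(age = newdata$age, predicted = as.numeric(pred),
                    gap = as.numeric(pred) - newdata$age)
  if ("subject_id" %in% names(newdata))
    out <- cbind(subject_id = newdata$subject_id, out)
  attr(out, "r") <- stats::cor(out$age, out$predicted)
  attr(out, "mae") <- mean(abs(out$gap))
  attr(out, "me") <- mean(out$gap)
  class(out) <- c("brainage_result", "data.frame")
  out
}

#' @export
print.brainage_result <- function(x, ...) {
  cat(sprintf(
    "<brainage_result> n = %d | r = %.3f | MAE = %.2f yr | ME = %+.2f yr\n",
    nrow(x), attr(x, "r"), attr(x, "mae"), attr(x, "me")))
  invisible(x)
}

#' Brain-age-gap group analysis with split resampling
#'
#' Each round resplits the non-delayed pool into 70% training and 30%
#' held-out, refits the model, and computes MAE and ME in the held-out set
#' and in each (fixed) group, plus two-sample t-tests of the group's gaps
#' (ME) and absolute gaps (MAE) against the held-out set. Reported per
#' group: mean/min/max of MAE and ME across rounds and the median p-value.
#'
#' @param pool non-delayed subjects (data.frame).
#' @param groups named list of group data.frames (disjoint from pool).
#' @param features,covariates model inputs.
#' @param n_rounds resampling rounds (100).
#' @param train_frac training fraction (0.7).
#' @param seed integer seed.
#' @return list(groups = per-group summary data.frame, holdout = held-out
#'   MAE/ME summaries, rounds = per-round raw values).
#' @export
gap_group_analysis <- function(pool, groups, features,
                               covariates = c("sex", "race"),
                               n_rounds = 100, train_frac = 0.7, seed = 1) {
  stopifnot(length(groups) >= 1)
  for (g in names(groups)) {
    if (nrow(groups[[g]]) < 5)
      warning("group ", g, " has fewer than 5 subjects; ",
              "estimates will be wide")
  }
  rounds <- list()
  for (r in seq_len(n_rounds)) {
    idx <- with_seed(substream_seed(seed, 501L, r), {
      sample(seq_len(nrow(pool)), round(train_frac * nrow(pool)))
    })
    model <- brainage(pool[idx, , drop = FALSE], features, covariates,
                      prune = TRUE, seed = substream_seed(seed, 502L, r))
    held <- predict(model, pool[-idx, , drop = FALSE])
    row <- list(round = r, holdout_mae = attr(held, "mae"),
                holdout_me = attr(held, "me"))
    for (g in names(groups)) {
      pg <- predict(model, groups[[g]])
      row[[paste0(g, "_mae")]] <- attr(pg, "mae")
      row[[paste0(g, "_me")]] <- attr(pg, "me")
      row[[paste0(g, "_p_me")]] <-
        stats::t.test(pg$gap, held$gap)$p.value
      row[[paste0(g, "_p_mae")]] <-
        stats::t.test(abs(pg$gap), abs(held$gap))$p.value
    }
    rounds[[r]] <- as.data.frame(row)
  }
  rd <- do.call(rbind, rounds)
  summ <- lapply(names(groups), function(g) {
    data.frame(group = g,
               mae_mean = mean(rd[[paste0(g, "_mae")]]),
               mae_min = min(rd[[paste0(g, "_mae")]]),
               mae_max = max(rd[[paste0(g, "_mae")]]),
               me_mean = mean(rd[[paste0(g, "_me")]]),
               me_min = min(rd[[paste0(g, "_me")]]),
               me_max = max(rd[[paste0(g, "_me")]]),
               median_p_me = stats::median(rd[[paste0(g, "_p_me")]]),
               median_p_mae = stats::median(rd[[paste0(g, "_p_mae")]]))
  })
  list(groups = do.call(rbind, summ),
       holdout = data.frame(mae_mean = mean(rd$holdout_mae),
                            me_mean = mean(rd$holdout_me)),
       rounds = rd)
}

#' Group-difference models per feature
#'
#' For each feature (z-scored across the analysed sample, so betas are
#' standardized): a main-effect model `z ~ group + age + covariates` and
#' an interaction model adding `group:age`. Benjamini-Hochberg FDR is
#' applied separately per effect family (main, interaction).
#'
#' @param table data.frame containing a logical/0-1 `group_col`.
#' @param group_col name of the group indicator column.
#' @param features feature columns.
#' @param covariates additional covariates (e.g. sex, race, ahi,
#'   medication).
#' @return data.frame: feature, beta_group, p_group, q_group,
#'   beta_interaction, p_interaction, q_interaction.
#' @export
group_difference_models <- function(table, group_col, features,
                                    covariates = c("sex", "race")) {
  g <- as.numeric(table[[group_col]])
  if (sum(g, na.rm = TRUE) == 0) stop("empty group: ", group_col)
  out <- lapply(features, function(f) {
    v <- table[[f]]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    d <- data.frame(z = z, grp = g, age = table$age,
                    table[, covariates, drop = FALSE])
    d <- d[stats::complete.cases(d), ]
    m1 <- stats::lm(z ~ ., data = d)
    m2 <- stats::lm(z ~ . + grp:age, data = d)
    c1 <- summary(m1)$coefficients
    c2 <- summary(m2)$coefficients
    data.frame(feature = f,
               beta_group = c1["grp", "Estimate"],
               p_group = c1["grp", "Pr(>|t|)"],
               beta_interaction = c2["grp:age", "Estimate"],
               p_interaction = c2["grp:age", "Pr(>|t|)"])
  })
  res <- do.call(rbind, out)
  res$q_group <- stats::p.adjust(res$p_group, method = "BH")
  res$q_interaction <- stats::p.adjust(res$p_interaction, method = "BH")
  res
}

#' Age-bin similarity profile
#'
#' Features are z-scored with the comparison sample's mean and SD; the
#' comparison sample is cut into two-year bins centered at 3, 5, ..., 13
#' and four-year bins centered at 16, 20, ..., 80 years; for each bin with
#' at least `min_n` subjects the mean absolute difference between bin
#' feature means and the group's feature means is returned. The curve's
#' minimum marks the age the group most resembles.
#'
#' @param comparison reference sample data.frame (with `age`).
#' @param group group data.frame.
#' @param features shared feature columns.
#' @param min_n minimum subjects per bin (10).
#' @return data.frame: center, half_width, n, mean_abs_diff (bins below
#'   `min_n` omitted).
#' @export
profile_similarity <- function(comparison, group, features, min_n = 10) {
  centers <- c(seq(3, 13, 2), seq(16, 80, 4))
  half <- c(rep(1, 6), rep(2, 17))
  mu <- vapply(features, function(f) mean(comparison[[f]], na.rm = TRUE),
               numeric(1))
  sd_ <- vapply(features, function(f) {
    s <- stats::sd(comparison[[f]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  zc <- sweep(sweep(as.matrix(comparison[, features, drop = FALSE]),
                    2, mu), 2, sd_, `/`)
  zg <- sweep(sweep(as.matrix(group[, features, drop = FALSE]),
                    2, mu), 2, sd_, `/`)
  gmean <- colMeans(zg, na.rm = TRUE)
  out <- lapply(seq_along(centers), function(k) {
    sel <- comparison$age >= centers[k] - half[k] &
      comparison$age < centers[k] + half[k]
    if (sum(sel) < min_n) return(NULL)
    bmean <- colMeans(zc[sel, , drop = FALSE], na.rm = TRUE)
    data.frame(center = centers[k], half_width = half[k], n = sum(sel),
               mean_abs_diff = mean(abs(bmean - gmean)))
  })
  do.call(rbind, out)
}
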