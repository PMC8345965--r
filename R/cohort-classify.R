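## HDL-cholesterol matching and the feature-elimination classifier.

#' Match cases to controls on HDL-cholesterol
#'
#' Greedy one-to-one matching: candidate case-control pairs within
#' `tolerance_mg_dl` of each other are taken in ascending order of
#' |difference| (ties broken by subject id for determinism), each subject
#' used at most once. The study matched nine patients with nine controls at
#' +/- 1 mg/dL.
#'
#' @param table A cohort table with `hdl_cholesterol`, `group`, `subject_id`.
#' @param tolerance_mg_dl Maximum |HDL-C difference| in mg/dL (default 1.0).
#' @return data.frame of pairs: `case_id`, `control_id`, `case_hdlc`,
#'   `control_hdlc`, `delta` (zero rows if none qualify).
#' @export
match_by_hdl_cholesterol <- function(table, tolerance_mg_dl = 1.0) {
  if (!"hdl_cholesterol" %in% names(table))
    stop_format("column 'hdl_cholesterol' not found")
  if (any(is.na(table$hdl_cholesterol)))
    stop_format("hdl_cholesterol must be present for all subjects")
  cases <- table[table$group == "ACS", ]
  ctrls <- table[table$group == "control", ]
  cand <- expand.grid(i = seq_len(nrow(cases)), j = seq_len(nrow(ctrls)))
  cand$delta <- abs(cases$hdl_cholesterol[cand$i] -
                    ctrls$hdl_cholesterol[cand$j])
  cand <- cand[cand$delta <= tolerance_mg_dl + 1e-12, , drop = FALSE]
  cand <- cand[order(cand$delta, cases$subject_id[cand$i],
                     ctrls$subject_id[cand$j]), , drop = FALSE]
  used_case <- logical(nrow(cases)); used_ctrl <- logical(nrow(ctrls))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_case[i] && !used_ctrl[j]) {
      keep[k] <- TRUE; used_case[i] <- TRUE; used_ctrl[j] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  data.frame(case_id = cases$subject_id[sel$i],
             control_id = ctrls$subject_id[sel$j],
             case_hdlc = cases$hdl_cholesterol[sel$i],
             control_hdlc = ctrls$hdl_cholesterol[sel$j],
             delta = sel$delta)
}

# Ridge-penalized logistic regression by penalized IRLS (penalty on slopes,
# not the intercept). Used only as the flagged fallback when maximum
# likelihood diverges on (quasi-)separated data.
ridge_logistic <- function(X, y, lambda = 0.1, max_iter = 100, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  D <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(Xd, Xd * W) + D
    grad <- crossprod(Xd, y - mu) - D %*% beta
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(Xd, Xd * (mu * (1 - mu))) + D
  se <- sqrt(diag(solve(H)))
  list(coef = stats::setNames(beta, colnames(Xd)),
       se = stats::setNames(se, colnames(Xd)), fitted = mu)
}

glm_is_separated <- function(fit) {
  !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || max(abs(stats::coef(fit))) > 1e3
}

fit_logistic_classifier <- function(X, y) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  if (glm_is_separated(fit)) {
    rf <- ridge_logistic(as.matrix(X), y)
    list(coef = rf$coef, se = rf$se, penalized = TRUE,
         predict = function(newX)
           stats::plogis(drop(cbind(1, as.matrix(newX)) %*% rf$coef)))
  } else {
    sm <- summary(fit)$coefficients
    list(coef = stats::coef(fit), se = sm[, "Std. Error"], penalized = FALSE,
         predict = function(newX)
           stats::plogis(drop(cbind(1, as.matrix(newX)) %*% stats::coef(fit))))
  }
}

#' Recursive-feature-elimination logistic classifier with effectivity
#'
#' Reproduces the study's machine-learning layer: a stratified
#' training/verification split (75/25 by default), standardization of the
#' features to zero mean / unit variance on the training data, recursive
#' feature elimination (iteratively refit the logistic model and drop the
#' feature with the smallest absolute standardized coefficient until
#' `n_keep` remain), a final logistic fit on the selected features, and
#' "effectivity" -- percent of subjects correctly classified at probability
#' threshold 0.5 -- on both splits. Odds ratios (per 1 sd of the training
#' data) with Wald 95% CIs are reported per selected feature. Maximum
#' likelihood is replaced by a small ridge penalty, and flagged, when
#' separation is detected (the groups are near-separable on the stability
#' score, where unpenalized ML diverges).
#'
#' @param table A cohort table with `group` (control/ACS).
#' @param features Character vector of feature columns (numeric;
#'   0/1-coded categoricals allowed).
#' @param train_fraction Training share of each group (default 0.75).
#' @param seed Integer seed for the stratified split.
#' @param n_keep Number of features to retain (default 1).
#' @return An object of class `classifier_report`: `selected_features`,
#'   `coefficients`, `odds_ratios` (data.frame with CI), `penalized`,
#'   `training_effectivity`, `verification_effectivity`, `split_seed`,
#'   `train_fraction`, `train_ids`, `verification_ids`.
#' @export
rfe_logistic <- function(table, features, train_fraction = 0.75, seed = 1L,
                         n_keep = 1L) {
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop_format("feature(s) not found: %s", paste(missing, collapse = ", "))
  if (n_keep < 1L || n_keep > length(features))
    stop_format("n_keep must be between 1 and the number of features")
  y <- as.integer(table$group == "ACS")
  X <- as.matrix(as.data.frame(lapply(table[features], as.numeric)))
  colnames(X) <- features
  if (any(!is.finite(X))) stop_format("features must be finite numerics")
  idx_by_group <- split(seq_len(nrow(table)), table$group)
  train_idx <- with_seed(seed, {
    sort(unlist(lapply(idx_by_group, function(ix) {
      ntr <- round(train_fraction * length(ix))
      if (ntr < 2L) stop_format("fewer than 2 training subjects in a group")
      sample(ix, ntr)
    }), use.names = FALSE))
  })
  verif_idx <- setdiff(seq_len(nrow(table)), train_idx)
  if (!length(verif_idx)) stop_format("empty verification split")
  ytr <- y[train_idx]; yve <- y[verif_idx]
  if (length(unique(ytr)) < 2L)
    stop_format("training split contains a single class")
  ctr <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Ztr <- Z[train_idx, , drop = FALSE]
  keep <- features
  fit <- fit_logistic_classifier(Ztr[, keep, drop = FALSE], ytr)
  while (length(keep) > n_keep) {
    slopes <- fit$coef[keep]
    slopes[is.na(slopes)] <- 0  # collinear feature dropped by glm
    drop_feat <- keep[which.min(abs(slopes))]
    keep <- setdiff(keep, drop_feat)
    fit <- fit_logistic_classifier(Ztr[, keep, drop = FALSE], ytr)
  }
  acc <- function(idx) {
    p <- fit$predict(Z[idx, keep, drop = FALSE])
    100 * mean((p > 0.5) == (y[idx] == 1))
  }
  cf <- fit$coef[keep]; se <- fit$se[keep]
  or_tab <- data.frame(
    feature = keep,
    odds_ratio = exp(cf),
    ci_lower = exp(cf - 1.96 * se),
    ci_upper = exp(cf + 1.96 * se),
    row.names = NULL)
  structure(
    list(selected_features = keep, coefficients = fit$coef,
         odds_ratios = or_tab, penalized = fit$penalized,
         training_effectivity = acc(train_idx),
         verification_effectivity = acc(verif_idx),
         split_seed = seed, train_fraction = train_fraction,
         train_ids = table$subject_id[train_idx],
         verification_ids = table$subject_id[verif_idx]),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> features: %s%s\n",
              paste(x$selected_features, collapse = ", "),
              if (x$penalized) "  [ridge fallback: separation detected]" else ""))
  cat(sprintf("  effectivity: training %.1f%%, verification %.1f%% (seed %d, %d/%d split)\n",
              x$training_effectivity, x$verification_effectivity,
              x$split_seed, length(x$train_ids), length(x$verification_ids)))
  print(x$odds_ratios)
  invisible(x)
}
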