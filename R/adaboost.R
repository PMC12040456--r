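# AdaBoost.R2 (Drucker 1997) over rpart weak learners.
#
# Boosting proceeds through deterministic case reweighting (no bootstrap
# resampling), so fits are exactly reproducible. Linear loss; prediction is
# the weighted median of the weak learners' outputs with weights
# log(1 / beta_t).

fit_adaboost_r2 <- function(x, y, nrounds = 50, maxdepth = 4) {
  n <- nrow(x)
  df <- as.data.frame(x)
  df$.y <- y
  w <- rep(1 / n, n)
  learners <- list()
  betas <- numeric(0)
  for (t in seq_len(nrounds)) {
    tree <- rpart::rpart(
      .y ~ ., data = df, weights = w, method = "anova",
      control = rpart::rpart.control(maxdepth = maxdepth, minsplit = 5,
                                     cp = 0, xval = 0)
    )
    pred <- stats::predict(tree, newdata = df)
    abs_err <- abs(y - pred)
    max_err <- max(abs_err)
    if (max_err < .Machine$double.eps) {
      # perfect weak learner: keep it with full confidence and stop
      learners[[length(learners) + 1]] <- tree
      betas <- c(betas, .Machine$double.eps)
      break
    }
    loss <- abs_err / max_err
    err <- sum(w * loss)
    if (err >= 0.5) break
    beta <- err / (1 - err)
    learners[[length(learners) + 1]] <- tree
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (length(learners) == 0) {
    # no weak learner beat the 0.5 loss bound; fall back to one stump
    learners <- list(rpart::rpart(.y ~ ., data = df, method = "anova",
                                  control = rpart::rpart.control(
                                    maxdepth = 1, cp = 0, xval = 0)))
    betas <- 0.5
  }
  list(learners = learners, log_inv_beta = log(1 / betas))
}

predict_adaboost_r2 <- function(model, x) {
  df <- as.data.frame(x)
  preds <- vapply(model$learners, function(l) {
    stats::predict(l, newdata = df)
  }, numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  wts <- model$log_inv_beta
  apply(preds, 1, function(p) weighted_median(p, wts))
}

# smallest value whose cumulative weight reaches half the total
weighted_median <- function(values, weights) {
  ord <- order(values)
  cw <- cumsum(weights[ord])
  values[ord][which(cw >= 0.5 * sum(weights))[1]]
}
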