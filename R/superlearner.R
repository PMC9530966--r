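#' Candidate learner specification
#'
#' Learners are the regression candidates stacked by [fit_superlearner()].
#' The registry holds `intercept_only`, `linear_additive`,
#' `gradient_boosted_trees` (xgboost), `k_nearest_neighbors` (FNN), and
#' `saturated` — a cell-mean regression on the full cross-classification of
#' the (discretised) features, used to make the estimators exact on
#' finite-state processes.
#'
#' @param name Registry name.
#' @param ... Hyperparameters (`nrounds`, `max_depth`, `eta` for the boosted
#'   trees; `k` for nearest neighbours).
#' @return A `learner_spec`.
#' @examples
#' learner("gradient_boosted_trees", nrounds = 30, max_depth = 2)
#' @export
learner <- function(name = c("intercept_only", "linear_additive",
                             "gradient_boosted_trees", "k_nearest_neighbors",
                             "saturated"), ...) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...)), class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("<learner>", x$name, "\n")
  invisible(x)
}

default_learners <- function() {
  list(learner("intercept_only"), learner("linear_additive"),
       learner("gradient_boosted_trees", nrounds = 30, max_depth = 2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fit one candidate; returns a prediction closure over new feature frames.
fit_candidate <- function(spec, X, y, w, loss) {
  Xm <- as.matrix(X)
  p <- spec$params
  switch(spec$name,
    intercept_only = {
      mu <- stats::weighted.mean(y, w)
      function(newX) rep(mu, nrow(newX))
    },
    linear_additive = {
      sds <- apply(Xm, 2, stats::sd)
      keep <- !is.na(sds) & sds > 0
      Xd <- cbind(`(Intercept)` = 1, Xm[, keep, drop = FALSE])
      fit <- if (loss == "log") {
        suppressWarnings(stats::glm.fit(Xd, clamp(y, 0, 1), weights = w,
                                        family = stats::binomial()))
      } else {
        stats::lm.wfit(Xd, y, w)
      }
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      function(newX) {
        eta <- cbind(1, as.matrix(newX)[, keep, drop = FALSE]) %*% beta
        if (loss == "log") stats::plogis(drop(eta)) else drop(eta)
      }
    },
    gradient_boosted_trees = {
      obj <- if (loss == "log") "binary:logistic" else "reg:squarederror"
      yy <- if (loss == "log") clamp(y, 0, 1) else y
      dm <- xgboost::xgb.DMatrix(Xm, label = yy, weight = w)
      bst <- xgboost::xgb.train(
        params = list(max_depth = p$max_depth %||% 2, eta = p$eta %||% 0.3,
                      objective = obj, nthread = 1),
        data = dm, nrounds = p$nrounds %||% 30, verbose = 0)
      function(newX) predict(bst, xgboost::xgb.DMatrix(as.matrix(newX)))
    },
    k_nearest_neighbors = {
      k <- min(p$k %||% 20, nrow(Xm))
      function(newX) {
        FNN::knn.reg(train = Xm, test = as.matrix(newX), y = y, k = k)$pred
      }
    },
    saturated = {
      key <- interaction(as.data.frame(Xm), drop = TRUE)
      num <- tapply(w * y, key, sum)
      den <- tapply(w, key, sum)
      mu <- num / den
      fallback <- stats::weighted.mean(y, w)
      lev <- names(mu)
      function(newX) {
        kk <- interaction(as.data.frame(as.matrix(newX)), drop = TRUE)
        out <- mu[match(as.character(kk), lev)]
        out[is.na(out)] <- fallback
        unname(out)
      }
    })
}

cv_loss <- function(pred, y, w, loss) {
  if (loss == "log") {
    p <- clamp(pred, 1e-8, 1 - 1e-8)
    -stats::weighted.mean(y * log(p) + (1 - y) * log(1 - p), w)
  } else {
    stats::weighted.mean((y - pred)^2, w)
  }
}

softmax <- function(th) {
  e <- exp(th - max(th))
  e / sum(e)
}

#' Super learner: cross-validated convex stacking of candidate learners
#'
#' V-fold cross-validation produces held-out predictions for each candidate;
#' convex combination weights (non-negative, summing to one) are chosen to
#' minimise the cross-validated loss; candidates are then refit on the full
#' data and the predictor is their weighted combination.  With a single
#' candidate, or a constant target, no stacking is performed.
#'
#' @param X Data frame of numeric features.
#' @param y Numeric target.
#' @param learners List of [learner()] specifications (at least one).
#' @param v_folds Cross-validation folds for the weight estimation.
#' @param loss `"squared"` or `"log"` (targets in `[0,1]`).
#' @param weights Optional observation weights.
#' @return A `superlearner` object with `$weights`, `$cv_risks` (per
#'   candidate), `$cv_risk_ensemble`, and a [predict()] method.
#' @examples
#' X <- data.frame(x = rnorm(200))
#' y <- 1 + 2 * X$x
#' sl <- fit_superlearner(X, y, list(learner("intercept_only"),
#'                                   learner("linear_additive")))
#' sl$weights
#' @export
fit_superlearner <- function(X, y, learners, v_folds = 5,
                             loss = c("squared", "log"), weights = NULL) {
  loss <- match.arg(loss)
  stopifnot(length(learners) >= 1, all(is.finite(y)))
  w <- weights %||% rep(1, length(y))
  nm <- vapply(learners, function(l) l$name, character(1))

  if (length(y) < 2 || stats::sd(y) == 0) {
    # degenerate target: intercept carries it
    fits <- list(fit_candidate(learner("intercept_only"), X, y, w, loss))
    return(structure(list(weights = 1, names = "intercept_only",
                          fits = fits, cv_risks = NULL,
                          cv_risk_ensemble = 0, loss = loss),
                     class = "superlearner"))
  }
  if (length(learners) == 1L) {
    fits <- list(fit_candidate(learners[[1]], X, y, w, loss))
    return(structure(list(weights = 1, names = nm, fits = fits,
                          cv_risks = NULL, cv_risk_ensemble = NA_real_,
                          loss = loss), class = "superlearner"))
  }

  stopifnot(v_folds >= 2)
  n <- length(y)
  fold <- rep_len(seq_len(v_folds), n)
  Z <- matrix(NA_real_, n, length(learners))
  for (v in seq_len(v_folds)) {
    tr <- fold != v
    if (sum(tr) < 2 || stats::sd(y[tr]) == 0) {
      Z[!tr, ] <- stats::weighted.mean(y[tr], w[tr])
      next
    }
    for (j in seq_along(learners)) {
      f <- fit_candidate(learners[[j]], X[tr, , drop = FALSE], y[tr], w[tr],
                         loss)
      Z[!tr, j] <- f(X[!tr, , drop = FALSE])
    }
  }
  risks <- vapply(seq_along(learners),
                  function(j) cv_loss(Z[, j], y, w, loss), numeric(1))

  # convex weights: start from the best single candidate (a feasible point),
  # refine over the simplex via a softmax parameterisation
  best <- which.min(risks)
  obj <- function(th) cv_loss(drop(Z %*% softmax(th)), y, w, loss)
  th0 <- rep(0, length(learners)); th0[best] <- 8
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  alpha <- if (opt$value <= risks[best]) softmax(opt$par) else {
    a <- rep(0, length(learners)); a[best] <- 1; a
  }
  ens_risk <- cv_loss(drop(Z %*% alpha), y, w, loss)

  fits <- lapply(learners, function(l) fit_candidate(l, X, y, w, loss))
  structure(list(weights = alpha, names = nm, fits = fits, cv_risks = risks,
                 cv_risk_ensemble = ens_risk, loss = loss),
            class = "superlearner")
}

#' @export
predict.superlearner <- function(object, newdata, ...) {
  preds <- vapply(object$fits, function(f) as.numeric(f(newdata)),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% object$weights)
}

#' @export
print.superlearner <- function(x, ...) {
  cat("<superlearner>", x$loss, "loss; weights:\n")
  print(stats::setNames(round(x$weights, 3), x$names))
  invisible(x)
}
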