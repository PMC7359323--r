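# Surrogate stage: learn the forecast uniform-mixing time T_end from the nine
# material/process descriptors; evaluate by leave-one-out cross-validation and
# rank descriptors by permutation importance.

feature_cols <- function(table) {
  setdiff(names(table), c("t_end_s", "provenance"))
}

#' Assemble a feature table from run results
#'
#' One row per run: the nine descriptors (SI units) plus the response
#' `t_end_s` and a provenance tag. Runs whose endpoint estimate has no
#' crossing are excluded (the count is reported in a message and recorded in
#' the `n_excluded` attribute). A min/mean/max design-space summary per
#' descriptor is attached as the `design_summary` attribute.
#'
#' @param run_results list of `list(params = , estimate = , provenance = )`
#'   entries; `estimate` is an `endpoint_estimate` (or a bare `t_end` number)
#' @return a `feature_table` data.frame
#' @export
assemble_table <- function(run_results) {
  rows <- list(); n_excluded <- 0L
  for (r in run_results) {
    t_end <- if (inherits(r$estimate, "endpoint_estimate")) {
      if (isTRUE(r$estimate$no_crossing)) NA_real_ else r$estimate$t_end
    } else as.numeric(r$estimate)
    if (is.na(t_end)) {
      n_excluded <- n_excluded + 1L
      next
    }
    row <- as.data.frame(unclass(r$params)[descriptor_names()])
    row$t_end_s <- t_end
    row$provenance <- if (is.null(r$provenance)) "dem+arima" else r$provenance
    rows[[length(rows) + 1L]] <- row
  }
  if (n_excluded > 0)
    message(sprintf("assemble_table: %d run(s) without a cutoff crossing excluded",
                    n_excluded))
  if (!length(rows)) stop("no runs with a resolved t_end", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fc <- feature_cols(tab)
  zv <- fc[vapply(tab[fc], function(x) stats::var(x) == 0, TRUE)]
  if (length(zv))
    warning("zero-variance descriptor column(s): ", paste(zv, collapse = ", "),
            call. = FALSE)
  attr(tab, "design_summary") <- data.frame(
    descriptor = fc,
    min = vapply(tab[fc], min, 0),
    mean = vapply(tab[fc], mean, 0),
    max = vapply(tab[fc], max, 0), row.names = NULL)
  attr(tab, "n_excluded") <- n_excluded
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Write / read a feature table CSV
#' @param table a `feature_table`
#' @param file CSV path
#' @return the path (write) or a `feature_table` (read)
#' @export
write_feature_table <- function(table, file) {
  write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  if (!"t_end_s" %in% names(d))
    stop("feature table CSV must contain a 't_end_s' column", call. = FALSE)
  if (!"provenance" %in% names(d)) d$provenance <- "unknown"
  class(d) <- c("feature_table", "data.frame")
  d
}

default_tune <- function() {
  list(rf = list(mtry = c(2, 3, 5, 9), depth = c(3, 5, 10, NA), ntree = 500),
       svr = list(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1)),
       plsr = list(ncomp = 1:5),
       elastic_net = list(alpha = c(0.1, 0.5, 0.9)))
}

inner_folds <- function(n, k = 5) {
  k <- min(k, n)
  sample(rep(seq_len(k), length.out = n))
}

# ---- per-method fit/predict on one training fold -------------------------

fit_rf_tuned <- function(X, y, grid, keep_inbag = FALSE) {
  best <- NULL
  for (mtry in grid$mtry) {
    mtry_eff <- min(mtry, ncol(X))
    for (depth in grid$depth) {
      maxnodes <- if (is.na(depth)) NULL else min(2^depth, nrow(X))
      fit <- randomForest::randomForest(
        x = X, y = y, ntree = grid$ntree, mtry = mtry_eff,
        maxnodes = maxnodes, keep.inbag = keep_inbag)
      oob <- mean((fit$predicted - y)^2)  # OOB error is the inner criterion
      if (is.null(best) || oob < best$oob)
        best <- list(fit = fit, oob = oob,
                     pars = list(mtry = mtry_eff, depth = depth))
    }
  }
  best
}

fit_svr_tuned <- function(X, y, grid) {
  fold <- inner_folds(nrow(X))
  best <- NULL
  for (cost in grid$cost) {
    for (g in grid$gamma) {
      gam <- if (is.na(g)) 1 / ncol(X) else g
      mse <- 0
      for (k in unique(fold)) {
        tr <- fold != k
        f <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr], cost = cost,
                        gamma = gam, kernel = "radial", scale = FALSE)
        pr <- predict(f, X[!tr, , drop = FALSE])
        mse <- mse + sum((pr - y[!tr])^2)
      }
      if (is.null(best) || mse < best$mse)
        best <- list(mse = mse, pars = list(cost = cost, gamma = gam))
    }
  }
  fit <- e1071::svm(x = X, y = y, cost = best$pars$cost, gamma = best$pars$gamma,
                    kernel = "radial", scale = FALSE)
  list(fit = fit, pars = best$pars,
       predict = function(newX) as.numeric(predict(fit, newX)))
}

fit_plsr_tuned <- function(X, y, grid) {
  fold <- inner_folds(nrow(X))
  ncomp_max <- min(max(grid$ncomp), ncol(X), nrow(X) - 2)
  ncands <- grid$ncomp[grid$ncomp <= ncomp_max]
  best <- NULL
  for (nc in ncands) {
    mse <- 0
    for (k in unique(fold)) {
      tr <- fold != k
      f <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = nc,
                         mode = "regression", scale = FALSE)
      pr <- predict(f, X[!tr, , drop = FALSE])$predict[, 1, nc]
      mse <- mse + sum((pr - y[!tr])^2)
    }
    if (is.null(best) || mse < best$mse) best <- list(mse = mse, ncomp = nc)
  }
  fit <- mixOmics::pls(X, y, ncomp = best$ncomp, mode = "regression",
                       scale = FALSE)
  list(fit = fit, pars = list(ncomp = best$ncomp),
       predict = function(newX)
         as.numeric(predict(fit, newX)$predict[, 1, best$ncomp]))
}

fit_enet_tuned <- function(X, y, grid) {
  # cv.glmnet wants >= 3 observations per fold
  foldid <- inner_folds(nrow(X), k = max(3L, min(5L, nrow(X) %/% 3L)))
  best <- NULL
  for (alpha in grid$alpha) {
    cv <- glmnet::cv.glmnet(as.matrix(X), y, alpha = alpha, foldid = foldid,
                            standardize = FALSE)
    m <- min(cv$cvm)
    if (is.null(best) || m < best$cvm)
      best <- list(cvm = m, cv = cv, pars = list(alpha = alpha,
                                                 lambda = cv$lambda.min))
  }
  list(fit = best$cv, pars = best$pars,
       predict = function(newX)
         as.numeric(predict(best$cv, as.matrix(newX), s = "lambda.min")))
}

#' Fit surrogate models and evaluate by leave-one-out cross-validation
#'
#' For each requested method, every row is predicted by a model trained on all
#' other rows; hyperparameters are tuned inside each training fold (random
#' forest by its own out-of-bag error, SVR and PLSR by an inner 5-fold CV,
#' elastic net by `cv.glmnet` over the mixing grid). Descriptors are
#' standardized with training-fold statistics for SVR/PLSR/elastic net and
#' left untransformed for the random forest. R^2 is computed on the pooled
#' out-of-fold predictions as `1 - SSE/SST` (may be negative).
#'
#' @param table a `feature_table`
#' @param methods subset of `c("rf", "svr", "plsr", "elastic_net")`
#' @param seed master seed controlling all inner-CV fold assignments and
#'   random-forest bootstraps
#' @param tune optional list of tuning grids overriding [the defaults]; same
#'   shape as the `rf`/`svr`/`plsr`/`elastic_net` entries of the internal
#'   default grid
#' @return a `surrogate_report`: per method the LOOCV predictions, pooled
#'   `r_squared`, the modal tuned hyperparameters, and fold bookkeeping
#'   (`fold_train_rows`) proving row i was held out of its own fold
#' @export
fit_and_crossvalidate <- function(table,
                                  methods = c("rf", "svr", "plsr", "elastic_net"),
                                  seed = 1L, tune = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 10)
  methods <- match.arg(methods, several.ok = TRUE)
  grids <- utils::modifyList(default_tune(), if (is.null(tune)) list() else tune)
  fc <- feature_cols(table)
  X_all <- as.matrix(table[fc])
  y <- table$t_end_s
  n <- nrow(table)

  with_local_seed(seed, {
    per_method <- list()
    for (m in methods) {
      if (stats::var(y) == 0) {
        per_method[[m]] <- list(skipped = TRUE,
                                reason = "constant response in table")
        next
      }
      preds <- rep(NA_real_, n)
      pars <- vector("list", n)
      fold_train_rows <- vector("list", n)
      for (i in seq_len(n)) {
        tr <- setdiff(seq_len(n), i)
        fold_train_rows[[i]] <- tr
        Xtr <- X_all[tr, , drop = FALSE]
        Xte <- X_all[i, , drop = FALSE]
        if (m != "rf") {
          mu <- colMeans(Xtr)
          sdv <- apply(Xtr, 2, stats::sd)
          sdv[sdv == 0] <- 1
          Xtr <- scale(Xtr, center = mu, scale = sdv)
          Xte <- scale(Xte, center = mu, scale = sdv)
        }
        f <- switch(m,
          rf = {
            b <- fit_rf_tuned(Xtr, y[tr], grids$rf)
            list(pars = b$pars,
                 predict = function(newX) as.numeric(predict(b$fit, newX)))
          },
          svr = fit_svr_tuned(Xtr, y[tr], grids$svr),
          plsr = fit_plsr_tuned(Xtr, y[tr], grids$plsr),
          elastic_net = fit_enet_tuned(Xtr, y[tr], grids$elastic_net))
        preds[i] <- f$predict(Xte)
        pars[[i]] <- f$pars
      }
      r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
      per_method[[m]] <- list(skipped = FALSE, loocv_predictions = preds,
                              r_squared = r2, fold_hyperparameters = pars,
                              fold_train_rows = fold_train_rows)
    }
    structure(list(methods = per_method, response = y, n_rows = n,
                   feature_names = fc, seed = seed),
              class = "surrogate_report")
  })
}

#' @exportS3Method base::print
print.surrogate_report <- function(x, ...) {
  cat(sprintf("Surrogate LOOCV report (%d rows, %d descriptors):\n", x$n_rows,
              length(x$feature_names)))
  for (m in names(x$methods)) {
    e <- x$methods[[m]]
    if (isTRUE(e$skipped)) cat(sprintf("  %-12s skipped: %s\n", m, e$reason))
    else cat(sprintf("  %-12s R^2 = %.3f\n", m, e$r_squared))
  }
  if (!is.null(x$importances)) {
    cat("  rf permutation importance (% increase in OOB MSE):\n")
    imp <- x$importances
    for (k in order(-imp$importance))
      cat(sprintf("    %-16s %8.2f\n", imp$descriptor[k], imp$importance[k]))
  }
  invisible(x)
}

oob_predictions <- function(rf, X) {
  pr <- predict(rf, X, predict.all = TRUE)$individual
  inbag <- rf$inbag
  oob <- inbag == 0
  rowSums(pr * oob) / rowSums(oob)
}

#' Permutation importance of the descriptors under a random forest
#'
#' Quantifies each descriptor as the percentage increase in mean-squared error
#' after randomly permuting that column, averaged over `n_permutations`
#' replicates. The error is always computed out-of-fold: each row is scored
#' only by the trees whose bootstrap sample excluded it (out-of-bag).
#'
#' @param table a `feature_table`
#' @param fitted_rf optional `randomForest` fit with `keep.inbag = TRUE`; when
#'   NULL a tuned forest is fitted on the full table
#' @param n_permutations permutation replicates per descriptor (>= 10)
#' @param seed RNG seed for permutations (and the forest fit, when refitted)
#' @param tune optional rf tuning grid (see [fit_and_crossvalidate()])
#' @return data.frame with `descriptor`, `importance` (percent change in MSE),
#'   `sd` over replicates, `rank`, and a `zero_variance` flag (such columns
#'   get importance 0 by definition)
#' @export
permutation_importance <- function(table, fitted_rf = NULL,
                                   n_permutations = 20, seed = 1L,
                                   tune = NULL) {
  stopifnot(n_permutations >= 10)
  grids <- utils::modifyList(default_tune(), if (is.null(tune)) list() else tune)
  fc <- feature_cols(table)
  X <- as.matrix(table[fc])
  y <- table$t_end_s
  with_local_seed(seed, {
    if (is.null(fitted_rf))
      fitted_rf <- fit_rf_tuned(X, y, grids$rf, keep_inbag = TRUE)$fit
    if (is.null(fitted_rf$inbag))
      stop("fitted_rf must be grown with keep.inbag = TRUE", call. = FALSE)
    base_mse <- mean((oob_predictions(fitted_rf, X) - y)^2)
    imp <- sdv <- numeric(length(fc))
    zero_var <- vapply(fc, function(nm) stats::var(X[, nm]) == 0, TRUE)
    for (k in seq_along(fc)) {
      if (zero_var[k]) next  # importance 0 by definition
      delta <- numeric(n_permutations)
      for (r in seq_len(n_permutations)) {
        Xp <- X
        Xp[, k] <- X[sample(nrow(X)), k]
        delta[r] <- 100 * (mean((oob_predictions(fitted_rf, Xp) - y)^2) -
                             base_mse) / base_mse
      }
      imp[k] <- mean(delta)
      sdv[k] <- stats::sd(delta)
    }
    out <- data.frame(descriptor = fc, importance = imp, sd = sdv,
                      zero_variance = unname(zero_var))
    out$rank <- rank(-out$importance, ties.method = "first")
    attr(out, "base_oob_mse") <- base_mse
    out
  })
}

#' Write a surrogate report as JSON
#' @param report a `surrogate_report`
#' @param file output JSON path
#' @return `file`, invisibly
#' @export
write_surrogate_report <- function(report, file) {
  out <- list(n_rows = report$n_rows, seed = report$seed,
              feature_names = report$feature_names,
              methods = lapply(report$methods, function(e) {
                if (isTRUE(e$skipped)) list(skipped = TRUE, reason = e$reason)
                else list(r_squared = e$r_squared,
                          loocv_predictions = e$loocv_predictions)
              }))
  if (!is.null(report$importances))
    out$importances <- report$importances[c("descriptor", "importance", "sd",
                                            "rank")]
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
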