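meta_cols <- c("plant_id", "species", "condition", "label")

feature_cols <- function(table) setdiff(names(table), meta_cols)

check_feature_table <- function(table) {
  if (!"label" %in% names(table)) stop("feature table needs a 'label' column")
  if (anyNA(table$label)) stop("missing labels in feature table")
  fc <- feature_cols(table)
  if (!length(fc)) stop("feature table has no feature columns")
  if (nrow(table) < 2) stop("feature table needs at least 2 rows")
  fc
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize the features of a feature table
#'
#' Centres and scales every feature column to mean 0 and (population) sd 1,
#' the scaling used before feeding linear classifiers so coefficients are
#' comparable across features. Constant features carry no information and are
#' dropped with a warning. The fitted parameters are attached so they can be
#' re-applied to new rows.
#'
#' @param table a feature table ([feature_table()] layout).
#' @param scaling optional parameter data.frame (`feature`, `mean`, `sd`)
#'   from a previous call, applied instead of fitting new parameters.
#' @return the standardized table, with attribute `scaling`.
#' @export
standardize_features <- function(table, scaling = NULL) {
  fc <- check_feature_table(table)
  if (is.null(scaling)) {
    mu <- vapply(table[fc], mean, numeric(1))
    sd_ <- vapply(table[fc], pop_sd, numeric(1))
    const <- sd_ == 0
    if (all(const)) stop("all features are constant")
    if (any(const)) {
      warning("dropping constant feature(s): ",
              paste(fc[const], collapse = ", "))
      table <- table[, c(meta_cols[meta_cols %in% names(table)], fc[!const])]
      fc <- fc[!const]
      mu <- mu[!const]
      sd_ <- sd_[!const]
    }
    scaling <- data.frame(feature = fc, mean = unname(mu), sd = unname(sd_))
  } else {
    keep <- intersect(fc, scaling$feature)
    table <- table[, c(meta_cols[meta_cols %in% names(table)], keep)]
    fc <- keep
  }
  for (f in fc) {
    p <- scaling[scaling$feature == f, ]
    table[[f]] <- (table[[f]] - p$mean) / p$sd
  }
  attr(table, "scaling") <- scaling
  table
}

#' Winsorize outlying standardized values
#'
#' Values with |z| beyond `z_max` are clipped to +/- `z_max`, bounding the
#' contribution of extreme observations without discarding rows. Idempotent.
#'
#' @param table a standardized feature table.
#' @param z_max clipping bound in sd units (default 3).
#' @return the clipped table, with attribute `n_clipped`.
#' @export
clip_outliers <- function(table, z_max = 3) {
  fc <- check_feature_table(table)
  n_clipped <- 0L
  for (f in fc) {
    v <- table[[f]]
    n_clipped <- n_clipped + sum(abs(v) > z_max)
    table[[f]] <- pmin(pmax(v, -z_max), z_max)
  }
  attr(table, "n_clipped") <- n_clipped
  table
}

#' Drop one member of every highly correlated feature pair
#'
#' Computes the Pearson correlation matrix of the features and, while any
#' pair exceeds the threshold in absolute value, removes one member of the
#' worst pair: the one with the larger mean absolute correlation to all other
#' remaining features (ties broken by feature-name order, so the result is
#' deterministic). Mitigates multicollinearity before fitting linear models.
#'
#' @param table a feature table with at least 3 rows.
#' @param threshold absolute correlation above which a pair is pruned
#'   (default 0.7).
#' @param protect feature names never to drop (their partners are dropped
#'   instead; a protected-protected pair is left in place with a warning).
#' @return the pruned table, with attribute `dropped_pairs`: a data.frame of
#'   `feature_a`, `feature_b`, `r`, `dropped`.
#' @export
prune_correlated <- function(table, threshold = 0.7, protect = character()) {
  fc <- check_feature_table(table)
  if (nrow(table) < 3) stop("need at least 3 rows to estimate correlations")
  kept <- fc
  log_rows <- list()
  repeat {
    if (length(kept) < 2) break
    cm <- abs(stats::cor(table[kept]))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- kept[idx[1]]
    b <- kept[idx[2]]
    pair <- sort(c(a, b))
    cand <- setdiff(pair, protect)
    if (!length(cand)) {
      warning("correlated pair ", pair[1], " / ", pair[2],
              " both protected; kept despite |r| > ", threshold)
      # zero this pair out of consideration by dropping it from the scan
      cm_protected <- TRUE
      # mark as handled: remove from further scans via a shadow matrix
      # (simplest: break if the only offending pairs are protected)
      offenders <- which(cm > threshold, arr.ind = TRUE)
      all_protected <- all(apply(offenders, 1, function(ij)
        all(kept[ij] %in% protect)))
      if (all_protected) break else next
    }
    if (length(cand) == 1) {
      drop <- cand
    } else {
      mean_r <- vapply(pair, function(f)
        mean(cm[f, setdiff(kept, f)]), numeric(1))
      drop <- if (diff(mean_r) == 0) pair[1] else pair[which.max(mean_r)]
    }
    r_signed <- stats::cor(table[[a]], table[[b]])
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(feature_a = pair[1], feature_b = pair[2], r = r_signed,
                 dropped = drop, stringsAsFactors = FALSE)
    kept <- setdiff(kept, drop)
  }
  out <- table[, c(meta_cols[meta_cols %in% names(table)], kept)]
  attr(out, "dropped_pairs") <- if (length(log_rows))
    do.call(rbind, log_rows) else
      data.frame(feature_a = character(), feature_b = character(),
                 r = numeric(), dropped = character())
  attr(out, "scaling") <- attr(table, "scaling")
  out
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

fit_linear <- function(x, y, model, cost = 1) {
  if (model == "logistic_regression") {
    # ridge-penalised logistic regression; lambda = 1/(n*C) matches the
    # standard unit-cost parameterisation of the penalised log-loss
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1 / (nrow(x) * cost),
                          standardize = FALSE)
    co <- as.numeric(stats::coef(fit))[-1]
    names(co) <- colnames(x)
    list(fit = fit, coefficients = co,
         predict = function(newx)
           factor(stats::predict(fit, newx = newx, type = "class")[, 1],
                  levels = levels(y)))
  } else {
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    names(w) <- colnames(x)
    # orient w so that a positive decision value means the second label
    # (e1071's internal sign depends on which class it saw first)
    dv <- drop(x %*% w) - fit$rho
    pred <- stats::predict(fit, x)
    agree <- mean((dv > 0) == (pred == levels(y)[2]))
    if (agree < 0.5) w <- -w
    list(fit = fit, coefficients = w,
         predict = function(newx)
           factor(as.character(stats::predict(fit, newx)),
                  levels = levels(y)))
  }
}

#' Cross-validated linear classification of growth condition
#'
#' Fits a linear classifier (L2-penalised logistic regression or a
#' linear-kernel SVM, both at unit cost) to discriminate the two labels of a
#' feature table under seeded stratified k-fold cross-validation. Accuracy is
#' reported per fold; the coefficients come from a final fit on the full
#' table, so they describe the model the whole data support.
#'
#' @param table a standardized (and optionally clipped/pruned) feature table.
#' @param model `"logistic_regression"` (alias `"lr"`) or `"linear_svm"`
#'   (alias `"svm"`).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param cost inverse regularisation strength (default 1).
#' @param standardize_in_fold if `TRUE`, standardization parameters are
#'   re-fitted on each training fold and applied to its test fold, instead of
#'   using the incoming (globally standardized) values.
#' @return a `classification_report`: fold accuracies, their mean and sd,
#'   named signed coefficients, retained feature names, fold assignment.
#' @export
crossval_classify <- function(table, model = c("logistic_regression",
                                               "linear_svm", "lr", "svm"),
                              k = 5, seed = 1L, cost = 1,
                              standardize_in_fold = FALSE) {
  model <- match.arg(model)
  model <- c(lr = "logistic_regression", svm = "linear_svm")[model] %|na|% model
  fc <- check_feature_table(table)
  y <- droplevels(factor(table$label))
  if (nlevels(y) != 2) stop("need exactly 2 label levels")
  if (min(table(y)) < 2) stop("need at least 2 rows per class")
  fold <- stratified_folds(y, k, seed)
  for (f in seq_len(k)) {
    if (!any(fold == f)) stop("empty fold; use a smaller k")
    if (min(table(y[fold != f])) < 2)
      stop("a training fold is left with fewer than 2 plants of a class; ",
           "use a smaller k")
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    tab_tr <- table[tr, , drop = FALSE]
    tab_te <- table[te, , drop = FALSE]
    if (standardize_in_fold) {
      tab_tr <- standardize_features(tab_tr)
      tab_te <- standardize_features(tab_te,
                                     scaling = attr(tab_tr, "scaling"))
    }
    xtr <- as.matrix(tab_tr[intersect(fc, names(tab_tr))])
    xte <- as.matrix(tab_te[intersect(fc, names(tab_te))])
    m <- fit_linear(xtr, y[tr], model, cost)
    acc[f] <- mean(m$predict(xte) == y[te])
  }
  full <- fit_linear(as.matrix(table[fc]), y, model, cost)
  structure(list(model = model, k = k, seed = seed,
                 fold_accuracies = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 coefficients = full$coefficients,
                 retained_features = fc, folds = fold,
                 positive_class = levels(y)[2],
                 dropped_pairs = attr(table, "dropped_pairs")),
            class = "classification_report")
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s, %d-fold CV\n", x$model, x$k))
  cat(sprintf("  accuracy: %.3f (sd %.3f); positive class: %s\n",
              x$mean_accuracy, x$sd_accuracy, x$positive_class))
  cat("  top coefficients:\n")
  imp <- feature_importance(x)
  for (i in seq_len(min(4, nrow(imp))))
    cat(sprintf("    %-28s %+.3f\n", imp$feature[i], imp$coefficient[i]))
  invisible(x)
}

#' Rank features by the magnitude of their model coefficients
#'
#' With standardized inputs, the absolute coefficient measures how strongly a
#' feature drives the decision and its sign the direction: positive pushes
#' toward the positive class (the second label level, `social` in the default
#' tables).
#'
#' @param report a `classification_report`.
#' @return data.frame `feature`, `coefficient`, ordered by decreasing
#'   `|coefficient|`.
#' @export
feature_importance <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  co <- report$coefficients
  ord <- order(abs(co), decreasing = TRUE)
  data.frame(feature = names(co)[ord], coefficient = unname(co[ord]),
             row.names = NULL)
}

#' Cross-validated accuracy under label permutation
#'
#' Repeats the cross-validation with labels randomly permuted; the resulting
#' accuracies form the chance-level null distribution against which the
#' observed accuracy can be judged.
#'
#' @param table a standardized feature table.
#' @param model,k,cost as in [crossval_classify()].
#' @param n_perm number of permutations.
#' @param seed integer seed (drives both permutations and fold assignment).
#' @return numeric vector of `n_perm` mean CV accuracies.
#' @export
permutation_accuracy <- function(table, model = "logistic_regression",
                                 k = 5, n_perm = 100, seed = 1L, cost = 1) {
  perms <- with_seed(seed, replicate(n_perm, sample(nrow(table)),
                                     simplify = FALSE))
  vapply(seq_len(n_perm), function(i) {
    tab <- table
    tab$label <- table$label[perms[[i]]]
    crossval_classify(tab, model = model, k = k,
                      seed = derive_seed(seed, i),
                      cost = cost)$mean_accuracy
  }, numeric(1))
}
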