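# Classifier-based evaluation: t-test feature selection, a linear-margin
# classifier (linear-kernel SVM, C = 1, train-standardised features) and
# Gaussian naive Bayes, scored by the balanced average accuracy
# Aacc = (acc(NC) + acc(PD)) / 2 so that unbalanced cohorts still put a
# random classifier at 0.5.

#' Select the most discriminating region pairs by t-test
#'
#' Ranks pairs by the absolute Welch t statistic of the NC-vs-PD contrast on
#' the *training* FC matrix and returns the top `n` canonical pair indices
#' (ties broken by ascending pair index). Test data must never enter this
#' step.
#'
#' @param fc Training FC matrix (scans by pairs).
#' @param group Character vector of `"NC"`/`"PD"` labels, one per row.
#' @param n Number of features to keep (`<= P`).
#' @return An integer vector of `n` pair indices.
#' @export
select_features <- function(fc, group, n) {
  check_count(n, min = 1)
  if (n > ncol(fc)) {
    abort("`n` exceeds the number of region pairs.",
          class = "fcrepro_parameter_error")
  }
  st <- welch_t_stats(fc, group == "NC")
  order(-abs(st$t), seq_len(ncol(fc)))[seq_len(n)]
}

# --- internal classifiers ---------------------------------------------------

fit_linear_svm <- function(x, y) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  model <- e1071::svm(z, factor(y, levels = c("NC", "PD")),
                      kernel = "linear", cost = 1, scale = FALSE)
  list(model = model, mu = mu, sd = sdv)
}

predict_linear_svm <- function(fit, x) {
  z <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, "/")
  as.character(stats::predict(fit$model, z))
}

# Gaussian naive Bayes with per-class means/variances; variances are floored
# at 1e-9 x the largest feature variance so a degenerate feature cannot blow
# up the log-likelihood.
fit_gnb <- function(x, y) {
  classes <- c("NC", "PD")
  floor_v <- 1e-9 * max(apply(x, 2, var), .Machine$double.eps)
  stats_by <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mu = colMeans(xc), v = pmax(apply(xc, 2, var), floor_v))
  })
  names(stats_by) <- classes
  prior <- table(factor(y, levels = classes)) / length(y)
  list(stats = stats_by, log_prior = log(as.numeric(prior) + 1e-300),
       classes = classes)
}

predict_gnb <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(i) {
    st <- fit$stats[[i]]
    fit$log_prior[i] - 0.5 * colSums(
      (t(x) - st$mu)^2 / st$v + log(2 * pi * st$v))
  }, numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

fit_classifier <- function(classifier, x, y) {
  switch(classifier,
         linear_svm = fit_linear_svm(x, y),
         gnb = fit_gnb(x, y))
}

predict_classifier <- function(classifier, fit, x) {
  switch(classifier,
         linear_svm = predict_linear_svm(fit, x),
         gnb = predict_gnb(fit, x))
}

a_acc_from_predictions <- function(truth, predicted) {
  acc_nc <- mean(predicted[truth == "NC"] == "NC")
  acc_pd <- mean(predicted[truth == "PD"] == "PD")
  tibble(acc_nc = acc_nc, acc_pd = acc_pd, a_acc = (acc_nc + acc_pd) / 2)
}

#' Train on one collection, test on another
#'
#' Selects `n_features` pairs on the training collection only, fits the
#' requested classifier, predicts every test scan, and reports per-class
#' accuracies and their balanced mean `a_acc`. Training and test scan sets
#' must be disjoint unless `allow_overlap = TRUE` (resubstitution, logged).
#'
#' @param train,test Scan collections sharing a parcellation; the test
#'   collection must contain both classes.
#' @param classifier `"linear_svm"` or `"gnb"`.
#' @param n_features Number of selected region pairs.
#' @param allow_overlap Permit overlapping train/test scans (default off).
#' @param fc_train,fc_test Optional precomputed FC matrices.
#' @return A one-row tibble: `train_id`, `test_id`, `classifier`,
#'   `n_features`, `acc_nc`, `acc_pd`, `a_acc`.
#' @export
evaluate <- function(train, test, classifier = c("linear_svm", "gnb"),
                     n_features = 100, allow_overlap = FALSE,
                     fc_train = NULL, fc_test = NULL) {
  classifier <- match.arg(classifier)
  train <- validate_collection(train)
  test <- validate_collection(test)
  overlap <- intersect(paste(train$dataset_id, train$scan_id),
                       paste(test$dataset_id, test$scan_id))
  if (length(overlap)) {
    if (!allow_overlap) {
      abort("train and test collections share scans; set allow_overlap = TRUE for resubstitution.",
            class = "fcrepro_evaluation_error")
    }
    warn("train/test scan overlap: reporting resubstitution accuracy.")
  }
  if (length(setdiff(c("NC", "PD"), unique(test$group)))) {
    abort("test collection must contain both classes.",
          class = "fcrepro_evaluation_error")
  }
  if (is.null(fc_train)) fc_train <- fc_matrix(train)
  if (is.null(fc_test)) fc_test <- fc_matrix(test)
  feats <- select_features(fc_train, train$group, n_features)
  fit <- fit_classifier(classifier, fc_train[, feats, drop = FALSE],
                        train$group)
  pred <- predict_classifier(classifier, fit,
                             fc_test[, feats, drop = FALSE])
  acc <- a_acc_from_predictions(test$group, pred)
  tibble(train_id = train$dataset_id[1], test_id = test$dataset_id[1],
         classifier = classifier, n_features = as.integer(n_features),
         acc_nc = acc$acc_nc, acc_pd = acc$acc_pd, a_acc = acc$a_acc)
}

#' Repeated stratified half-splits of one collection
#'
#' For each repeat: split the collection in half (stratified by group, at
#' subject level by default so replicate scans never straddle the train/test
#' boundary), train on one half, test on the other, and record `a_acc`.
#'
#' @param scans A scan collection.
#' @param classifier `"linear_svm"` or `"gnb"`.
#' @param n_features Features per repeat (selected on the training half).
#' @param n_repeats Number of random half-splits (default 500).
#' @param seed Integer seed or `NULL`.
#' @param split_unit `"subject"` (default) or `"scan"`: the unit randomised
#'   into halves.
#' @param permute_labels If `TRUE`, the group labels are freshly permuted
#'   (at `split_unit` level) before every repeat — the randomized-label null
#'   under which a classifier can only reach chance, `a_acc = 0.5`, on
#'   average. Default `FALSE`.
#' @return An object of class `fc_split_half`: the per-repeat `a_acc` values
#'   with their mean and standard deviation. `tidy()`/`glance()` methods
#'   included.
#' @export
split_half_batch <- function(scans, classifier = c("linear_svm", "gnb"),
                             n_features = 100, n_repeats = 500, seed = NULL,
                             split_unit = c("subject", "scan"),
                             permute_labels = FALSE) {
  classifier <- match.arg(classifier)
  split_unit <- match.arg(split_unit)
  check_count(n_repeats, min = 1)
  scans <- validate_collection(scans)
  fc <- fc_matrix(scans)
  accs <- with_seed_if(seed, vapply(seq_len(n_repeats), function(i) {
    group <- if (permute_labels) {
      permute_group(scans$subject_id, scans$group,
                    if (split_unit == "subject") "subject" else "scan")
    } else {
      scans$group
    }
    if (split_unit == "subject") {
      side1 <- character()
      for (grp in c("NC", "PD")) {
        subj <- unique(scans$subject_id[group == grp])
        if (length(subj) < 2) {
          abort(sprintf("group %s has fewer than 2 subjects.", grp),
                class = "fcrepro_split_error")
        }
        subj <- sample(subj)
        side1 <- c(side1, subj[seq_len(ceiling(length(subj) / 2))])
      }
      in_train <- scans$subject_id %in% side1
    } else {
      in_train <- logical(nrow(scans))
      for (grp in c("NC", "PD")) {
        rows <- which(group == grp)
        rows <- sample(rows)
        in_train[rows[seq_len(ceiling(length(rows) / 2))]] <- TRUE
      }
    }
    feats <- select_features(fc[in_train, , drop = FALSE],
                             group[in_train], n_features)
    fit <- fit_classifier(classifier, fc[in_train, feats, drop = FALSE],
                          group[in_train])
    pred <- predict_classifier(classifier, fit,
                               fc[!in_train, feats, drop = FALSE])
    a_acc_from_predictions(group[!in_train], pred)$a_acc
  }, numeric(1)))
  structure(list(
    a_acc = accs,
    mean = mean(accs),
    sd = sd(accs),
    classifier = classifier,
    n_features = as.integer(n_features),
    n_repeats = n_repeats,
    split_unit = split_unit,
    permute_labels = permute_labels,
    seed = seed
  ), class = "fc_split_half")
}

#' @export
print.fc_split_half <- function(x, ...) {
  cat(sprintf(
    "<fc_split_half> %s, %d features, %d repeats: mean Aacc = %.3f (sd %.3f)\n",
    x$classifier, x$n_features, x$n_repeats, x$mean, x$sd))
  invisible(x)
}

#' @export
tidy.fc_split_half <- function(x, ...) {
  tibble(repeat_index = seq_along(x$a_acc), a_acc = x$a_acc)
}

#' @export
glance.fc_split_half <- function(x, ...) {
  tibble(classifier = x$classifier, n_features = x$n_features,
         n_repeats = x$n_repeats, mean_a_acc = x$mean, sd_a_acc = x$sd)
}

#' Aggregated accuracy over one training dataset's evaluations
#'
#' The arithmetic mean of the `a_acc` values of the evaluations of a single
#' training dataset against each of the other datasets.
#'
#' @param eval_results A tibble of [evaluate()] rows sharing one `train_id`.
#' @return A single number.
#' @export
aggregate_accuracy <- function(eval_results) {
  stopifnot(is.data.frame(eval_results), nrow(eval_results) >= 1)
  if (length(unique(eval_results$train_id)) != 1) {
    abort("aggregate_accuracy() expects evaluations of a single training dataset.",
          class = "fcrepro_parameter_error")
  }
  mean(eval_results$a_acc)
}
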