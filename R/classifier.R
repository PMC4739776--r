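#' Training configuration for the ORF classifier
#'
#' Defaults mirror the published procedure: 600 positive and 300 negative
#' examples for training and the same again for testing, a radial-basis
#' SVM tuned by five-fold cross-validation, a probability cutoff of 0.7,
#' and an expression filter requiring RPKM > 1 and more than 10 reads.
#'
#' @param n_pos_train,n_neg_train,n_pos_test,n_neg_test sample sizes drawn
#'   without replacement from the positive/negative pools.
#' @param cv_folds cross-validation folds.
#' @param prob_cutoff probability at or above which an ORF is called
#'   translated.
#' @param rpkm_min,reads_min expression filter: RPKM above `rpkm_min` in at
#'   least one sample group and strictly more than `reads_min` reads.
#' @param cost_grid,gamma_grid RBF hyperparameter grids searched by CV.
#' @param seed RNG seed for sampling and fold assignment.
#' @return A list of class `ribocall_training_spec`.
#' @export
training_spec <- function(n_pos_train = 600L, n_neg_train = 300L,
                          n_pos_test = 600L, n_neg_test = 300L,
                          cv_folds = 5L, prob_cutoff = 0.7,
                          rpkm_min = 1, reads_min = 10L,
                          cost_grid = c(0.1, 1, 10, 100),
                          gamma_grid = c(0.01, 0.1, 1, 10),
                          seed = 1L) {
  stopifnot(prob_cutoff > 0, prob_cutoff < 1, cv_folds >= 2)
  structure(list(
    n_pos_train = n_pos_train, n_neg_train = n_neg_train,
    n_pos_test = n_pos_test, n_neg_test = n_neg_test,
    cv_folds = cv_folds, prob_cutoff = prob_cutoff,
    rpkm_min = rpkm_min, reads_min = reads_min,
    cost_grid = cost_grid, gamma_grid = gamma_grid, seed = seed
  ), class = "ribocall_training_spec")
}

FEATURE_COLS <- c("f1", "f2", "pme")

apply_expression_filter <- function(features, spec) {
  filter(features, .data$rpkm > spec$rpkm_min,
         .data$n_reads > spec$reads_min)
}

#' Build labelled training and test sets
#'
#' Positives are expressed canonical ORFs; negatives are expressed
#' off-frame AUG ORFs inside coding regions (`internal` type) and candidate
#' ORFs in short non-coding RNAs. Both pools are filtered by the expression
#' rule (RPKM > 1, more than 10 reads), then train and test examples are
#' drawn disjointly without replacement under `spec$seed`. Feature columns
#' are `f1`, `f2` and `pme` (`f3` is redundant by normalisation).
#'
#' @param features feature tibble from [orf_features()] carrying a `label`
#'   column with values `"positive"`/`"negative"`, e.g. from
#'   [label_training_pools()].
#' @param spec a [training_spec()].
#' @return List with `train` and `test` tibbles (feature columns plus
#'   `label` factor) and the pool sizes.
#' @export
build_training_sets <- function(features, spec = training_spec()) {
  d <- apply_expression_filter(features, spec)
  pos <- filter(d, .data$label == "positive")
  neg <- filter(d, .data$label == "negative")
  need_pos <- spec$n_pos_train + spec$n_pos_test
  need_neg <- spec$n_neg_train + spec$n_neg_test
  if (nrow(pos) < need_pos || nrow(neg) < need_neg) {
    abort(sprintf(paste0(
      "training pools too small: %d positives (need %d), %d negatives ",
      "(need %d) after the expression filter"),
      nrow(pos), need_pos, nrow(neg), need_neg))
  }
  set.seed(spec$seed)
  pi <- sample.int(nrow(pos), need_pos)
  ni <- sample.int(nrow(neg), need_neg)
  take <- function(d, idx) select(d[idx, ], dplyr::all_of(FEATURE_COLS),
                                  "label", "orf_id")
  train <- bind_rows(take(pos, pi[seq_len(spec$n_pos_train)]),
                     take(neg, ni[seq_len(spec$n_neg_train)]))
  test <- bind_rows(take(pos, pi[spec$n_pos_train + seq_len(spec$n_pos_test)]),
                    take(neg, ni[spec$n_neg_train + seq_len(spec$n_neg_test)]))
  train$label <- factor(train$label, levels = c("negative", "positive"))
  test$label <- factor(test$label, levels = c("negative", "positive"))
  list(train = train, test = test,
       pool_sizes = c(positive = nrow(pos), negative = nrow(neg)))
}

#' Label classifier training pools
#'
#' Marks canonical ORFs as positives and internal AUG-start ORFs plus
#' ORFs on short non-coding RNAs as negatives; all other ORFs get `NA`.
#'
#' @param features feature tibble including `orf_type` and `start_codon`.
#' @param transcripts transcript tibble with `biotype`.
#' @return `features` with a `label` column.
#' @export
label_training_pools <- function(features, transcripts) {
  bt <- setNames(transcripts$biotype, transcripts$transcript_id)
  lab <- rep(NA_character_, nrow(features))
  lab[features$orf_type == "canonical"] <- "positive"
  neg <- (features$orf_type == "internal" &
            features$start_codon == "AUG") |
    (bt[features$transcript_id] %in% "short_ncRNA")
  lab[neg] <- "negative"
  mutate(features, label = lab)
}

#' Train the translated-ORF classifier
#'
#' Fits a radial-basis SVM on `(f1, f2, pme)` with hyperparameters chosen
#' by k-fold cross-validation over a `(cost, gamma)` grid; the selection
#' criterion is mean held-out AUC. Probabilities come from Platt scaling
#' (`e1071::svm(probability = TRUE)`).
#'
#' @param train labelled training tibble from [build_training_sets()].
#' @param spec a [training_spec()].
#' @return Object of class `orf_classifier` with the fitted SVM, the CV
#'   grid results and the chosen hyperparameters.
#' @export
train_orf_classifier <- function(train, spec = training_spec()) {
  if (length(unique(train$label)) < 2) {
    abort("training set must contain both classes")
  }
  x <- as.matrix(train[, FEATURE_COLS])
  y <- factor(train$label, levels = c("negative", "positive"))
  set.seed(spec$seed)
  folds <- sample(rep_len(seq_len(spec$cv_folds), nrow(train)))
  grid <- expand.grid(cost = spec$cost_grid, gamma = spec$gamma_grid)
  cv <- t(vapply(seq_len(nrow(grid)), function(g) {
    per_fold <- vapply(seq_len(spec$cv_folds), function(k) {
      tr <- folds != k
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        probability = TRUE)
      pr <- attr(predict(fit, x[!tr, , drop = FALSE], probability = TRUE),
                 "probabilities")[, "positive"]
      if (length(unique(y[!tr])) < 2) return(c(NA_real_, NA_real_))
      truth <- y[!tr] == "positive"
      c(attr(roc_curve(pr, truth), "auc"), mean((pr - truth)^2))
    }, numeric(2))
    c(cv_auc = mean(per_fold[1, ], na.rm = TRUE),
      cv_brier = mean(per_fold[2, ], na.rm = TRUE))
  }, numeric(2)))
  grid$cv_auc <- cv[, "cv_auc"]
  grid$cv_brier <- cv[, "cv_brier"]
  # AUC ranks ranking quality; the Brier score breaks ties toward a
  # well-calibrated probability scale (a flat Platt sigmoid can rank
  # perfectly yet never cross the call cutoff)
  best <- grid[order(-grid$cv_auc, grid$cv_brier, grid$cost, grid$gamma)[1], ]
  set.seed(spec$seed)
  fit <- e1071::svm(x, y, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, probability = TRUE)
  structure(list(fit = fit, grid = as_tibble(grid),
                 cost = best$cost, gamma = best$gamma,
                 cv_auc = best$cv_auc, n_train = nrow(train),
                 spec = spec),
            class = "orf_classifier")
}

#' @export
print.orf_classifier <- function(x, ...) {
  cat("<orf_classifier> radial-basis SVM on (f1, f2, pme)\n",
      sprintf("  cost = %g, gamma = %g (CV AUC = %.4f, n = %d)\n",
              x$cost, x$gamma, x$cv_auc, x$n_train), sep = "")
  invisible(x)
}

#' Predicted translation probabilities
#'
#' @param object an `orf_classifier`.
#' @param newdata tibble with columns `f1`, `f2`, `pme`.
#' @param ... unused.
#' @return `newdata` with a `prob_translated` column.
#' @export
predict.orf_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, FEATURE_COLS])
  pr <- attr(predict(object$fit, x, probability = TRUE),
             "probabilities")[, "positive"]
  mutate(newdata, prob_translated = unname(pr))
}

#' @exportS3Method generics::tidy
tidy.orf_classifier <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.orf_classifier <- function(x, ...) {
  tibble(cost = x$cost, gamma = x$gamma, cv_auc = x$cv_auc,
         n_train = x$n_train, cv_folds = x$spec$cv_folds,
         seed = x$spec$seed)
}

#' ROC curve and AUC
#'
#' Computes the full ROC (true positive rate against false positive rate
#' over all score thresholds) and the trapezoidal AUC.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (or coercible) true labels.
#' @return Tibble of class `ribocall_roc` with `threshold`, `fpr`, `tpr`;
#'   the AUC is in `attr(, "auc")` and via [glance()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    abort("ROC requires both classes in the labels")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(l))
  fpr <- c(0, fp[keep] / sum(!l))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  out <- tibble(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr)
  structure(out, class = c("ribocall_roc", class(out)), auc = auc)
}

#' @exportS3Method generics::glance
glance.ribocall_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_points = nrow(x))
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model an `orf_classifier`.
#' @param test labelled tibble from [build_training_sets()].
#' @param cutoff probability cutoff for FPR/FNR reporting.
#' @return List with the `ribocall_roc` curve, `auc`, and `fpr`/`fnr` at
#'   the cutoff.
#' @export
evaluate_classifier <- function(model, test,
                                cutoff = model$spec$prob_cutoff) {
  pr <- predict(model, test)$prob_translated
  truth <- test$label == "positive"
  roc <- roc_curve(pr, truth)
  called <- pr >= cutoff
  list(roc = roc, auc = attr(roc, "auc"),
       fpr = sum(called & !truth) / sum(!truth),
       fnr = sum(!called & truth) / sum(truth))
}

#' Call translated ORFs
#'
#' Applies the expression filter, scores every remaining candidate ORF,
#' calls ORFs at the probability cutoff, and collapses called ORFs sharing
#' a stop codon to one representative start.
#'
#' @param model an `orf_classifier`.
#' @param features feature tibble from [orf_features()] (with `orf_type`).
#' @param profiles A-site profile tibble (for representative-start
#'   selection).
#' @param spec a [training_spec()]; supplies cutoff and expression filter.
#' @return List with `predictions` (all scored ORFs with `prob_translated`
#'   and `call`), `called` (representative called ORFs) and `summary`
#'   (counts by `orf_type`).
#' @export
call_orfs <- function(model, features, profiles, spec = model$spec) {
  scored <- apply_expression_filter(features, spec)
  scored <- predict(model, scored)
  scored$call <- scored$prob_translated >= spec$prob_cutoff
  called <- filter(scored, .data$call)
  rep_orfs <- collapse_stop_groups(called, profiles)
  list(predictions = scored,
       called = rep_orfs,
       summary = count(rep_orfs, .data$orf_type, name = "n_orfs"))
}
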