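# labelled feature pool with a clear positive/negative structure
make_pool <- function(n_pos, n_neg, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    orf_id = paste0("o", seq_len(n_pos + n_neg)),
    f1 = c(pmin(pmax(rnorm(n_pos, 0.65, 0.05), 0), 1),
           pmin(pmax(rnorm(n_neg, 0.20, 0.08), 0), 1)),
    f2 = c(pmin(pmax(rnorm(n_pos, 0.24, 0.04), 0), 1),
           pmin(pmax(rnorm(n_neg, 0.30, 0.10), 0), 1)),
    pme = c(pmin(pmax(rnorm(n_pos, 0.9, 0.05), 0), 1),
            pmin(pmax(rnorm(n_neg, 0.3, 0.15), 0), 1)),
    n_reads = 100L, rpkm = 50,
    label = rep(c("positive", "negative"), c(n_pos, n_neg))
  )
}

test_that("training-set construction is disjoint, sized and reproducible", {
  pool <- make_pool(1500, 800)
  spec <- training_spec(seed = 1L)
  sets <- build_training_sets(pool, spec)
  expect_equal(table(sets$train$label)[["positive"]], 600L)
  expect_equal(table(sets$train$label)[["negative"]], 300L)
  expect_equal(table(sets$test$label)[["positive"]], 600L)
  expect_equal(table(sets$test$label)[["negative"]], 300L)
  expect_length(intersect(sets$train$orf_id, sets$test$orf_id), 0L)
  sets2 <- build_training_sets(pool, spec)
  expect_identical(sets$train$orf_id, sets2$train$orf_id)
  # pool too small
  expect_error(build_training_sets(make_pool(100, 800), spec),
               "pools too small")
})

test_that("the expression filter removes weak ORFs before scoring", {
  pool <- make_pool(20, 20)
  pool$n_reads[1] <- 10L    # exactly 10 reads: excluded (rule is > 10)
  pool$rpkm[2] <- 0.5       # RPKM below 1: excluded
  spec <- training_spec(n_pos_train = 5, n_neg_train = 5,
                        n_pos_test = 5, n_neg_test = 5)
  d <- build_training_sets(pool, spec)
  expect_equal(unname(d$pool_sizes), c(18L, 20L))
})

test_that("ROC and AUC agree with exhaustive pair counting", {
  # perfect separation
  r <- roc_curve(c(.9, .8, .7, .1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(r, "auc"), 1)
  # hand-built: pos .9/.6, neg .7/.1 -> 3 of 4 pairs correct
  r2 <- roc_curve(c(.9, .6, .7, .1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(r2, "auc"), 0.75)
  # constant scores -> chance
  r3 <- roc_curve(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(attr(r3, "auc"), 0.5)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals the Mann-Whitney U normalisation", {
  set.seed(53)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    # independent oracle: count concordant pairs directly
    pos <- scores[labels]; neg <- scores[!labels]
    u <- sum(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(attr(roc_curve(scores, labels), "auc"), u / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("training separates a separable pool and is reproducible", {
  pool <- make_pool(80, 80)
  spec <- training_spec(n_pos_train = 30, n_neg_train = 30,
                        n_pos_test = 30, n_neg_test = 30, seed = 2L)
  sets <- build_training_sets(pool, spec)
  model <- train_orf_classifier(sets$train, spec)
  ev <- evaluate_classifier(model, sets$test)
  expect_gt(ev$auc, 0.99)
  # probabilities invariant to row order; training reproducible
  pr1 <- predict(model, sets$test)$prob_translated
  perm <- sample(nrow(sets$test))
  pr2 <- predict(model, sets$test[perm, ])$prob_translated
  expect_equal(pr2, pr1[perm], tolerance = 1e-9)
  model2 <- train_orf_classifier(sets$train, spec)
  expect_equal(predict(model2, sets$test)$prob_translated, pr1,
               tolerance = 1e-9)
  expect_error(train_orf_classifier(
    dplyr::filter(sets$train, label == "positive"), spec), "both classes")
  # broom-style accessors
  expect_true(all(c("cost", "gamma", "cv_auc") %in% names(tidy(model))))
  expect_equal(nrow(glance(model)), 1L)
})

test_that("calls obey the probability cutoff", {
  pool <- make_pool(60, 60)
  spec <- training_spec(n_pos_train = 20, n_neg_train = 20,
                        n_pos_test = 20, n_neg_test = 20, seed = 3L)
  sets <- build_training_sets(pool, spec)
  model <- train_orf_classifier(sets$train, spec)
  feats <- dplyr::mutate(pool,
                         transcript_id = orf_id, start = 0L, stop = 30L,
                         start_codon = "AUG", orf_type = "noncoding_ORF")
  profiles <- tibble::tibble(transcript_id = feats$transcript_id,
                             n_reads = 0L,
                             profile = lapply(seq_len(nrow(feats)),
                                              function(i) integer(30)))
  res <- call_orfs(model, feats, profiles, spec)
  expect_true(all(res$predictions$call ==
                    (res$predictions$prob_translated >= 0.7)))
  expect_true(all(res$called$prob_translated >= 0.7))
})
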