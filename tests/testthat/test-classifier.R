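# Balanced sampling, SVM fitting/prediction, chain-level cross-validation.

test_that("balanced sampling keeps all positives and matches counts", {
  labels <- c(rep("binding", 30), rep("nonbinding", 300))
  sel <- balanced_sample(labels, seed = 4)
  expect_length(sel, 60)
  expect_true(all(1:30 %in% sel))
  expect_equal(sum(labels[sel] == "nonbinding"), 30)
  # reproducible for a fixed seed, distinct across seeds
  expect_identical(sel, balanced_sample(labels, seed = 4))
  expect_false(identical(sel, balanced_sample(labels, seed = 5)))

  few <- c(rep("binding", 30), rep("nonbinding", 20))
  expect_warning(sel2 <- balanced_sample(few, seed = 1), "keeping all")
  expect_length(sel2, 50)
})

test_that("fold assignment is chain-level with near-equal sizes", {
  ids <- sprintf("c%03d", 1:123)
  f <- fold_chains(ids, k = 5, seed = 2)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(25L, 25L, 25L, 24L, 24L))
  expect_equal(sort(names(f)), sort(ids))  # every chain exactly once
})

test_that("the SVM separates separable toy data and scores monotonically", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, 3), 30, 2), matrix(rnorm(60, -3), 30, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("binding", "nonbinding"), each = 30)
  m <- dbp_fit(x, y, seed = 1)
  pred <- predict(m, x)
  expect_equal(pred$label, y)  # training accuracy 1 on separable data
  expect_true(all(pred$score[1:30] > 0), all(pred$score[31:60] < 0))

  # thresholding contracts
  expect_true(all(predict(m, x, threshold = Inf)$label == "nonbinding"))
  expect_true(all(predict(m, x, threshold = -Inf)$label == "binding"))
  p1 <- predict(m, x, threshold = -0.5)$label == "binding"
  p2 <- predict(m, x, threshold = 0.5)$label == "binding"
  expect_true(all(!p2 | p1))  # stricter threshold predicts a subset

  expect_error(predict(m, x[, 1, drop = FALSE]), "f2")
  expect_error(dbp_fit(x, rep("binding", 60)), "single class")
})

test_that("zero-variance feature columns are tolerated", {
  set.seed(9)
  x <- cbind(sig = c(rnorm(20, 2), rnorm(20, -2)), flat = rep(1, 40))
  y <- rep(c("binding", "nonbinding"), each = 20)
  m <- dbp_fit(x, y)
  pred <- predict(m, x)
  expect_true(all(is.finite(pred$score)))  # constant column is not NaN-scaled
  expect_gt(mean(pred$label == y), 0.9)
})

test_that("cross-validation is chain-level, reproducible and leakage-free", {
  ds <- small_dataset(n_chains = 6, seed = 42)
  cv <- dbp_cv(ds, k = 3, seed = 7)
  expect_s3_class(cv, "dbp_cv")
  expect_equal(nrow(cv$fold_metrics), 3)
  # every chain is tested exactly once
  tested <- unique(cv$scores[, c("fold", "chain")])
  expect_equal(sort(tested$chain),
               sort(vapply(ds$chains, `[[`, character(1), "id")))
  expect_equal(nrow(tested), 6)
  # every surface residue of every chain is scored (none removed)
  n_surface <- sum(vapply(ds$chains, function(ch)
    sum(ch$annotation$is_surface), numeric(1)))
  expect_equal(nrow(cv$scores), n_surface)

  # bit-identical reruns under the same seed
  cv2 <- dbp_cv(ds, k = 3, seed = 7)
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
  expect_identical(cv$scores, cv2$scores)

  # the propensity table depends only on training folds: rebuilding it
  # from the training chains of fold 1 gives the table the fold used
  ids <- names(cv$folds)
  train_chains <- ds$chains[match(ids[cv$folds != 1],
                                  vapply(ds$chains, `[[`, character(1),
                                         "id"))]
  tab <- do.call(rbind, lapply(train_chains, function(ch)
    ch$annotation[ch$annotation$is_surface, c("resname", "binding_label")]))
  ip_train <- interface_propensity(tab$resname, tab$binding_label)
  expect_false(any(is.na(ip_train$ip)))
  expect_equal(ip_train$n_b + ip_train$n_nb, nrow(tab))
})

test_that("a planted feature signal is recovered while permuted labels are not", {
  ds <- small_dataset(n_chains = 8, seed = 12)
  cv <- dbp_cv(ds, k = 4, seed = 3)
  prevalence <- mean(cv$scores$label == "binding")
  expect_gt(cv$mean$pr_auc, 2 * prevalence)

  # permuting labels within each chain destroys the signal
  ds_null <- ds
  set.seed(77)
  ds_null$chains <- lapply(ds_null$chains, function(ch) {
    s <- ch$annotation$is_surface
    ch$annotation$binding_label[s] <- sample(ch$annotation$binding_label[s])
    ch
  })
  cv_null <- dbp_cv(ds_null, k = 4, seed = 3)
  expect_lt(cv_null$mean$pr_auc, cv$mean$pr_auc)
  expect_lt(abs(cv_null$mean$pr_auc - prevalence), 0.15)
})
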