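# RBF-SVM training with balanced sampling and chain-level cross-validation.

#' Balanced undersampling of the nonbinding class
#'
#' Keeps every binding example and samples an equal number of nonbinding
#' examples without replacement. When fewer nonbinding than binding
#' examples exist, all of both classes are kept with a warning.
#'
#' @param labels character/factor vector with values "binding" /
#'   "nonbinding".
#' @param seed integer seed making the selection reproducible.
#' @return Integer indices of the selected examples (positives first).
#' @export
balanced_sample <- function(labels, seed = 1) {
  pos <- which(labels == "binding")
  neg <- which(labels == "nonbinding")
  if (!length(pos) || !length(neg))
    stop("need at least one binding and one nonbinding example")
  if (length(neg) < length(pos)) {
    warning("fewer nonbinding than binding examples; keeping all of both")
    return(c(pos, neg))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  c(pos, sort(sample(neg, length(pos))))
}

# Save/restore the global RNG state so that seeded helpers do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit the RBF-kernel SVM residue classifier
#'
#' Trains a radial-basis-function support vector machine (via
#' \pkg{e1071}/LibSVM) on a feature matrix of surface residues. Columns are
#' z-scored with statistics of the training data (zero-variance columns are
#' centred and left unscaled); the same transform is applied at prediction
#' time. The fitted object produces a continuous decision score oriented so
#' that larger means more binding-like.
#'
#' @param x numeric feature matrix (rows = residues).
#' @param y labels, "binding" / "nonbinding" (character or factor).
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; defaults to 1/ncol(x).
#' @param seed seed for LibSVM's internal shuffling.
#' @return Object of class `dbp_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
dbp_fit <- function(x, y, cost = 1, gamma = 1 / ncol(x), seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  yf <- factor(y, levels = c("binding", "nonbinding"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- e1071::svm(xs, yf, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  # orient the decision score: positive = binding
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- mean(dv[yf == "binding"]) < mean(dv[yf == "nonbinding"])
  out <- list(svm = fit, center = ctr, scale = scl, schema = colnames(x),
              flip = flip, cost = cost, gamma = gamma,
              n_binding = sum(yf == "binding"),
              n_nonbinding = sum(yf == "nonbinding"))
  class(out) <- "dbp_model"
  out
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("RBF-SVM DNA-binding residue classifier\n")
  cat(sprintf("  features: %d  cost: %g  gamma: %g\n",
              length(x$schema), x$cost, x$gamma))
  cat(sprintf("  trained on %d binding / %d nonbinding residues (%d SVs)\n",
              x$n_binding, x$n_nonbinding, nrow(x$svm$SV)))
  invisible(x)
}

#' @export
summary.dbp_model <- function(object, ...) {
  print(object)
  cat("  feature columns:\n   ",
      paste(utils::head(object$schema, 6), collapse = ", "),
      if (length(object$schema) > 6) ", ..." else "", "\n")
  invisible(object)
}

#' Score surface residues with a fitted classifier
#'
#' Returns the continuous decision score for every row of `newdata`
#' (larger = more binding-like) and the thresholded label. Prediction never
#' filters residues: every surface residue supplied is scored.
#'
#' @param object a `dbp_model`.
#' @param newdata feature matrix with the training columns.
#' @param threshold decision threshold on the signed score (default 0).
#' @param ... unused.
#' @return Data frame with `score` and `label` ("binding"/"nonbinding"),
#'   row names carried over from `newdata`.
#' @export
predict.dbp_model <- function(object, newdata, threshold = 0, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$schema, colnames(newdata))
  if (length(missing))
    stop("feature columns missing from newdata: ",
         paste(missing, collapse = ", "))
  xs <- scale(newdata[, object$schema, drop = FALSE],
              center = object$center, scale = object$scale)
  dv <- attr(stats::predict(object$svm, xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (object$flip) dv <- -dv
  data.frame(key = if (is.null(rownames(newdata)))
               rep(NA_character_, length(dv)) else rownames(newdata),
             score = unname(dv),
             label = ifelse(dv >= threshold, "binding", "nonbinding"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign chains to cross-validation folds
#'
#' Chains (never residues) are shuffled and dealt round-robin into `k`
#' folds, so fold sizes differ by at most one chain.
#'
#' @param chain_ids chain identifiers.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return Named integer vector mapping each chain to its fold.
#' @export
fold_chains <- function(chain_ids, k = 5, seed = 1) {
  stopifnot(length(chain_ids) >= k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(length(chain_ids))
  fold <- integer(length(chain_ids))
  fold[perm] <- rep_len(seq_len(k), length(chain_ids))
  stats::setNames(fold, chain_ids)
}

# Surface rows (resnames + labels) of a list of prepared chains.
.surface_table <- function(chains) {
  do.call(rbind, lapply(chains, function(ch) {
    s <- ch$annotation[ch$annotation$is_surface, ]
    data.frame(chain = ch$id, key = s$key, resname = s$resname,
               label = s$binding_label, stringsAsFactors = FALSE)
  }))
}

#' Chain-level k-fold cross-validation of the full pipeline
#'
#' Splits the dataset's chains into `k` folds; for each fold, derives the
#' interface-propensity table from the training folds only, assembles
#' features, balances the training residues, fits the RBF SVM and scores
#' every surface residue of the untouched (imbalanced) test fold. Per-fold
#' recall, precision and F1 at the decision threshold and the
#' precision-recall AUC are reported together with their unweighted mean
#' over folds. Folds whose test chains contain no binding residue are
#' excluded from the averages with a warning.
#'
#' @param dataset a `dbp_dataset` (list of prepared `dbp_chain` objects,
#'   each carrying binding labels).
#' @param k number of folds.
#' @param seed seed controlling fold assignment, negative sampling and SVM
#'   fitting; the whole run is reproducible for a fixed seed.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL`: 1/n_features).
#' @param threshold decision threshold for the labelled metrics.
#' @param encoding,feature_set passed to [assemble_features()].
#' @param pseudocount propensity pseudocount.
#' @return Object of class `dbp_cv`: the per-fold metric table with a mean
#'   row, fold assignment, per-residue scores and the run configuration.
#' @export
dbp_cv <- function(dataset, k = 5, seed = 1, cost = 1, gamma = NULL,
                   threshold = 0, encoding = "rw",
                   feature_set = c("pssm", "wip", "wbc", "scasa"),
                   pseudocount = 1) {
  stopifnot(inherits(dataset, "dbp_dataset"))
  chains <- dataset$chains
  ids <- vapply(chains, `[[`, character(1), "id")
  names(chains) <- ids
  folds <- fold_chains(ids, k = k, seed = seed)
  rows <- list(); scores_all <- list()
  for (f in seq_len(k)) {
    train_ids <- ids[folds != f]
    test_ids <- ids[folds == f]
    train_tab <- .surface_table(chains[train_ids])
    ip <- if ("wip" %in% feature_set)
      interface_propensity(train_tab$resname, train_tab$label,
                           pseudocount = pseudocount) else NULL
    feat <- lapply(chains, assemble_features, ip_table = ip,
                   encoding = encoding, feature_set = feature_set)
    x_train <- do.call(rbind, feat[train_ids])
    y_train <- train_tab$label
    sel <- balanced_sample(y_train, seed = seed + f)
    g <- if (is.null(gamma)) 1 / ncol(x_train) else gamma
    model <- dbp_fit(x_train[sel, , drop = FALSE], y_train[sel],
                     cost = cost, gamma = g, seed = seed + f)
    test_tab <- .surface_table(chains[test_ids])
    x_test <- do.call(rbind, feat[test_ids])
    pred <- predict(model, x_test, threshold = threshold)
    scores_all[[f]] <- data.frame(fold = f, chain = test_tab$chain,
                                  key = test_tab$key,
                                  score = pred$score, pred = pred$label,
                                  label = test_tab$label,
                                  stringsAsFactors = FALSE)
    truth <- test_tab$label == "binding"
    if (!any(truth)) {
      warning("fold ", f, " has no binding residues; metrics undefined")
      rows[[f]] <- data.frame(fold = f, n_chains = length(test_ids),
                              n_residues = nrow(test_tab),
                              recall = NA, precision = NA, f1 = NA,
                              pr_auc = NA)
      next
    }
    cc <- confusion_counts(pred$label == "binding", truth)
    m <- classification_metrics(cc)
    auc <- pr_auc(pred$score, truth)
    rows[[f]] <- data.frame(fold = f, n_chains = length(test_ids),
                            n_residues = nrow(test_tab),
                            recall = m$recall, precision = m$precision,
                            f1 = m$f1, pr_auc = auc)
  }
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(fold = NA, n_chains = sum(tab$n_chains),
                         n_residues = sum(tab$n_residues),
                         t(colMeans(tab[, c("recall", "precision", "f1",
                                            "pr_auc")], na.rm = TRUE)))
  out <- list(folds = folds, fold_metrics = tab, mean = mean_row,
              scores = do.call(rbind, scores_all),
              config = list(k = k, seed = seed, cost = cost, gamma = gamma,
                            threshold = threshold, encoding = encoding,
                            feature_set = feature_set,
                            pseudocount = pseudocount))
  class(out) <- "dbp_cv"
  out
}

#' @export
print.dbp_cv <- function(x, ...) {
  cat(sprintf("%d-fold chain-level cross-validation (%d chains, seed %d)\n",
              x$config$k, length(x$folds), x$config$seed))
  tab <- x$fold_metrics
  tab[, 4:7] <- round(tab[, 4:7], 3)
  print(tab, row.names = FALSE)
  with(x$mean, cat(sprintf(
    "mean over folds: recall %.3f  precision %.3f  F1 %.3f  PR-AUC %.3f\n",
    recall, precision, f1, pr_auc)))
  invisible(x)
}

#' @export
summary.dbp_cv <- function(object, ...) {
  print(object)
  prev <- mean(object$scores$label == "binding")
  cat(sprintf("pooled surface residues: %d (prevalence %.3f)\n",
              nrow(object$scores), prev))
  invisible(object)
}
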