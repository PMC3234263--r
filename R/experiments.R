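# Higher-level experiments: patch-size sweep, leave-one-feature-out
# ablation, and the top-k ranking case study.

#' Patch-size sweep
#'
#' Cross-validated PR-AUC as a function of surface-patch size for one or
#' both PSSM encodings. The fold assignment (seed) is shared across all
#' cells of the grid so rows are comparable; patches are rebuilt per size
#' without recomputing annotation, contact graphs or profiles.
#'
#' @param dataset a `dbp_dataset`.
#' @param sizes patch sizes to evaluate.
#' @param encodings subset of `c("rw", "c")`.
#' @param seed shared CV seed.
#' @param ... further arguments to [dbp_cv()].
#' @return Data frame with columns `L`, `encoding`, `feature_dim`,
#'   `pr_auc`.
#' @export
patch_size_sweep <- function(dataset, sizes = c(1, 5, 15, 25),
                             encodings = c("rw", "c"), seed = 1, ...) {
  stopifnot(inherits(dataset, "dbp_dataset"))
  rows <- list()
  for (L in sizes) {
    ds <- dataset
    ds$chains <- lapply(ds$chains, rebuild_patches, L = L)
    for (enc in encodings) {
      cv <- dbp_cv(ds, seed = seed, encoding = enc, ...)
      dim_pssm <- if (enc == "rw") 40 else 20 * L
      rows[[length(rows) + 1]] <- data.frame(
        L = L, encoding = enc, feature_dim = dim_pssm + 3,
        pr_auc = cv$mean$pr_auc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-feature-out ablation
#'
#' Runs the cross-validation once per feature configuration, with the same
#' folds and seeds for every row, and reports the usual metrics.
#'
#' @param dataset a `dbp_dataset`.
#' @param feature_sets named list of feature-block subsets; the default is
#'   the full set plus each leave-one-out variant.
#' @param seed shared CV seed.
#' @param ... further arguments to [dbp_cv()].
#' @return Data frame with one row per configuration (recall, precision,
#'   F1, PR-AUC, feature dimension) and the shared fold assignment as a
#'   `folds` attribute.
#' @export
feature_ablation <- function(dataset,
                             feature_sets = list(
                               all = c("pssm", "wip", "wbc", "scasa"),
                               without_pssm = c("wip", "wbc", "scasa"),
                               without_wip = c("pssm", "wbc", "scasa"),
                               without_scasa = c("pssm", "wip", "wbc"),
                               without_wbc = c("pssm", "wip", "scasa")),
                             seed = 1, ...) {
  stopifnot(inherits(dataset, "dbp_dataset"))
  rows <- list(); folds <- NULL
  for (nm in names(feature_sets)) {
    cv <- dbp_cv(dataset, seed = seed, feature_set = feature_sets[[nm]],
                 ...)
    if (is.null(folds)) folds <- cv$folds
    stopifnot(identical(folds, cv$folds))
    fs <- feature_sets[[nm]]
    dim <- sum(c(pssm = 40, wip = 1, wbc = 1, scasa = 1)[fs])
    rows[[nm]] <- data.frame(variant = nm, feature_dim = dim,
                             recall = cv$mean$recall,
                             precision = cv$mean$precision,
                             f1 = cv$mean$f1, pr_auc = cv$mean$pr_auc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Rank-based case study on one labelled complex
#'
#' Ranks the surface residues of a prepared chain by a single per-residue
#' scalar — raw or distance-weighted betweenness centrality or interface
#' propensity — takes the top k as predicted binding residues and scores
#' them against the chain's binding labels. With k equal to the number of
#' true binding residues, recall equals precision.
#'
#' @param chain a `dbp_chain` with binding labels.
#' @param by ranking scalar: `"bc"`, `"wbc"`, `"ip"` or `"wip"`.
#' @param k number of top residues to call binding; defaults to the number
#'   of true binding residues.
#' @param ip_table a `propensity_table`, required for the propensity-based
#'   rankings; for a self-contained case study it may be derived from the
#'   chain's own labels.
#' @return List with `recall`, `precision`, the ranked values, the
#'   predicted and true keys.
#' @export
rank_case_study <- function(chain, by = c("wbc", "bc", "wip", "ip"),
                            k = NULL, ip_table = NULL) {
  by <- match.arg(by)
  stopifnot(inherits(chain, "dbp_chain"))
  surf <- chain$annotation[chain$annotation$is_surface, ]
  truth <- surf$key[surf$binding_label == "binding"]
  if (is.null(k)) k <- length(truth)
  if (by %in% c("ip", "wip")) {
    if (is.null(ip_table))
      ip_table <- interface_propensity(surf$resname, surf$binding_label)
    ipv <- stats::setNames(ip_table$ip[surf$resname], surf$key)
  }
  values <- switch(by,
    bc = chain$bc[surf$key],
    wbc = vapply(chain$patches[surf$key], patch_average, numeric(1),
                 values = chain$bc),
    ip = ipv,
    wip = vapply(chain$patches[surf$key], patch_average, numeric(1),
                 values = ipv))
  names(values) <- surf$key
  res <- top_k_eval(values, truth, k)
  c(res, list(by = by, k = k, values = values, truth = truth))
}
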