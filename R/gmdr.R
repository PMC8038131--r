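# Generalized multifactor dimensionality reduction: score residuals
# from a covariate-only null logistic model, multilocus cell pooling
# against a score-sum threshold, balanced accuracy under 10-fold
# stratified cross-validation, cross-validation consistency, and the
# fold-win sign test used for model selection.

#' GMDR score statistic
#'
#' Per-subject scores `s_i = y_i - p_hat_i`, the response residuals of
#' the null logistic model of outcome on covariates only. With no
#' covariates this reduces to `y_i - mean(y)`. The scores sum to ~0
#' whenever the null model has an intercept.
#'
#' @param outcome binary 0/1 vector.
#' @param covariates optional data.frame of covariates (factors allowed).
#' @return numeric score vector, same length/order as `outcome`.
#' @export
compute_scores <- function(outcome, covariates = NULL) {
  stopifnot(all(outcome %in% 0:1))
  if (is.null(covariates) || length(covariates) == 0) {
    return(outcome - mean(outcome))
  }
  stopifnot(nrow(covariates) == length(outcome))
  df <- cbind(data.frame(.y = outcome), covariates)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) {
    stop("null model did not converge with covariates: ",
         paste(names(covariates), collapse = ", "))
  }
  unname(outcome - stats::fitted(fit))
}

# integer cell index 1..3^k of a SNP combination; NA where any genotype
# is missing
cell_index <- function(g, combo) {
  mat <- unclass(g)[, combo, drop = FALSE]
  idx <- rep(1L, nrow(mat))
  mult <- 1L
  for (j in seq_along(combo)) {
    idx <- idx + mat[, j] * mult
    mult <- mult * 3L
  }
  idx
}

#' Pool multilocus genotype cells into high/low risk
#'
#' Each of the 3^k cells of a k-SNP combination is labeled high risk
#' when the sum of subject scores in the cell exceeds the threshold
#' `T` (default 0); cells at or below `T` -- including ties -- and
#' cells unobserved in the training data are labeled low.
#'
#' @param g a [genotype_matrix()] (training subjects).
#' @param combo character vector of snp ids (k >= 1).
#' @param scores score vector from [compute_scores()], aligned to `g`.
#' @param threshold the score-sum threshold `T`.
#' @return list of class `cell_partition`: `high` (logical length 3^k),
#'   `observed` (logical), `combo`, `threshold`.
#' @export
partition_cells <- function(g, combo, scores, threshold = 0) {
  stopifnot(length(combo) >= 1)
  idx <- cell_index(g, combo)
  ok <- !is.na(idx)
  n_cells <- 3L^length(combo)
  sums <- numeric(n_cells)
  seen <- logical(n_cells)
  agg <- rowsum(scores[ok], idx[ok])
  cells <- as.integer(rownames(agg))
  sums[cells] <- agg[, 1]
  seen[cells] <- TRUE
  structure(list(high = seen & sums > threshold, observed = seen,
                 combo = combo, threshold = threshold),
            class = "cell_partition")
}

#' Balanced accuracy of a cell partition
#'
#' Predicts case for subjects whose cell is labeled high and reports
#' `(sensitivity + specificity) / 2` against the true labels. Cells
#' unseen in training follow `unseen`: predicted low (default) or the
#' subject excluded from evaluation.
#'
#' @param partition a [partition_cells()] result.
#' @param g a [genotype_matrix()] of the evaluated subjects.
#' @param outcome their binary labels.
#' @param unseen `"low"` or `"exclude"`.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(partition, g, outcome,
                              unseen = c("low", "exclude")) {
  unseen <- match.arg(unseen)
  idx <- cell_index(g, partition$combo)
  keep <- !is.na(idx)
  if (unseen == "exclude") keep <- keep & partition$observed[idx]
  idx <- idx[keep]; outcome <- outcome[keep]
  pred <- partition$high[idx]
  n_case <- sum(outcome == 1); n_ctrl <- sum(outcome == 0)
  if (n_case == 0 || n_ctrl == 0) {
    stop("balanced accuracy undefined: a class is absent from the fold")
  }
  sens <- sum(pred & outcome == 1) / n_case
  spec <- sum(!pred & outcome == 0) / n_ctrl
  (sens + spec) / 2
}

#' Stratified cross-validation folds keyed to subject ids
#'
#' Fold assignment is a deterministic function of the sorted subject
#' ids, the outcome and the seed -- never of row order -- so permuting
#' subjects changes nothing downstream.
#'
#' @param subject_ids character vector.
#' @param outcome binary vector aligned to `subject_ids`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold labels named by subject id, in input order.
#' @export
make_folds <- function(subject_ids, outcome, n_folds = 10, seed = 1L) {
  stopifnot(!anyDuplicated(subject_ids))
  ord <- order(subject_ids)
  ids <- subject_ids[ord]; y <- outcome[ord]
  fold <- integer(length(ids))
  withr::with_seed(seed, {
    for (cls in c(0, 1)) {
      i <- which(y == cls)
      if (length(i) < n_folds) {
        stop("class ", cls, " has fewer subjects than folds; ",
             "use fewer folds or another seed")
      }
      fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  })
  names(fold) <- ids
  out <- unname(fold[match(subject_ids, ids)])
  names(out) <- subject_ids
  out
}

#' Cross-validated GMDR evaluation of one SNP combination
#'
#' For each fold: cells are pooled on the 9/10 training split and
#' balanced accuracy is computed on the training split (TRBA) and the
#' held-out tenth (TEBA). TRBA/TEBA are fold means; `fold_wins` counts
#' folds with test BA > 0.5 and feeds the sign test.
#'
#' @param g a [genotype_matrix()].
#' @param combo character vector of snp ids.
#' @param scores scores aligned to `g` rows.
#' @param outcome binary labels aligned to `g` rows.
#' @param folds fold assignment from [make_folds()] (aligned to `g`).
#' @param threshold cell score-sum threshold.
#' @param unseen unseen-cell policy for test folds.
#' @return list of class `gmdr_result`: combo, trba, teba,
#'   fold_train_ba, fold_test_ba, fold_wins, sign_p.
#' @export
cross_validate <- function(g, combo, scores, outcome, folds,
                           threshold = 0, unseen = "low") {
  idx_all <- cell_index(g, combo)
  n_cells <- 3L^length(combo)
  n_folds <- max(folds)
  called <- !is.na(idx_all)
  train_ba <- test_ba <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f & called
    te <- folds == f & called
    agg <- rowsum(scores[tr], idx_all[tr])
    cells <- as.integer(rownames(agg))
    high <- seen <- logical(n_cells)
    seen[cells] <- TRUE
    high[cells] <- agg[, 1] > threshold
    train_ba[f] <- ba_from_labels(high, seen, idx_all[tr], outcome[tr], "low")
    test_ba[f] <- ba_from_labels(high, seen, idx_all[te], outcome[te], unseen)
  }
  wins <- sum(test_ba > 0.5)
  structure(list(combo = combo, trba = mean(train_ba), teba = mean(test_ba),
                 fold_train_ba = train_ba, fold_test_ba = test_ba,
                 fold_wins = wins, sign_p = sign_test(wins, n_folds)),
            class = "gmdr_result")
}

# balanced accuracy from precomputed cell labels (fast path used by
# cross_validate; semantics identical to balanced_accuracy())
ba_from_labels <- function(high, seen, idx, y, unseen) {
  if (unseen == "exclude") {
    keep <- seen[idx]
    idx <- idx[keep]; y <- y[keep]
  }
  pred <- high[idx]
  n_case <- sum(y == 1); n_ctrl <- sum(y == 0)
  if (n_case == 0 || n_ctrl == 0) {
    stop("balanced accuracy undefined: a class is absent from the fold")
  }
  (sum(pred & y == 1) / n_case + sum(!pred & y == 0) / n_ctrl) / 2
}

#' MDR sign test on cross-validation fold wins
#'
#' One-sided binomial tail `P(X >= fold_wins)` for `X ~
#' Binomial(n_folds, 1/2)`: the probability, under a fair-coin null, of
#' at least the observed number of folds with test balanced accuracy
#' above 0.5.
#'
#' @param fold_wins observed count of winning folds.
#' @param n_folds number of folds.
#' @return p-value in `[0, 1]`.
#' @examples
#' sign_test(10, 10)  # 1/1024
#' sign_test(8, 10)   # 56/1024
#' @export
sign_test <- function(fold_wins, n_folds) {
  stopifnot(fold_wins >= 0, fold_wins <= n_folds)
  stats::pbinom(fold_wins - 1, n_folds, 0.5, lower.tail = FALSE)
}

#' Exhaustive (or forward) GMDR model search
#'
#' For each model size k, evaluates SNP subsets by cross-validated
#' GMDR and reports the best: highest mean test balanced accuracy,
#' ties resolved by higher cross-validation consistency then
#' lexicographic order. CVC is the number of folds whose training-best
#' subset (by training BA on that fold's training split) equals the
#' overall best subset. `strategy = "forward"` grows the model by one
#' SNP per k from the previous best (nested sequence) instead of
#' enumerating all C(m, k) subsets.
#'
#' @param g a [genotype_matrix()] restricted to the candidate SNPs.
#' @param outcome binary labels aligned to `g`.
#' @param covariates optional covariate data.frame for the score model.
#' @param k_range model sizes to search (default 1:ncol(g)).
#' @param n_folds folds (default 10).
#' @param seed integer seed for fold construction.
#' @param strategy `"exhaustive"` (default) or `"forward"`.
#' @param threshold cell score-sum threshold.
#' @return data.frame, one row per k: model, trba, teba, fold_wins,
#'   sign_p, cvc, n_evaluated; attribute `details` holds the
#'   `gmdr_result` of each best model.
#' @export
search_best_models <- function(g, outcome, covariates = NULL,
                               k_range = seq_len(ncol(g)), n_folds = 10,
                               seed = 1L,
                               strategy = c("exhaustive", "forward"),
                               threshold = 0) {
  strategy <- match.arg(strategy)
  m <- ncol(g)
  if (any(k_range > m)) stop("model size k exceeds candidate count ", m)
  scores <- compute_scores(outcome, covariates)
  folds <- make_folds(rownames(g), outcome, n_folds, seed)
  snps <- colnames(g)
  rows <- list(); details <- list()
  prev_best <- character()
  for (k in sort(k_range)) {
    subsets <- if (strategy == "exhaustive") {
      utils::combn(snps, k, simplify = FALSE)
    } else {
      if (length(prev_best) == k - 1) {
        lapply(setdiff(snps, prev_best), function(s) sort(c(prev_best, s)))
      } else {
        utils::combn(snps, k, simplify = FALSE)
      }
    }
    evals <- lapply(subsets, function(cm) {
      cross_validate(g, cm, scores, outcome, folds, threshold)
    })
    teba <- vapply(evals, `[[`, 0, "teba")
    # per-fold training-best subset, for CVC
    tb <- vapply(evals, `[[`, numeric(n_folds), "fold_train_ba")
    fold_best <- apply(matrix(tb, nrow = n_folds), 1, which.max)
    cvc_of <- function(i) sum(fold_best == i)
    best_teba <- max(teba)
    tied <- which(teba >= best_teba - 1e-12)
    if (length(tied) > 1) {
      cvcs <- vapply(tied, cvc_of, 0L)
      tied <- tied[cvcs == max(cvcs)]
    }
    best_i <- tied[1] # subsets enumerated in lexicographic order
    best <- evals[[best_i]]
    prev_best <- best$combo
    rows[[length(rows) + 1]] <- data.frame(
      k = k, model = paste(best$combo, collapse = " "),
      trba = best$trba, teba = best$teba,
      fold_wins = best$fold_wins, sign_p = best$sign_p,
      cvc = cvc_of(best_i), n_evaluated = length(subsets),
      stringsAsFactors = FALSE)
    details[[as.character(k)]] <- best
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}
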