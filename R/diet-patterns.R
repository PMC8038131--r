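# Dietary patterns from food-group intakes: principal-component
# extraction on the correlation matrix, eigenvalue retention, varimax
# rotation, regression-method factor scores, and 70th-percentile
# dichotomization into high/low pattern exposures.

#' Extract dietary-pattern factors
#'
#' Principal-component factoring of the food-group correlation matrix:
#' components with eigenvalue above `retention_threshold` (default 1.5)
#' are retained and varimax-rotated (normalized Kaiser). Loadings with
#' absolute value at or above `loading_min` (default 0.40) are flagged
#' as significant contributions. Each factor's sign is fixed so its
#' largest-|loading| variable loads positively.
#'
#' @param x numeric matrix/data.frame, subjects x food groups; at least
#'   two columns and more subjects than columns.
#' @param retention_threshold eigenvalue cutoff for retention.
#' @param loading_min |loading| cutoff for the significance mask.
#' @return list of class `factor_model`: loadings (rotated),
#'   eigenvalues (all), retained, significant (logical mask), center,
#'   scale, cor.
#' @export
extract_factors <- function(x, retention_threshold = 1.5,
                            loading_min = 0.40) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) > ncol(x))
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  if (any(scale_ == 0)) stop("constant food-group column(s)")
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  retained <- sum(eig$values > retention_threshold)
  if (retained < 1) {
    stop("no eigenvalue above ", retention_threshold,
         "; lower the retention threshold")
  }
  L <- eig$vectors[, seq_len(retained), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(retained)]), retained)
  if (retained > 1) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
    L <- L %*% rot$rotmat
  }
  # fix rotation sign: anchor variable of each factor loads positively
  for (j in seq_len(retained)) {
    anchor <- which.max(abs(L[, j]))
    if (L[anchor, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(x), paste0("pattern_", seq_len(retained)))
  structure(list(loadings = L, eigenvalues = eig$values,
                 retained = retained,
                 significant = abs(L) >= loading_min,
                 loading_min = loading_min,
                 center = center, scale = scale_, cor = R),
            class = "factor_model")
}

#' Regression-method factor scores
#'
#' Scores are `Z R^-1 L` on standardized intakes, rescaled to unit
#' variance per factor (analytically, so a subject at the variable
#' means scores exactly 0 on every factor).
#'
#' @param model a [extract_factors()] result.
#' @param x food-group matrix on the model's variable set.
#' @return numeric matrix, subjects x retained factors.
#' @export
score_patterns <- function(model, x) {
  x <- as.matrix(x)
  stopifnot(identical(colnames(x), names(model$center)))
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  W <- solve(model$cor, model$loadings)
  scores <- z %*% W
  sdev <- sqrt(diag(t(W) %*% model$cor %*% W))
  scores <- sweep(scores, 2, sdev, "/")
  colnames(scores) <- colnames(model$loadings)
  scores
}

#' Percentile dichotomization of pattern scores
#'
#' High = score at or above the sample percentile (default 70th); ties
#' at the cutoff go to high.
#'
#' @param scores matrix from [score_patterns()].
#' @param percentile percentile in (0, 100).
#' @return data.frame of binary factor columns `<pattern>_high`
#'   (levels low/high).
#' @export
pattern_exposures <- function(scores, percentile = 70) {
  stopifnot(percentile > 0, percentile < 100)
  out <- lapply(colnames(scores), function(p) {
    cutoff <- stats::quantile(scores[, p], percentile / 100, names = FALSE)
    factor(ifelse(scores[, p] >= cutoff, "high", "low"),
           levels = c("low", "high"))
  })
  names(out) <- paste0(colnames(scores), "_high")
  as.data.frame(out)
}
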