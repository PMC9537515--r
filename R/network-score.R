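# Decomposable Gaussian BIC score for linear-Gaussian Bayesian networks.
#
# For node y with parent set P on n observations, the local score is the
# maximised Gaussian log-likelihood of the regression y ~ P minus a BIC
# penalty counting |P| coefficients, one intercept and one variance:
#
#   score(y | P) = -n/2 * (log(2 * pi * sigma2_mle) + 1) - (|P| + 2)/2 * log n
#
# On column-standardised data, sigma2_mle comes straight from the sample
# covariance matrix S (MLE, divided by n):
#
#   sigma2 = S[y,y] - S[y,P] %*% solve(S[P,P]) %*% S[P,y]
#
# so each candidate parent set costs one small symmetric solve. The network
# score is the sum of local scores (decomposability), which is what makes
# single-arc hill climbing cheap.

# MLE covariance of a centred/scaled data matrix
mle_cov <- function(x) crossprod(x) / nrow(x)

# internal fast path: score from a covariance matrix, -Inf on degeneracy
score_cov <- function(S, n, j, parents) {
  if (length(parents) == 0L) {
    s2 <- S[j, j]
  } else {
    Spp <- S[parents, parents, drop = FALSE]
    Spj <- S[parents, j]
    sol <- tryCatch(solve(Spp, Spj), error = function(e) NULL)
    if (is.null(sol)) {
      return(-Inf)
    }
    s2 <- S[j, j] - sum(Spj * sol)
  }
  if (!is.finite(s2) || s2 < 1e-12) {
    return(-Inf)
  }
  -n / 2 * (log(2 * pi * s2) + 1) - (length(parents) + 2) / 2 * log(n)
}

# standardize columns; constant columns are a degeneracy
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds < 1e-12)) {
    stop("degeneracy error: constant or non-finite column(s) ",
      paste(colnames(x)[!is.finite(sds) | sds < 1e-12], collapse = ", "))
  }
  scale(x, center = mu, scale = sds)
}

#' Local Gaussian BIC score of one node given a parent set
#'
#' The decomposable score driving structure learning: the maximised Gaussian
#' log-likelihood of the node's linear regression on its parents minus
#' `(k + 2)/2 * log(n)` where `k` is the number of parents (the +2 counts
#' the intercept and the residual variance).
#'
#' @param data Data frame or matrix of numeric columns (observations x
#'   variables). Columns are standardised internally.
#' @param node Column name of the child node.
#' @param parents Character vector of parent column names (possibly empty).
#' @return The local BIC score (a scalar; larger is better).
#' @export
local_score <- function(data, node, parents = character()) {
  x <- standardize_columns(data[, , drop = FALSE])
  vars <- colnames(x)
  stopifnot(node %in% vars, all(parents %in% vars), !(node %in% parents))
  n <- nrow(x)
  if (n <= length(parents) + 2) stop("need n > |parents| + 2 observations")
  sc <- score_cov(mle_cov(x), n, match(node, vars), match(parents, vars))
  if (!is.finite(sc)) stop("degeneracy error: singular parent design for node ", node)
  sc
}

# --- score cache ------------------------------------------------------------

new_score_cache <- function(S, n) {
  list(S = S, n = n, env = new.env(parent = emptyenv()))
}

cached_score <- function(cache, j, parents) {
  # parent-set bitmask is exact as a double for < 53 variables
  key <- paste0(j, "|", sum(2^(parents - 1)))
  hit <- cache$env[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  val <- score_cov(cache$S, cache$n, j, parents)
  cache$env[[key]] <- val
  val
}
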