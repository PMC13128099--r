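#' @useDynLib progphen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rbinom quantile sd cor predict
#'   chisq.test fisher.test pchisq approx setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw from a log-normal distribution parameterized by mean and sd
#'
#' Converts the desired arithmetic mean/sd of the distribution into the
#' meanlog/sdlog parameters and samples, optionally rejecting draws at or
#' below `lower` / above `upper` (resampling until accepted).
#'
#' @param n number of draws
#' @param mean,sd target arithmetic mean and standard deviation (> 0)
#' @param lower,upper truncation bounds (exclusive lower, inclusive upper)
#' @return numeric vector of length `n`
#' @keywords internal
rlnorm_meansd <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(mean > 0, sd > 0)
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  out <- stats::rlnorm(n, mu, sqrt(sigma2))
  bad <- which(out <= lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rlnorm(length(bad), mu, sqrt(sigma2))
    bad <- bad[out[bad] <= lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated log-normal sampler failed to accept")
  }
  out
}

rnorm_trunc <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Rank-based binary AUROC
#'
#' Wraps pROC for the two-class area under the ROC curve; returns NA (with no
#' warning) when only one class is present, so callers can flag undefined
#' metrics instead of silently reporting 0.
#'
#' @param truth logical or 0/1 vector of positives
#' @param score numeric scores, higher = more positive
#' @keywords internal
binary_auroc <- function(truth, score) {
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                 direction = "<", levels = c(0L, 1L))))
}

#' Macro one-vs-rest AUROC over a probability matrix
#'
#' @param prob matrix n x C of class probabilities, columns named by class
#' @param labels vector of true class labels (matching colnames)
#' @return list(per_class, macro)
#' @keywords internal
macro_auroc <- function(prob, labels) {
  classes <- colnames(prob)
  per <- vapply(classes, function(cl) binary_auroc(labels == cl, prob[, cl]),
                numeric(1))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

classification_metrics <- function(prob, labels) {
  classes <- colnames(prob)
  pred <- classes[max.col(prob, ties.method = "first")]
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    tn <- sum(pred != cl & labels != cl)
    c(auroc = binary_auroc(labels == cl, prob[, cl]),
      sensitivity = if ((tp + fn) > 0) tp / (tp + fn) else NA_real_,
      specificity = if ((tn + fp) > 0) tn / (tn + fp) else NA_real_,
      precision   = if ((tp + fp) > 0) tp / (tp + fp) else NA_real_)
  })
  tab <- do.call(rbind, per)
  rownames(tab) <- classes
  list(per_class = tab, macro = colMeans(tab, na.rm = TRUE),
       accuracy = mean(pred == labels))
}

#' Solve the assignment problem (Hungarian algorithm)
#'
#' Minimum-cost perfect matching on a square cost matrix via the O(n^3)
#' potential/augmenting-path formulation. Used to align cluster labels
#' between clustering runs; no assignment-problem solver ships with the
#' declared dependencies.
#'
#' @param cost square numeric matrix
#' @return integer vector `a` with `a[i]` the column matched to row `i`
#' @export
hungarian_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # column index 1 and row id 0 are dummies (potentials u, v; way[] stores
  # the augmenting path), following the O(n^3) shortest-augmenting-path form
  u <- numeric(n + 1)   # u[r + 1] is the potential of row r
  v <- numeric(n + 1)   # v[j] is the potential of column j - 1
  p <- integer(n + 1)   # p[j]: row currently assigned to column j - 1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) ans[p[j]] <- j - 1L
  ans
}

# Deterministic child seeds below 2^31, derived from a base seed.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(i) %% 2147483L
}
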