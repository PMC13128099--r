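# Time-series K-means over per-patient embedding sequences under dynamic
# time warping, with silhouette / Davies-Bouldin validity, a K scan, and
# bootstrap stability of the clustering.

as_sequence_list <- function(seqs) {
  if (inherits(seqs, "embedding_sequences")) seqs <- unclass(seqs)
  stopifnot(is.list(seqs), length(seqs) > 0L)
  out <- lapply(seqs, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (nrow(s) == 0L) stop("empty sequence", call. = FALSE)
    s
  })
  dims <- vapply(out, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("sequences must share one vector dimension", call. = FALSE)
  }
  out
}

#' Dynamic time warping distance between two sequences
#'
#' Minimum cumulative Euclidean pointwise distance over all monotone warping
#' paths (boundary-anchored, steps (1,0), (0,1), (1,1)), computed by dynamic
#' programming. Sequences are matrices with time on the rows; numeric
#' vectors are treated as univariate sequences.
#'
#' @param x,y sequences (matrices or vectors) of equal vector dimension
#' @param return_path also return the optimal warping path (L x 2 index
#'   matrix, starting at (1,1) and ending at (N,M))
#' @return the distance, or a list(distance, path)
#' @export
dtw_distance <- function(x, y, return_path = FALSE) {
  to_mat <- function(s) {
    if (is.null(dim(s))) s <- matrix(as.numeric(s), ncol = 1L)
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  }
  x <- to_mat(x); y <- to_mat(y)
  if (nrow(x) == 0L || nrow(y) == 0L) stop("empty sequence", call. = FALSE)
  if (ncol(x) != ncol(y)) stop("sequence dimensions differ", call. = FALSE)
  if (!return_path) return(cpp_dtw(x, y))
  cpp_dtw_path(x, y)
}

#' Pairwise DTW distance matrix
#' @param seqs list of sequences (or `embedding_sequences`)
#' @return symmetric matrix of DTW distances
#' @export
dtw_pairwise <- function(seqs) {
  s <- as_sequence_list(seqs)
  D <- cpp_dtw_pairwise(s)
  dimnames(D) <- list(names(s), names(s))
  D
}

resample_sequence <- function(s, len) {
  if (nrow(s) == len) return(s)
  if (nrow(s) == 1L) return(s[rep(1L, len), , drop = FALSE])
  idx <- seq(1, nrow(s), length.out = len)
  apply(s, 2L, function(col) stats::approx(seq_len(nrow(s)), col,
                                           xout = idx)$y)
}

# one DTW-barycenter-averaging pass: align members to the centroid, average
# the member vectors mapped onto each centroid index
dba_update <- function(members, centroid) {
  acc <- matrix(0, nrow(centroid), ncol(centroid))
  cnt <- numeric(nrow(centroid))
  for (s in members) {
    p <- cpp_dtw_path(s, centroid)$path
    # repeated centroid indices on the path must accumulate, so sum via
    # rowsum on the path rows rather than indexed assignment
    g <- rowsum(s[p[, 1L], , drop = FALSE], p[, 2L])
    rows <- as.integer(rownames(g))
    acc[rows, ] <- acc[rows, , drop = FALSE] + g
    cnt_add <- tabulate(p[, 2L], nrow(centroid))
    cnt <- cnt + cnt_add
  }
  keep <- cnt > 0
  centroid[keep, ] <- acc[keep, , drop = FALSE] / cnt[keep]
  centroid
}

kmeanspp_init <- function(s, K) {
  n <- length(s)
  first <- sample.int(n, 1L)
  chosen <- first
  d2 <- vapply(s, function(x) cpp_dtw(x, s[[first]]), numeric(1))^2
  while (length(chosen) < K) {
    prob <- d2
    if (sum(prob) <= 0) prob <- rep(1, n)
    nxt <- sample.int(n, 1L, prob = prob)
    chosen <- c(chosen, nxt)
    d2 <- pmin(d2, vapply(s, function(x) cpp_dtw(x, s[[nxt]]),
                          numeric(1))^2)
  }
  chosen
}

#' Time-series K-means under DTW
#'
#' Alternates nearest-centroid assignment (by DTW) with DTW-barycenter-
#' averaging centroid updates, minimizing the within-cluster objective
#' `J = sum_i sum_{j in C_i} DTW(H_j, mu_i)`. Initialization is
#' k-means++-style under DTW; `n_init` seeded restarts are run and the best
#' objective kept. Centroids have fixed length equal to the median sequence
#' length. The recorded objective is non-increasing across iterations within
#' a restart (the loop stops, keeping the best state, if an update would
#' increase it). An emptied cluster is re-seeded from the sequence farthest
#' from its centroid.
#'
#' @param seqs list of sequences (or `embedding_sequences`)
#' @param K number of clusters (2 <= K <= #sequences)
#' @param seed RNG seed
#' @param n_init number of restarts
#' @param max_iter iteration cap per restart
#' @param centroid_length centroid length; median sequence length if NULL
#' @return object of class `ts_kmeans`: `cluster` (named assignments),
#'   `centroids`, `objective`, `history`, `K`
#' @export
ts_kmeans <- function(seqs, K, seed = 1L, n_init = 5L, max_iter = 30L,
                      centroid_length = NULL) {
  s <- as_sequence_list(seqs)
  n <- length(s)
  stopifnot(K >= 1L, K <= n)
  len <- centroid_length %||% max(1L, round(stats::median(
    vapply(s, nrow, integer(1)))))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(derive_seed(seed, init))
    cent <- lapply(s[kmeanspp_init(s, K)], resample_sequence, len = len)
    prev <- NULL
    history <- numeric(0)
    for (iter in seq_len(max_iter)) {
      D <- cpp_dtw_cross(s, cent)
      assign_ <- max.col(-D, ties.method = "first")
      # re-seed empty clusters from the farthest sequence
      for (k in which(tabulate(assign_, K) == 0L)) {
        far <- which.max(D[cbind(seq_len(n), assign_)])
        assign_[far] <- k
        cent[[k]] <- s[[far]]
        D[, k] <- vapply(s, function(x) cpp_dtw(x, cent[[k]]), numeric(1))
      }
      J <- sum(D[cbind(seq_len(n), assign_)])
      if (!is.null(prev) && J >= prev$J - 1e-9) break
      prev <- list(J = J, assign = assign_, cent = cent)
      history <- c(history, J)
      for (k in seq_len(K)) {
        members <- s[assign_ == k]
        if (length(members) == 1L) {
          cent[[k]] <- members[[1L]]  # the barycenter of one sequence
        } else if (length(members) > 1L) {
          cent[[k]] <- dba_update(members, cent[[k]])
        }
      }
    }
    if (is.null(best) || prev$J < best$J) {
      best <- prev
      best$history <- history
    }
  }
  cl <- best$assign
  names(cl) <- names(s)
  structure(list(K = K, cluster = cl, centroids = best$cent,
                 objective = best$J, history = best$history,
                 centroid_length = len),
            class = "ts_kmeans")
}

#' @export
print.ts_kmeans <- function(x, ...) {
  cat(sprintf("<ts_kmeans> K=%d, n=%d, objective J=%.4f, sizes: %s\n",
              x$K, length(x$cluster), x$objective,
              paste(tabulate(x$cluster, x$K), collapse = "/")))
  invisible(x)
}

#' Silhouette score under DTW
#'
#' Mean over sequences of `(b - a) / max(a, b)` with `a` the mean DTW
#' distance to the own cluster and `b` the smallest mean distance to another
#' cluster. Sequences in singleton clusters contribute 0. Computing from a
#' precomputed [dtw_pairwise()] matrix and on the fly give identical values.
#'
#' @param seqs list of sequences, or NULL if `distmat` is given
#' @param assignments integer cluster per sequence
#' @param distmat optional precomputed DTW distance matrix
#' @return silhouette score in [-1, 1]
#' @export
silhouette_dtw <- function(seqs, assignments, distmat = NULL) {
  D <- distmat %||% dtw_pairwise(seqs)
  n <- nrow(D)
  stopifnot(length(assignments) == n)
  ks <- sort(unique(assignments))
  if (length(ks) < 2L) stop("silhouette needs at least two clusters",
                            call. = FALSE)
  if (all(tabulate(match(assignments, ks)) == 1L)) {
    stop("silhouette undefined: all clusters are singletons", call. = FALSE)
  }
  sil <- vapply(seq_len(n), function(i) {
    own <- assignments == assignments[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(ks, assignments[i]), function(k) {
      mean(D[i, assignments == k])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Davies-Bouldin index under DTW
#'
#' Mean over clusters of `max_{j != i} (s_i + s_j) / DTW(mu_i, mu_j)` with
#' `s_i` the mean DTW distance of cluster members to their centroid. Lower
#' is better; coincident centroids give an infinite ratio (flagged with a
#' warning).
#'
#' @param seqs list of sequences
#' @param model a fitted [ts_kmeans()] (or list with `centroids` and
#'   `cluster`)
#' @return DBI >= 0
#' @export
dbi_dtw <- function(seqs, model) {
  s <- as_sequence_list(seqs)
  K <- length(model$centroids)
  assign_ <- model$cluster
  sig <- vapply(seq_len(K), function(k) {
    members <- s[assign_ == k]
    if (length(members) == 0L) return(NA_real_)
    mean(vapply(members, function(x) cpp_dtw(x, model$centroids[[k]]),
                numeric(1)))
  }, numeric(1))
  M <- cpp_dtw_pairwise(model$centroids)
  ratios <- vapply(seq_len(K), function(i) {
    r <- vapply(setdiff(seq_len(K), i), function(j) {
      if (M[i, j] == 0) Inf else (sig[i] + sig[j]) / M[i, j]
    }, numeric(1))
    max(r, na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(ratios))) warning("coincident centroids: DBI infinite")
  mean(ratios)
}

#' Scan cluster numbers and score validity
#'
#' Fits [ts_kmeans()] for each K in `k_range` and reports the objective J,
#' silhouette score and Davies-Bouldin index under DTW, flagging a K as
#' acceptable when SS > 0.25 and DBI < 1. The final choice of K is left to
#' the caller.
#'
#' @param seqs list of sequences
#' @param k_range candidate cluster numbers
#' @param seed RNG seed
#' @param n_init restarts per K
#' @return data frame with one row per K (K, J, silhouette, dbi, acceptable)
#' @export
select_k <- function(seqs, k_range = 2:10, seed = 1L, n_init = 5L) {
  s <- as_sequence_list(seqs)
  stopifnot(min(k_range) >= 2L, max(k_range) <= length(s) - 1L)
  D <- cpp_dtw_pairwise(s)
  rows <- lapply(k_range, function(K) {
    fit <- ts_kmeans(s, K, seed = derive_seed(seed, K), n_init = n_init)
    ss <- silhouette_dtw(NULL, fit$cluster, distmat = D)
    dbi <- suppressWarnings(dbi_dtw(s, fit))
    data.frame(K = K, J = fit$objective, silhouette = ss, dbi = dbi,
               acceptable = is.finite(ss) && is.finite(dbi) &&
                 ss > 0.25 && dbi < 1)
  })
  do.call(rbind, rows)
}

# overlap-maximizing relabeling of boot clusters onto reference clusters
match_cluster_labels <- function(ref, boot, K) {
  overlap <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (j in seq_len(K)) overlap[k, j] <- sum(ref == k & boot == j)
  }
  hungarian_assignment(max(overlap) - overlap)  # ref cluster k -> boot col
}

#' Bootstrap stability of a DTW K-means clustering
#'
#' Repeats: fit K-means on a random `frac` subsample, assign *all* sequences
#' to the nearest subsample centroid, optimally match the bootstrap cluster
#' labels to the full-sample solution (maximum-overlap assignment via the
#' Hungarian algorithm), and record the per-cluster Jaccard agreement of
#' memberships plus the silhouette and DBI of the bootstrap assignment.
#'
#' @param seqs list of sequences
#' @param K number of clusters
#' @param n_iter bootstrap iterations
#' @param frac subsample fraction
#' @param seed RNG seed
#' @param n_init restarts per fit
#' @param reference optional full-sample [ts_kmeans()] fit to compare with
#' @return list with `per_iteration` (data frame), `jaccard_mean`,
#'   `jaccard_sd` (per cluster), `summary` (means and sds of mean Jaccard,
#'   SS, DBI) and the `reference` fit
#' @export
bootstrap_stability <- function(seqs, K, n_iter = 100L, frac = 0.9,
                                seed = 1L, n_init = 5L, reference = NULL) {
  s <- as_sequence_list(seqs)
  n <- length(s)
  reference <- reference %||% ts_kmeans(s, K, seed = seed, n_init = n_init)
  D_full <- cpp_dtw_pairwise(s)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  jac <- matrix(NA_real_, n_iter, K)
  ss <- numeric(n_iter); dbi <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, it))
    idx <- sample.int(n, max(K, floor(frac * n)))
    fit_b <- ts_kmeans(s[idx], K, seed = derive_seed(seed, n_iter + it),
                       n_init = n_init)
    Dx <- cpp_dtw_cross(s, fit_b$centroids)
    boot <- max.col(-Dx, ties.method = "first")
    perm <- match_cluster_labels(reference$cluster, boot, K)
    for (k in seq_len(K)) {
      A <- reference$cluster == k
      B <- boot == perm[k]
      jac[it, k] <- if (any(A | B)) sum(A & B) / sum(A | B) else NA_real_
    }
    ss[it] <- silhouette_dtw(NULL, boot, distmat = D_full)
    dbi[it] <- suppressWarnings(
      dbi_dtw(s, list(centroids = fit_b$centroids, cluster = boot)))
  }
  per_iter <- data.frame(iteration = seq_len(n_iter),
                         jaccard_mean = rowMeans(jac, na.rm = TRUE),
                         silhouette = ss, dbi = dbi)
  list(per_iteration = per_iter,
       jaccard_mean = colMeans(jac, na.rm = TRUE),
       jaccard_sd = apply(jac, 2L, stats::sd, na.rm = TRUE),
       summary = data.frame(
         metric = c("jaccard", "silhouette", "dbi"),
         mean = c(mean(per_iter$jaccard_mean), mean(ss), mean(dbi)),
         sd = c(stats::sd(per_iter$jaccard_mean), stats::sd(ss),
                stats::sd(dbi))),
       reference = reference)
}
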