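# Directed patient graph (DPG): nodes are enhanced encounter windows; edges
# join each node to its top-k Jaccard-similar encounters (across the whole
# cohort) and consecutive windows of the same patient, always oriented from
# the earlier encounter to the later one and weighted by elapsed days.

#' Jaccard similarity of two binary vectors
#'
#' |u AND v| / |u OR v|, defined as 0 when both vectors are all-zero.
#'
#' @param u,v equal-length binary (0/1 or logical) vectors
#' @return similarity in [0, 1]
#' @export
jaccard_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  u <- as.logical(u); v <- as.logical(v)
  uni <- sum(u | v)
  if (uni == 0L) return(0)
  sum(u & v) / uni
}

#' Build the directed patient graph
#'
#' For every node the `k` most Jaccard-similar other nodes (ties broken by
#' descending similarity, then node order, i.e. (patient_id, window_index))
#' become candidate edges, oriented from the earlier window date to the later
#' one; same-date pairs are oriented by node order so rebuilding the graph is
#' deterministic. Consecutive windows of each patient are always connected.
#' Edge weight is the elapsed time in days (>= 0). Self-loops and duplicate
#' edges are never produced.
#'
#' @param features an `encounter_features` object from [vectorize_cohort()]
#' @param k number of similarity neighbors per node (clamped with a warning
#'   when it reaches the candidate-pool size)
#' @param cross_patient_only restrict similarity candidates to other
#'   patients' windows (default). A patient's consecutive windows are
#'   already chained by temporal edges, and chronic conditions make a
#'   patient's own windows trivially self-similar, so admitting them would
#'   spend the similarity budget without linking comparable patients.
#' @param block_size rows per block in the exact pairwise Jaccard search
#' @return object of class `progression_graph` with `nodes`, `edges`
#'   (src, dst, elapsed_days, type, origin), the feature matrix `X` and `k`
#' @export
build_dpg <- function(features, k = 25L, cross_patient_only = TRUE,
                      block_size = 1024L) {
  stopifnot(inherits(features, "encounter_features"), k >= 1L)
  X <- features$X
  meta <- features$windows
  n <- nrow(X)
  pid <- as.integer(factor(meta$patient_id))
  max_pool <- if (cross_patient_only) n - max(tabulate(pid)) else n - 1L
  if (k > max_pool) {
    warning(sprintf("k = %d exceeds the candidate pool (%d); clamping",
                    k, max_pool))
    k <- max(1L, max_pool)
  }
  storage.mode(X) <- "double"
  rs <- rowSums(X)
  nbr <- matrix(0L, n, k)
  admissible <- matrix(TRUE, n, k)   # excluded candidates never become edges
  for (from in seq(1L, n, by = block_size)) {
    to <- min(from + block_size - 1L, n)
    inter <- tcrossprod(X[from:to, , drop = FALSE], X)
    uni <- outer(rs[from:to], rs, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
    if (cross_patient_only) {
      sim[outer(pid[from:to], pid, "==")] <- -Inf
    } else {
      sim[cbind(seq_len(to - from + 1L), from:to)] <- -Inf  # no self edges
    }
    for (r in seq_len(to - from + 1L)) {
      top <- order(-sim[r, ], seq_len(n))[seq_len(k)]
      nbr[from + r - 1L, ] <- top
      admissible[from + r - 1L, ] <- is.finite(sim[r, top])
    }
  }

  origin <- rep(seq_len(n), each = k)[as.vector(t(admissible))]
  target <- as.integer(t(nbr))[as.vector(t(admissible))]
  d_o <- meta$window_start[origin]
  d_t <- meta$window_start[target]
  # orient earlier -> later; same-date ties by node order
  fwd <- (d_o < d_t) | (d_o == d_t & origin < target)
  src <- ifelse(fwd, origin, target)
  dst <- ifelse(fwd, target, origin)
  sim_edges <- data.frame(src = src, dst = dst,
                          elapsed_days = as.integer(abs(as.numeric(d_t - d_o))),
                          type = rep("similarity", length(src)),
                          origin = origin)

  # within-patient consecutive-window chain
  same_patient <- meta$patient_id[-n] == meta$patient_id[-1L]
  chain_src <- which(same_patient)
  tmp_edges <- data.frame(
    src = chain_src, dst = chain_src + 1L,
    elapsed_days = as.integer(meta$window_start[chain_src + 1L] -
                                meta$window_start[chain_src]),
    type = "temporal", origin = NA_integer_)

  edges <- rbind(tmp_edges, sim_edges)
  dup <- duplicated(edges[c("src", "dst")])
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- meta
  nodes$node_id <- seq_len(n)
  structure(list(nodes = nodes, edges = edges, X = features$X,
                 feature_space = features$feature_space, k = k),
            class = "progression_graph")
}

#' @export
print.progression_graph <- function(x, ...) {
  cat(sprintf("<progression_graph> %d nodes, %d edges (k = %d)\n",
              nrow(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Check the structural invariants of a progression graph
#'
#' Asserts chronology (every edge runs from an earlier-or-equal date to a
#' later one), absence of self-loops and duplicate edges, connectivity of
#' each patient's window chain, and the similarity-degree bound (each node
#' originates at most `k` similarity edges). Errors on first violation.
#'
#' @param graph a `progression_graph`
#' @return TRUE, invisibly
#' @export
validate_dpg <- function(graph) {
  stopifnot(inherits(graph, "progression_graph"))
  e <- graph$edges
  d <- graph$nodes$window_start
  if (any(d[e$src] > d[e$dst])) stop("chronology violated", call. = FALSE)
  if (any(e$src == e$dst)) stop("self-loop present", call. = FALSE)
  if (any(duplicated(e[c("src", "dst")]))) stop("duplicate edge",
                                                call. = FALSE)
  if (any(e$elapsed_days != as.integer(d[e$dst] - d[e$src]))) {
    stop("edge weight is not the elapsed time in days", call. = FALSE)
  }
  sim_per_origin <- table(e$origin[e$type == "similarity"])
  if (length(sim_per_origin) && max(sim_per_origin) > graph$k) {
    stop("similarity degree bound exceeded", call. = FALSE)
  }
  pieces <- split(graph$nodes$node_id, graph$nodes$patient_id)
  chain_ok <- vapply(pieces, function(v) {
    if (length(v) < 2L) return(TRUE)
    all(paste(v[-length(v)], v[-1L]) %in% paste(e$src, e$dst))
  }, logical(1))
  if (!all(chain_ok)) stop("patient window chain broken", call. = FALSE)
  invisible(TRUE)
}

directed_adjacency <- function(graph, connectivity = c("binary", "exp_decay"),
                               tau = 365) {
  connectivity <- match.arg(connectivity)
  e <- graph$edges
  n <- nrow(graph$nodes)
  w <- if (connectivity == "binary") rep(1, nrow(e))
       else exp(-e$elapsed_days / tau)
  Matrix::sparseMatrix(i = e$src, j = e$dst, x = w, dims = c(n, n))
}

#' Magnetic Laplacian of a progression graph
#'
#' Builds the complex Hermitian (magnetic) Laplacian encoding edge direction
#' in a phase: with directed adjacency A, symmetrization
#' `A_s = (A + t(A)) / 2`, phase `Theta = 2 pi q (A - t(A))` on the 0/1
#' connectivity pattern, and `H = A_s * exp(i Theta)`, the normalized form is
#' `L = I - D_s^{-1/2} H D_s^{-1/2}` with `D_s` the degree of `A_s`. `q = 0`
#' recovers the symmetrized normalized Laplacian; `q = 0.25` makes a one-way
#' edge purely imaginary. Eigenvalues are real and lie in [0, 2].
#'
#' The elapsed-time edge weights are available through
#' `connectivity = "exp_decay"` (weight `exp(-days/tau)`); the default
#' consumes 0/1 connectivity, with direction carried by the phase only.
#'
#' @param graph a `progression_graph`
#' @param q charge parameter in [0, 0.25]
#' @param connectivity "binary" or "exp_decay"
#' @param tau decay scale in days for `exp_decay`
#' @return object of class `magnetic_laplacian` with sparse real/imaginary
#'   parts `L_re`, `L_im`, `H_re`, `H_im`, degree vector and `q`
#' @export
magnetic_laplacian <- function(graph, q = 0.25,
                               connectivity = c("binary", "exp_decay"),
                               tau = 365) {
  stopifnot(inherits(graph, "progression_graph"))
  if (q < 0 || q > 0.25) stop("q must be in [0, 0.25]", call. = FALSE)
  if (nrow(graph$nodes) == 0L) stop("empty graph", call. = FALSE)
  connectivity <- match.arg(connectivity)
  e <- graph$edges
  n <- nrow(graph$nodes)
  if (any(duplicated(rbind(e[c("src", "dst")],
                           setNames(e[c("dst", "src")], c("src", "dst")))))) {
    stop("reciprocal directed edges are not representable", call. = FALSE)
  }
  w <- if (connectivity == "binary") rep(1, nrow(e))
       else exp(-e$elapsed_days / tau)
  # A_s = (A + t(A))/2 entrywise; an edge (u,v) contributes w/2 at (u,v) and
  # (v,u), with phases +2*pi*q and -2*pi*q respectively
  i <- c(e$src, e$dst); j <- c(e$dst, e$src)
  x <- rep(w, 2L) / 2
  theta <- rep(c(2, -2) * pi * q, each = nrow(e))
  As <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  H_re <- Matrix::sparseMatrix(i = i, j = j, x = x * cos(theta),
                               dims = c(n, n))
  H_im <- Matrix::sparseMatrix(i = i, j = j, x = x * sin(theta),
                               dims = c(n, n))
  deg <- Matrix::rowSums(As)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dm <- Matrix::Diagonal(x = dinv)
  N_re <- Dm %*% H_re %*% Dm
  N_im <- Dm %*% H_im %*% Dm
  L_re <- Matrix::Diagonal(nrow(As)) - N_re
  L_im <- -N_im
  structure(list(q = q, H_re = H_re, H_im = H_im, L_re = L_re, L_im = L_im,
                 degree = deg, connectivity = connectivity),
            class = "magnetic_laplacian")
}

#' Dense complex matrix form of a magnetic Laplacian
#' @param ml a `magnetic_laplacian`
#' @param which "laplacian" or "hermitian"
#' @return dense complex matrix
#' @export
as_complex_matrix <- function(ml, which = c("laplacian", "hermitian")) {
  which <- match.arg(which)
  if (which == "laplacian") {
    as.matrix(ml$L_re) + 1i * as.matrix(ml$L_im)
  } else {
    as.matrix(ml$H_re) + 1i * as.matrix(ml$H_im)
  }
}
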