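# Outcome-oriented representation learning on the DPG: two graph-convolution
# layers and a fully connected softmax head predicting the next-window
# progression state, trained end-to-end by gradient descent (Adam).
#
# Four encoder variants are provided. MagNet operates on the directed graph
# through the magnetic propagation operator (complex Hermitian, phase 2*pi*q
# per edge direction) with a complex channel whose real and imaginary parts
# are concatenated before the head; GCN, GAT and GraphSAGE operate on the
# symmetrized graph with their standard propagation rules. All variants
# produce embeddings of dimension `embedding_dim` (MagNet splits it across
# the real and imaginary channels). Forward and backward passes are written
# explicitly and are checked against numerical gradients in the test suite.

#' Encoder configuration
#'
#' @param variant one of "magnet", "gcn", "gat", "graphsage"
#' @param embedding_dim node-embedding dimension (32 or 64 in the study
#'   settings; any positive even number for MagNet)
#' @param loss "focal" or "cross_entropy"
#' @param focal_gamma focusing parameter, ignored unless `loss = "focal"`
#' @param q magnetic charge parameter in [0, 0.25] (MagNet only)
#' @param dropout probability of dropping a hidden unit between the two
#'   convolution layers during training (inverted dropout; evaluation and
#'   embedding extraction always use the full network). The 0.5 default is
#'   the convention of the standard GCN/GAT implementations and keeps the
#'   learned representation from collapsing onto the three outcome classes.
#' @param learning_rate,epochs,patience Adam step size, epoch budget and
#'   early-stopping patience on validation loss
#' @param connectivity,tau how the convolution consumes edge weights:
#'   "binary" (default; direction only) or "exp_decay" (weight
#'   exp(-days/tau))
#' @param seed RNG seed controlling initialization and the patient split
#' @return object of class `encoder_config`
#' @export
encoder_config <- function(variant = c("magnet", "gcn", "gat", "graphsage"),
                           embedding_dim = 32L, loss = c("focal",
                                                         "cross_entropy"),
                           focal_gamma = 2, q = 0.25, dropout = 0.5,
                           learning_rate = 1e-3,
                           epochs = 200L, patience = 20L,
                           connectivity = c("binary", "exp_decay"),
                           tau = 365, seed = 1L) {
  variant <- match.arg(variant)
  loss <- match.arg(loss)
  if (embedding_dim <= 0L) stop("embedding_dim must be positive",
                                call. = FALSE)
  if (variant == "magnet" && embedding_dim %% 2L != 0L) {
    stop("MagNet splits embedding_dim across real/imaginary channels; use an even dimension",
         call. = FALSE)
  }
  if (focal_gamma < 0) stop("focal_gamma must be >= 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  structure(list(variant = variant, embedding_dim = as.integer(embedding_dim),
                 n_layers = 2L, loss = loss, focal_gamma = focal_gamma, q = q,
                 dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 connectivity = match.arg(connectivity), tau = tau,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Focal loss for multiclass probabilities
#'
#' Mean over samples of `-(1 - p_true)^gamma * log(p_true)`, with
#' probabilities clipped at 1e-12. `gamma = 0` reduces exactly to
#' cross-entropy; the loss is non-negative and non-increasing in the
#' probability assigned to the true class.
#'
#' @param prob matrix of class probabilities (rows sum to 1)
#' @param labels true class per row: integer column indices or values of
#'   `colnames(prob)`
#' @param gamma focusing parameter >= 0
#' @return scalar loss
#' @export
focal_loss <- function(prob, labels, gamma = 2) {
  prob <- rbind(prob)
  if (is.character(labels) || is.factor(labels)) {
    labels <- match(as.character(labels), colnames(prob))
  }
  stopifnot(length(labels) == nrow(prob), all(labels >= 1),
            all(labels <= ncol(prob)), gamma >= 0)
  pt <- pmax(prob[cbind(seq_len(nrow(prob)), labels)], 1e-12)
  mean(-(1 - pt)^gamma * log(pt))
}

# loss + gradient wrt logits, averaged over masked rows
softmax_loss_grad <- function(logits, y, rows, loss, gamma) {
  lg <- logits[rows, , drop = FALSE]
  lg <- lg - apply(lg, 1L, max)
  p <- exp(lg)
  p <- p / rowSums(p)
  yv <- y[rows]
  m <- length(rows)
  pt <- pmax(p[cbind(seq_len(m), yv)], 1e-12)
  onehot <- matrix(0, m, ncol(p))
  onehot[cbind(seq_len(m), yv)] <- 1
  if (loss == "cross_entropy" || gamma == 0) {
    value <- mean(-log(pt))
    dlg <- (p - onehot) / m
  } else {
    value <- mean(-(1 - pt)^gamma * log(pt))
    # d/dp_t of -(1-p)^g log p, then chain through softmax
    dg_dpt <- gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
    dpt_dlg <- pt * (onehot - p)   # m x C
    dlg <- (dg_dpt / m) * dpt_dlg
  }
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[rows, ] <- dlg
  list(value = value, dlogits = dlogits, prob = p)
}

relu <- function(x) pmax(x, 0)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, ex) ifelse(x > 0, 1, ex + 1)

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

group_sum <- function(values, index, n) {
  values <- cbind(values)
  agg <- rowsum(values, index)
  out <- matrix(0, n, ncol(values))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# ---- propagation operators --------------------------------------------

# MagNet: P = D^-1/2 (A_s + I) exp(i Theta) D^-1/2 with self-loops at phase 0
magnet_propagation <- function(graph, q, connectivity, tau) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  w <- if (connectivity == "binary") rep(1, nrow(e))
       else exp(-e$elapsed_days / tau)
  i <- c(e$src, e$dst, seq_len(n))
  j <- c(e$dst, e$src, seq_len(n))
  x <- c(rep(w, 2L) / 2, rep(1, n))
  theta <- c(rep(c(2, -2) * pi * q, each = nrow(e)), rep(0, n))
  As <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  dinv <- 1 / sqrt(Matrix::rowSums(As))
  sc <- dinv[i] * dinv[j]
  list(re = Matrix::sparseMatrix(i = i, j = j, x = x * cos(theta) * sc,
                                 dims = c(n, n)),
       im = Matrix::sparseMatrix(i = i, j = j, x = x * sin(theta) * sc,
                                 dims = c(n, n)))
}

symmetric_pattern <- function(graph) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  Matrix::sparseMatrix(i = c(e$src, e$dst), j = c(e$dst, e$src),
                       x = 1, dims = c(n, n))
}

# GCN: P = D^-1/2 (A_sym + I) D^-1/2 on the symmetrized 0/1 graph
gcn_propagation <- function(graph) {
  A <- symmetric_pattern(graph)
  A@x <- rep(1, length(A@x))        # collapse any duplicate accumulation
  A <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

# GraphSAGE: row-normalized neighbor averaging (no self term; the self
# channel has its own weight matrix)
sage_propagation <- function(graph) {
  A <- symmetric_pattern(graph)
  A@x <- rep(1, length(A@x))
  d <- Matrix::rowSums(A)
  Matrix::Diagonal(x = ifelse(d > 0, 1 / d, 0)) %*% A
}

# GAT: symmetric edge list with self-loops, as (target, source) pairs
gat_edges <- function(graph) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  ti <- c(e$src, e$dst, seq_len(n))
  sj <- c(e$dst, e$src, seq_len(n))
  keep <- !duplicated(cbind(ti, sj))
  list(ti = ti[keep], sj = sj[keep], n = n)
}

# ---- parameter initialization -----------------------------------------

init_params <- function(cfg, d_in, n_class = 3L) {
  h <- if (cfg$variant == "magnet") cfg$embedding_dim %/% 2L
       else cfg$embedding_dim
  p <- switch(cfg$variant,
    magnet = list(W1 = glorot(d_in, h), b1r = numeric(h), b1i = numeric(h),
                  W2 = glorot(h, h), b2r = numeric(h), b2i = numeric(h)),
    gcn = list(W1 = glorot(d_in, h), b1 = numeric(h),
               W2 = glorot(h, h), b2 = numeric(h)),
    graphsage = list(W1s = glorot(d_in, h), W1n = glorot(d_in, h),
                     b1 = numeric(h), W2s = glorot(h, h),
                     W2n = glorot(h, h), b2 = numeric(h)),
    gat = list(W1 = glorot(d_in, h), a1t = glorot(h, 1), a1s = glorot(h, 1),
               b1 = numeric(h), W2 = glorot(h, h), a2t = glorot(h, 1),
               a2s = glorot(h, 1), b2 = numeric(h))
  )
  p$Wh <- glorot(cfg$embedding_dim, n_class)
  p$bh <- numeric(n_class)
  p
}

# ---- forward / backward per variant -----------------------------------
# Each forward returns logits, the embedding matrix U and a cache; each
# backward consumes dlogits and returns gradients named like the params.

magnet_fwd <- function(params, pre, mask = NULL) {
  S1r <- pre$A0r %*% params$W1
  S1r <- sweep(S1r, 2L, params$b1r, "+")
  S1i <- pre$A0i %*% params$W1
  S1i <- sweep(S1i, 2L, params$b1i, "+")
  Z1r <- relu(S1r); Z1i <- relu(S1i)
  if (!is.null(mask)) { Z1r <- Z1r * mask; Z1i <- Z1i * mask }
  M1r <- as.matrix(pre$Pre %*% Z1r - pre$Pim %*% Z1i)
  M1i <- as.matrix(pre$Pre %*% Z1i + pre$Pim %*% Z1r)
  S2r <- sweep(M1r %*% params$W2, 2L, params$b2r, "+")
  S2i <- sweep(M1i %*% params$W2, 2L, params$b2i, "+")
  Z2r <- relu(S2r); Z2i <- relu(S2i)
  U <- cbind(Z2r, Z2i)
  logits <- sweep(U %*% params$Wh, 2L, params$bh, "+")
  list(logits = logits, U = U,
       cache = list(S1r = S1r, S1i = S1i, Z1r = Z1r, Z1i = Z1i, M1r = M1r,
                    M1i = M1i, S2r = S2r, S2i = S2i, mask = mask))
}

magnet_bwd <- function(params, pre, cache, U, dlogits) {
  h <- ncol(params$W2)
  dWh <- crossprod(U, dlogits); dbh <- colSums(dlogits)
  dU <- dlogits %*% t(params$Wh)
  dZ2r <- dU[, seq_len(h), drop = FALSE]
  dZ2i <- dU[, h + seq_len(h), drop = FALSE]
  dS2r <- dZ2r * (cache$S2r > 0); dS2i <- dZ2i * (cache$S2i > 0)
  dW2 <- crossprod(cache$M1r, dS2r) + crossprod(cache$M1i, dS2i)
  db2r <- colSums(dS2r); db2i <- colSums(dS2i)
  dM1r <- dS2r %*% t(params$W2); dM1i <- dS2i %*% t(params$W2)
  PreT <- pre$PreT; PimT <- pre$PimT
  dZ1r <- as.matrix(PreT %*% dM1r + PimT %*% dM1i)
  dZ1i <- as.matrix(-PimT %*% dM1r + PreT %*% dM1i)
  if (!is.null(cache$mask)) {
    dZ1r <- dZ1r * cache$mask
    dZ1i <- dZ1i * cache$mask
  }
  dS1r <- dZ1r * (cache$S1r > 0); dS1i <- dZ1i * (cache$S1i > 0)
  dW1 <- crossprod(pre$A0r, dS1r) + crossprod(pre$A0i, dS1i)
  list(W1 = as.matrix(dW1), b1r = colSums(dS1r), b1i = colSums(dS1i),
       W2 = dW2, b2r = db2r, b2i = db2i, Wh = dWh, bh = dbh)
}

gcn_fwd <- function(params, pre, mask = NULL) {
  S1 <- sweep(pre$A0 %*% params$W1, 2L, params$b1, "+")
  Z1 <- relu(S1)
  if (!is.null(mask)) Z1 <- Z1 * mask
  M1 <- as.matrix(pre$P %*% Z1)
  S2 <- sweep(M1 %*% params$W2, 2L, params$b2, "+")
  Z2 <- relu(S2)
  logits <- sweep(Z2 %*% params$Wh, 2L, params$bh, "+")
  list(logits = logits, U = Z2, cache = list(S1 = S1, Z1 = Z1, M1 = M1,
                                             S2 = S2, mask = mask))
}

gcn_bwd <- function(params, pre, cache, U, dlogits) {
  dWh <- crossprod(U, dlogits); dbh <- colSums(dlogits)
  dZ2 <- dlogits %*% t(params$Wh)
  dS2 <- dZ2 * (cache$S2 > 0)
  dW2 <- crossprod(cache$M1, dS2); db2 <- colSums(dS2)
  dM1 <- dS2 %*% t(params$W2)
  dZ1 <- as.matrix(pre$PT %*% dM1)
  if (!is.null(cache$mask)) dZ1 <- dZ1 * cache$mask
  dS1 <- dZ1 * (cache$S1 > 0)
  dW1 <- as.matrix(crossprod(pre$A0, dS1))
  list(W1 = dW1, b1 = colSums(dS1), W2 = dW2, b2 = db2, Wh = dWh, bh = dbh)
}

sage_fwd <- function(params, pre, mask = NULL) {
  S1 <- sweep(pre$X %*% params$W1s + pre$MX %*% params$W1n, 2L, params$b1,
              "+")
  Z1 <- relu(S1)
  if (!is.null(mask)) Z1 <- Z1 * mask
  MZ1 <- as.matrix(pre$M %*% Z1)
  S2 <- sweep(Z1 %*% params$W2s + MZ1 %*% params$W2n, 2L, params$b2, "+")
  Z2 <- relu(S2)
  logits <- sweep(Z2 %*% params$Wh, 2L, params$bh, "+")
  list(logits = logits, U = Z2,
       cache = list(S1 = S1, Z1 = Z1, MZ1 = MZ1, S2 = S2, mask = mask))
}

sage_bwd <- function(params, pre, cache, U, dlogits) {
  dWh <- crossprod(U, dlogits); dbh <- colSums(dlogits)
  dZ2 <- dlogits %*% t(params$Wh)
  dS2 <- dZ2 * (cache$S2 > 0)
  dW2s <- crossprod(cache$Z1, dS2)
  dW2n <- crossprod(cache$MZ1, dS2)
  db2 <- colSums(dS2)
  dZ1 <- dS2 %*% t(params$W2s) +
    as.matrix(pre$MT %*% (dS2 %*% t(params$W2n)))
  if (!is.null(cache$mask)) dZ1 <- dZ1 * cache$mask
  dS1 <- dZ1 * (cache$S1 > 0)
  list(W1s = as.matrix(crossprod(pre$X, dS1)),
       W1n = as.matrix(crossprod(pre$MX, dS1)),
       b1 = colSums(dS1), W2s = dW2s, W2n = dW2n, b2 = db2,
       Wh = dWh, bh = dbh)
}

gat_layer_fwd <- function(Z, W, at, as_, b, ed) {
  g <- Z %*% W
  st <- as.numeric(g %*% at)
  ss <- as.numeric(g %*% as_)
  epre <- st[ed$ti] + ss[ed$sj]
  e <- ifelse(epre > 0, epre, 0.2 * epre)
  mx <- tapply(e, ed$ti, max)
  a <- as.numeric(exp(e - mx[as.character(ed$ti)]))
  denom <- group_sum(a, ed$ti, ed$n)[, 1L]
  alpha <- a / denom[ed$ti]
  agg <- group_sum(alpha * g[ed$sj, , drop = FALSE], ed$ti, ed$n)
  S <- sweep(agg, 2L, b, "+")
  ex <- elu(S)
  list(out = ex, cache = list(Z = Z, g = g, epre = epre, alpha = alpha,
                              S = S, ex = ex))
}

gat_layer_bwd <- function(dout, W, at, as_, cache, ed) {
  dS <- dout * elu_grad(cache$S, cache$ex)
  db <- colSums(dS)
  g <- cache$g; alpha <- cache$alpha
  dg <- group_sum(alpha * dS[ed$ti, , drop = FALSE], ed$sj, ed$n)
  dalpha <- rowSums(dS[ed$ti, , drop = FALSE] * g[ed$sj, , drop = FALSE])
  ssum <- group_sum(alpha * dalpha, ed$ti, ed$n)[, 1L]
  de <- alpha * (dalpha - ssum[ed$ti])
  de <- de * ifelse(cache$epre > 0, 1, 0.2)
  dst <- group_sum(de, ed$ti, ed$n)[, 1L]
  dss <- group_sum(de, ed$sj, ed$n)[, 1L]
  dg <- dg + outer(dst, as.numeric(at)) + outer(dss, as.numeric(as_))
  dat <- crossprod(g, dst)
  das <- crossprod(g, dss)
  dW <- crossprod(cache$Z, dg)
  dZ <- dg %*% t(W)
  list(dZ = dZ, dW = dW, dat = dat, das = das, db = db)
}

gat_fwd <- function(params, pre, mask = NULL) {
  l1 <- gat_layer_fwd(pre$X, params$W1, params$a1t, params$a1s, params$b1,
                      pre$ed)
  h1 <- if (is.null(mask)) l1$out else l1$out * mask
  l2 <- gat_layer_fwd(h1, params$W2, params$a2t, params$a2s, params$b2,
                      pre$ed)
  logits <- sweep(l2$out %*% params$Wh, 2L, params$bh, "+")
  list(logits = logits, U = l2$out, cache = list(l1 = l1$cache,
                                                 l2 = l2$cache,
                                                 mask = mask))
}

gat_bwd <- function(params, pre, cache, U, dlogits) {
  dWh <- crossprod(U, dlogits); dbh <- colSums(dlogits)
  dZ2 <- dlogits %*% t(params$Wh)
  b2 <- gat_layer_bwd(dZ2, params$W2, params$a2t, params$a2s, cache$l2,
                      pre$ed)
  dh1 <- if (is.null(cache$mask)) b2$dZ else b2$dZ * cache$mask
  b1 <- gat_layer_bwd(dh1, params$W1, params$a1t, params$a1s, cache$l1,
                      pre$ed)
  list(W1 = b1$dW, a1t = b1$dat, a1s = b1$das, b1 = b1$db,
       W2 = b2$dW, a2t = b2$dat, a2s = b2$das, b2 = b2$db,
       Wh = dWh, bh = dbh)
}

# Precomputed, parameter-independent quantities per variant.
precompute <- function(graph, cfg) {
  X <- graph$X
  storage.mode(X) <- "double"
  switch(cfg$variant,
    magnet = {
      P <- magnet_propagation(graph, cfg$q, cfg$connectivity, cfg$tau)
      list(Pre = P$re, Pim = P$im, PreT = Matrix::t(P$re),
           PimT = Matrix::t(P$im),
           A0r = as.matrix(P$re %*% X), A0i = as.matrix(P$im %*% X))
    },
    gcn = {
      P <- gcn_propagation(graph)
      list(P = P, PT = Matrix::t(P), A0 = as.matrix(P %*% X))
    },
    graphsage = {
      M <- sage_propagation(graph)
      list(M = M, MT = Matrix::t(M), X = X, MX = as.matrix(M %*% X))
    },
    gat = list(X = X, ed = gat_edges(graph))
  )
}

variant_fwd <- function(cfg) switch(cfg$variant, magnet = magnet_fwd,
                                    gcn = gcn_fwd, graphsage = sage_fwd,
                                    gat = gat_fwd)
variant_bwd <- function(cfg) switch(cfg$variant, magnet = magnet_bwd,
                                    gcn = gcn_bwd, graphsage = sage_bwd,
                                    gat = gat_bwd)

# single loss + gradient evaluation (also the hook for numerical checks)
gnn_loss_grads <- function(params, pre, cfg, y, rows, mask = NULL) {
  fwd <- variant_fwd(cfg)(params, pre, mask)
  lg <- softmax_loss_grad(fwd$logits, y, rows, cfg$loss, cfg$focal_gamma)
  grads <- variant_bwd(cfg)(params, pre, fwd$cache, fwd$U, lg$dlogits)
  list(value = lg$value, grads = grads, logits = fwd$logits, U = fwd$U)
}

# ---- training ----------------------------------------------------------

#' Patient-level train/validation/test split
#'
#' Patients (not windows) are assigned to the three sets so no patient
#' contributes nodes to more than one of them.
#'
#' @param graph a `progression_graph`
#' @param fractions train/val/test proportions summing to 1
#' @param seed RNG seed
#' @return list of patient-id vectors `train`, `val`, `test`
#' @export
patient_split <- function(graph, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  ids <- unique(graph$nodes$patient_id)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  perm <- sample(ids)
  n <- length(ids)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = perm[seq_len(n_tr)],
       val = perm[n_tr + seq_len(min(n_va, n - n_tr))],
       test = perm[setdiff(seq_len(n), seq_len(n_tr + n_va))])
}

labeled_rows <- function(graph, patients) {
  which(graph$nodes$patient_id %in% patients & !is.na(graph$nodes$label))
}

#' Train a GNN encoder on a progression graph
#'
#' Full-graph (transductive) training with patient-level label masks: the
#' supervised loss is computed on training patients' labeled windows (each
#' patient's final window carries no label), validation loss drives early
#' stopping and best-checkpoint selection, and test patients are held out
#' entirely from the loss. Optimization is Adam; the run is seeded and
#' reproducible.
#'
#' @param graph a `progression_graph`
#' @param cfg an [encoder_config()]
#' @param split optional [patient_split()]; built from `cfg$seed` when NULL
#' @param verbose print epoch losses every 20 epochs
#' @return object of class `gnn_fit`: best `params`, `cfg`, `split`,
#'   `history` (per-epoch train/val loss) and the epoch of the best
#'   checkpoint
#' @export
train_gnn <- function(graph, cfg, split = NULL, verbose = FALSE) {
  stopifnot(inherits(graph, "progression_graph"),
            inherits(cfg, "encoder_config"))
  split <- split %||% patient_split(graph, seed = cfg$seed)
  y <- match(graph$nodes$label, STATE_LEVELS)
  rows_tr <- labeled_rows(graph, split$train)
  rows_va <- labeled_rows(graph, split$val)
  if (length(rows_tr) == 0L) stop("no labeled training nodes", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  pre <- precompute(graph, cfg)
  params <- init_params(cfg, ncol(graph$X))

  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  stale <- 0L
  h_mask <- if (cfg$variant == "magnet") cfg$embedding_dim %/% 2L
            else cfg$embedding_dim
  for (epoch in seq_len(cfg$epochs)) {
    mask <- if (cfg$dropout > 0) {
      matrix((stats::runif(nrow(graph$X) * h_mask) >= cfg$dropout) /
               (1 - cfg$dropout), nrow(graph$X), h_mask)
    } else NULL
    lgr <- gnn_loss_grads(params, pre, cfg, y, rows_tr, mask)
    if (!is.finite(lgr$value)) {
      stop(sprintf("non-finite training loss at epoch %d", epoch),
           call. = FALSE)
    }
    for (nm in names(lgr$grads)) {
      g <- lgr$grads[[nm]]
      m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
      v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
      mhat <- m_state[[nm]] / (1 - beta1^epoch)
      vhat <- v_state[[nm]] / (1 - beta2^epoch)
      params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat /
        (sqrt(vhat) + eps)
    }
    val_loss <- if (length(rows_va) > 0L) {
      fwd <- variant_fwd(cfg)(params, pre)
      softmax_loss_grad(fwd$logits, y, rows_va, cfg$loss,
                        cfg$focal_gamma)$value
    } else lgr$value
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = lgr$value,
                                         val_loss = val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
    if (verbose && epoch %% 20L == 0L) {
      message(sprintf("epoch %d train %.4f val %.4f", epoch, lgr$value,
                      val_loss))
    }
  }
  structure(list(params = best$params, cfg = cfg, split = split,
                 history = history, best_epoch = best$epoch),
            class = "gnn_fit")
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat(sprintf("<gnn_fit> %s dim=%d loss=%s; best epoch %d (val loss %.4f)\n",
              x$cfg$variant, x$cfg$embedding_dim, x$cfg$loss, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

gnn_forward <- function(fit, graph) {
  pre <- precompute(graph, fit$cfg)
  variant_fwd(fit$cfg)(fit$params, pre)
}

#' Predicted next-window state probabilities
#' @param fit a `gnn_fit`
#' @param graph the `progression_graph` it was trained on
#' @return matrix (nodes x states) of softmax probabilities
#' @export
predict_gnn <- function(fit, graph) {
  logits <- gnn_forward(fit, graph)$logits
  lg <- logits - apply(logits, 1L, max)
  p <- exp(lg)
  p <- p / rowSums(p)
  colnames(p) <- STATE_LEVELS
  p
}

#' Evaluate next-window state prediction
#'
#' One-vs-rest AUROC plus sensitivity, specificity and precision per class
#' (argmax predictions) with macro averages, on the labeled windows of the
#' requested patient set. A class absent from the evaluation split yields NA
#' metrics rather than a silent 0.
#'
#' @param fit a `gnn_fit`
#' @param graph the `progression_graph`
#' @param which "test", "val", "train", or a vector of patient ids
#' @return list with `per_class`, `macro`, `accuracy`, `n`
#' @export
evaluate_gnn <- function(fit, graph, which = "test") {
  patients <- if (is.character(which) && length(which) == 1L &&
                  which %in% names(fit$split)) fit$split[[which]] else which
  rows <- labeled_rows(graph, patients)
  if (length(rows) == 0L) stop("no labeled nodes in evaluation set",
                               call. = FALSE)
  prob <- predict_gnn(fit, graph)[rows, , drop = FALSE]
  labels <- graph$nodes$label[rows]
  out <- classification_metrics(prob, labels)
  out$n <- length(rows)
  out
}

#' Patient-level k-fold cross-validation of an encoder
#'
#' Splits patients into `folds` groups; each fold is held out in turn while
#' the rest train (with a 1/9 validation share for early stopping). Reports
#' per-fold macro metrics with mean and sd, and a pooled recomputation over
#' all held-out predictions.
#'
#' @param graph a `progression_graph`
#' @param cfg an [encoder_config()]
#' @param folds number of folds
#' @return list with `per_fold`, `mean`, `sd`, `pooled`
#' @export
gnn_cv <- function(graph, cfg, folds = 10L) {
  ids <- unique(graph$nodes$patient_id)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  fold_of <- sample(rep_len(seq_len(folds), length(ids)))
  per_fold <- vector("list", folds)
  pooled_prob <- NULL; pooled_lab <- NULL
  for (f in seq_len(folds)) {
    test_ids <- ids[fold_of == f]
    rest <- ids[fold_of != f]
    val_ids <- rest[seq_len(max(1L, length(rest) %/% 9L))]
    split <- list(train = setdiff(rest, val_ids), val = val_ids,
                  test = test_ids)
    fit <- train_gnn(graph, cfg, split = split)
    rows <- labeled_rows(graph, test_ids)
    prob <- predict_gnn(fit, graph)[rows, , drop = FALSE]
    labels <- graph$nodes$label[rows]
    per_fold[[f]] <- classification_metrics(prob, labels)$macro
    pooled_prob <- rbind(pooled_prob, prob)
    pooled_lab <- c(pooled_lab, labels)
  }
  tab <- do.call(rbind, per_fold)
  list(per_fold = tab, mean = colMeans(tab, na.rm = TRUE),
       sd = apply(tab, 2L, stats::sd, na.rm = TRUE),
       pooled = classification_metrics(pooled_prob, pooled_lab))
}

#' Node embeddings from a trained encoder
#'
#' Extraction is deterministic and side-effect-free: the same fit and graph
#' always return the same matrix. For MagNet the embedding is the
#' concatenation of the real and imaginary channels.
#'
#' @param fit a `gnn_fit`
#' @param graph the `progression_graph`
#' @return matrix (nodes x embedding_dim)
#' @export
node_embeddings <- function(fit, graph) {
  gnn_forward(fit, graph)$U
}

#' Per-patient chronological embedding sequences
#'
#' With `scale = TRUE` (default) embedding units are standardized across all
#' windows before the sequences are cut -- the usual preprocessing for
#' time-series clustering, so that no single high-variance unit dominates
#' the pointwise Euclidean distances inside DTW. For the MagNet encoder the
#' unit is a complex number whose real and imaginary parts sit in separate
#' columns; each complex unit is centred and divided by one shared scale
#' (the square root of its total real-plus-imaginary variance), which
#' equalizes units while preserving the relative magnitude of the
#' direction-encoding imaginary channel instead of inflating it to unit
#' variance on its own.
#'
#' @param fit a `gnn_fit`
#' @param graph the `progression_graph`
#' @param scale standardize embedding units before sequence cutting
#' @return named list (patient id) of matrices, rows in window order; class
#'   `embedding_sequences`
#' @export
embedding_sequences <- function(fit, graph, scale = TRUE) {
  U <- node_embeddings(fit, graph)
  if (scale) {
    mu <- colMeans(U)
    U <- sweep(U, 2L, mu)
    if (fit$cfg$variant == "magnet") {
      h <- ncol(U) %/% 2L
      s <- sqrt(apply(U[, seq_len(h), drop = FALSE], 2L, stats::var) +
                  apply(U[, h + seq_len(h), drop = FALSE], 2L, stats::var))
      s[!is.finite(s) | s < 1e-12] <- 1
      U <- sweep(U, 2L, rep(s, 2L), "/")
    } else {
      s <- apply(U, 2L, stats::sd)
      s[!is.finite(s) | s < 1e-12] <- 1
      U <- sweep(U, 2L, s, "/")
    }
  }
  idx <- split(seq_len(nrow(U)), graph$nodes$patient_id)
  ord <- lapply(idx, function(iv) iv[order(graph$nodes$window_index[iv])])
  out <- lapply(ord, function(iv) U[iv, , drop = FALSE])
  class(out) <- "embedding_sequences"
  out
}
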