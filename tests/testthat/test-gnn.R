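# A small fixed graph shared across the encoder tests.
gnn_fixture <- function() {
  coh <- cached_cohort(20, seed = 3)
  fe <- vectorize_cohort(coh)
  build_dpg(fe, k = 3)
}

test_that("focal loss satisfies its identities", {
  set.seed(1)
  prob <- matrix(runif(30), 10, 3)
  prob <- prob / rowSums(prob)
  colnames(prob) <- c("PreMCI", "MCI", "AD")
  y <- sample(1:3, 10, replace = TRUE)
  # gamma = 0 equals cross-entropy
  ce <- mean(-log(prob[cbind(1:10, y)]))
  expect_equal(focal_loss(prob, y, gamma = 0), ce, tolerance = 1e-12)
  # perfect prediction gives zero loss
  hard <- diag(3)[rep(1:3, 3), ]
  colnames(hard) <- colnames(prob)
  expect_equal(focal_loss(hard, rep(1:3, 3), gamma = 2), 0)
  # hand-evaluated single case: p = 0.5, gamma = 2 -> 0.25 ln 2
  expect_equal(focal_loss(matrix(c(0.5, 0.3, 0.2), 1), 1, gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  # non-negative and non-increasing in p_true
  ps <- seq(0.05, 0.95, 0.05)
  vals <- vapply(ps, function(p) {
    focal_loss(matrix(c(p, 1 - p, 0), 1), 1, gamma = 2)
  }, numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) < 0))
  # label names are accepted
  expect_equal(focal_loss(prob, colnames(prob)[y], gamma = 2),
               focal_loss(prob, y, gamma = 2))
})

test_that("analytic gradients match numerical gradients for every variant", {
  g <- gnn_fixture()
  y <- match(g$nodes$label, progphen:::STATE_LEVELS)
  rows <- which(!is.na(y))[seq(1, 160, 4)]
  for (v in c("magnet", "gcn", "graphsage", "gat")) {
    for (loss in c("focal", "cross_entropy")) {
      ec <- encoder_config(variant = v, embedding_dim = 8, loss = loss,
                           q = 0.1, seed = 2)
      pre <- progphen:::precompute(g, ec)
      set.seed(5)
      params <- progphen:::init_params(ec, ncol(g$X))
      lg <- progphen:::gnn_loss_grads(params, pre, ec, y, rows)
      for (nm in names(params)) {
        len <- length(params[[nm]])
        for (t in seq_len(min(2L, len))) {
          i <- ((t * 13) %% len) + 1L
          eps <- 1e-5
          up <- params; up[[nm]][i] <- up[[nm]][i] + eps
          dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
          num <- (progphen:::gnn_loss_grads(up, pre, ec, y, rows)$value -
                    progphen:::gnn_loss_grads(dn, pre, ec, y, rows)$value) /
            (2 * eps)
          ana <- lg$grads[[nm]][i]
          expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
        }
      }
    }
  }
})

test_that("with no similarity edges, embeddings depend only on the patient chain; with no edges at all, only on own features", {
  g <- gnn_fixture()
  # drop every edge: each node sees only itself
  g0 <- g
  g0$edges <- g0$edges[0, ]
  ec <- encoder_config(variant = "magnet", embedding_dim = 8, q = 0.1,
                       seed = 4)
  set.seed(7)
  params <- progphen:::init_params(ec, ncol(g0$X))
  fit <- structure(list(params = params, cfg = ec), class = "gnn_fit")
  U <- node_embeddings(fit, g0)
  # identical feature rows must give identical embeddings
  i <- which(duplicated(g0$X) | duplicated(g0$X, fromLast = TRUE))
  if (length(i) >= 2) {
    pair <- which(apply(g0$X, 1, paste, collapse = "") ==
                    paste(g0$X[i[1], ], collapse = ""))
    expect_equal(U[pair[1], ], U[pair[2], ])
  }
  # perturbing another node's features leaves this node unchanged
  g1 <- g0
  g1$X[5, ] <- 1L - g1$X[5, ]
  U1 <- node_embeddings(fit, g1)
  expect_equal(U1[-5, ], U[-5, ])
})

test_that("embeddings are permutation-equivariant", {
  g <- gnn_fixture()
  ec <- encoder_config(variant = "gcn", embedding_dim = 8, seed = 4)
  set.seed(7)
  params <- progphen:::init_params(ec, ncol(g$X))
  fit <- structure(list(params = params, cfg = ec), class = "gnn_fit")
  U <- node_embeddings(fit, g)
  perm <- sample(nrow(g$X))
  gp <- g
  inv <- order(perm)
  gp$X <- g$X[perm, ]
  gp$nodes <- g$nodes[perm, ]
  gp$nodes$node_id <- seq_len(nrow(gp$nodes))
  gp$edges$src <- inv[g$edges$src]
  gp$edges$dst <- inv[g$edges$dst]
  Up <- node_embeddings(fit, gp)
  expect_equal(Up, U[perm, ], tolerance = 1e-10)
})

test_that("patient-level splits are disjoint and training is seeded-reproducible", {
  g <- gnn_fixture()
  sp <- patient_split(g, seed = 9)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test),
                  unique(g$nodes$patient_id))

  ec <- encoder_config(variant = "gcn", embedding_dim = 8, epochs = 15,
                       seed = 31)
  f1 <- train_gnn(g, ec)
  f2 <- train_gnn(g, ec)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-6)
  expect_identical(f1$params, f2$params)
  # embedding extraction is side-effect-free
  expect_identical(node_embeddings(f1, g), node_embeddings(f1, g))
})

test_that("all four variants produce embeddings of the configured dimension", {
  g <- gnn_fixture()
  for (v in c("magnet", "gcn", "gat", "graphsage")) {
    ec <- encoder_config(variant = v, embedding_dim = 16, epochs = 2,
                         seed = 1)
    fit <- train_gnn(g, ec)
    expect_equal(ncol(node_embeddings(fit, g)), 16L)
  }
  expect_error(encoder_config(variant = "magnet", embedding_dim = 15),
               "even")
})

test_that("evaluation metrics behave for perfect and constant predictors", {
  labels <- c("AD", "MCI", "PreMCI", "AD", "MCI", "PreMCI")
  perfect <- diag(3)[match(labels, c("PreMCI", "MCI", "AD")), c(1, 2, 3)]
  colnames(perfect) <- c("PreMCI", "MCI", "AD")
  m <- progphen:::classification_metrics(perfect, labels)
  expect_equal(unname(m$macro[["auroc"]]), 1)
  expect_equal(unname(m$macro[["sensitivity"]]), 1)
  expect_equal(m$accuracy, 1)
  constant <- matrix(rep(c(0.5, 0.3, 0.2), each = 6), 6,
                     dimnames = list(NULL, c("PreMCI", "MCI", "AD")))
  mc <- progphen:::classification_metrics(constant, labels)
  expect_equal(unname(mc$per_class[, "auroc"]), rep(0.5, 3))
  # a class absent from the labels yields NA metrics, not zero
  m2 <- progphen:::classification_metrics(constant[1:4, ],
                                          c("AD", "MCI", "AD", "MCI"))
  expect_true(is.na(m2$per_class["PreMCI", "auroc"]))
})

test_that("training on shuffled labels yields chance-level discrimination", {
  g <- gnn_fixture()
  set.seed(13)
  g$nodes$label[!is.na(g$nodes$label)] <-
    sample(g$nodes$label[!is.na(g$nodes$label)])
  ec <- encoder_config(variant = "gcn", embedding_dim = 8, epochs = 40,
                       seed = 13)
  fit <- train_gnn(g, ec)
  ev <- evaluate_gnn(fit, g, "test")
  expect_lt(abs(ev$macro[["auroc"]] - 0.5), 0.12)
})

test_that("identical twin nodes receive identical embeddings", {
  # two isolated nodes with equal features and no neighbors
  g <- random_digraph(4, p = 0, seed = 2)
  g$edges <- data.frame(src = 1L, dst = 2L, elapsed_days = 3L,
                        type = "similarity", origin = 1L)
  X <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6)
  X[4, ] <- X[3, ]   # twins: nodes 3 and 4, both isolated
  g$X <- X
  ec <- encoder_config(variant = "graphsage", embedding_dim = 6, seed = 3)
  set.seed(4)
  params <- progphen:::init_params(ec, ncol(X))
  fit <- structure(list(params = params, cfg = ec), class = "gnn_fit")
  U <- node_embeddings(fit, g)
  expect_equal(U[3, ], U[4, ], tolerance = 1e-12)
})
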