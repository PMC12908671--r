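test_that("encoder config enforces head divisibility", {
  expect_error(encoder_config(embed_dim = 10, n_heads = 4),
               class = "affipose_invalid_input")
  cfg <- encoder_config(32, 4, 2)
  expect_equal(cfg$d_head, 8L)
})

test_that("input projection is a linear lift with self-loops appended", {
  cfg <- tiny_cfg()
  set.seed(1)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  # zero features -> bias rows
  raw <- list(node = matrix(0, 3, 45), edge = matrix(0, 2, 12),
              idx = rbind(c(1, 2), c(2, 1)))
  st <- project_inputs(raw, par, cfg)
  expect_equal(st$node_emb, matrix(par$proj$bn, 3, cfg$embed_dim, byrow = TRUE))
  expect_equal(st$edge_emb[1, ], par$proj$be)
  expect_equal(st$edge_emb[3, ], par$proj$e_self)       # self-loop embedding
  expect_equal(nrow(st$edge_emb), 2 + 3)
  expect_equal(st$edge_index[3:5, ], cbind(1:3, 1:3))
  # single node
  one <- project_inputs(list(node = matrix(rnorm(45), 1),
                             edge = matrix(numeric(), 0, 12),
                             idx = matrix(integer(), 0, 2)), par, cfg)
  expect_equal(dim(one$node_emb), c(1L, cfg$embed_dim))
  # linearity: doubling a raw feature column doubles its pre-bias contribution
  r1 <- raw; r1$node[1, 5] <- 1
  r2 <- raw; r2$node[1, 5] <- 2
  s1 <- project_inputs(r1, par, cfg)$node_emb[1, ] - par$proj$bn
  s2 <- project_inputs(r2, par, cfg)$node_emb[1, ] - par$proj$bn
  expect_equal(s2, 2 * s1)
  expect_error(project_inputs(list(node = matrix(0, 2, 44),
                                   edge = matrix(numeric(), 0, 12),
                                   idx = matrix(integer(), 0, 2)), par, cfg),
               class = "affipose_dimension_error")
})

test_that("single-node layer matches a closed-form hand computation", {
  cfg <- encoder_config(embed_dim = 4, n_heads = 2, n_layers = 1,
                        dropout = 0, ffn_hidden = 8)
  set.seed(7)
  N <- matrix(rnorm(4), 1)
  E <- matrix(rnorm(4), 1)
  lpar <- affipose:::init_layer_params(cfg)
  state <- structure(list(node_emb = N, edge_emb = E,
                          edge_index = cbind(1L, 1L), is_self = TRUE, n = 1L,
                          grp_split = list(`1` = 1L)),
                     class = "graph_state")
  out <- attention_layer(state, lpar, cfg)
  # by hand: softmax over one logit is 1, so each head output is V itself
  V <- N %*% lpar$Wv
  node_mh <- V %*% lpar$Wo
  A1 <- matrix(1, 1, 2)
  edge_mh <- A1 %*% lpar$We_out
  N1 <- N + node_mh; E1 <- E + edge_mh
  ln <- function(x, g, b) {
    mu <- mean(x); sd_ <- sqrt(mean((x - mu)^2) + 1e-5)
    (x - mu) / sd_ * g + b
  }
  ffn <- function(x, W1, b1, W2, b2) pmax(x %*% W1 + rep(b1, each = 1), 0) %*% W2 + rep(b2, each = 1)
  N2 <- N1 + ffn(matrix(ln(N1, lpar$ln_n_g, lpar$ln_n_b), 1),
                 lpar$ffn_n_W1, lpar$ffn_n_b1, lpar$ffn_n_W2, lpar$ffn_n_b2)
  E2 <- E1 + ffn(matrix(ln(E1, lpar$ln_e_g, lpar$ln_e_b), 1),
                 lpar$ffn_e_W1, lpar$ffn_e_b1, lpar$ffn_e_W2, lpar$ffn_e_b2)
  expect_equal(out$node_emb, N2, tolerance = 1e-10)
  expect_equal(out$edge_emb, E2, tolerance = 1e-10)
})

test_that("with unit edge biases and one head the layer is standard masked attention", {
  # 4-node path graph; reference scaled-dot-product attention over neighbors
  cfg <- encoder_config(embed_dim = 6, n_heads = 1, n_layers = 1,
                        dropout = 0, ffn_hidden = 12)
  set.seed(11)
  n <- 4
  N <- matrix(rnorm(n * 6), n)
  idx <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3),
               cbind(1:4, 1:4))
  lpar <- affipose:::init_layer_params(cfg)
  # force the per-head edge scalar to exactly 1: E rows = e1, Wb column = e1
  lpar$Wb <- matrix(0, 6, 1); lpar$Wb[1, 1] <- 1
  E <- matrix(0, nrow(idx), 6); E[, 1] <- 1
  state <- structure(list(node_emb = N, edge_emb = E, edge_index = idx,
                          is_self = c(rep(FALSE, 6), rep(TRUE, 4)), n = n,
                          grp_split = split(seq_len(nrow(idx)),
                                            factor(idx[, 1], levels = 1:n))),
                     class = "graph_state")
  out <- attention_layer(state, lpar, cfg, keep_cache = TRUE)
  # independent reference implementation (dense masked softmax)
  Q <- N %*% lpar$Wq; K <- N %*% lpar$Wk; V <- N %*% lpar$Wv
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(idx))) adj[idx[r, 1], idx[r, 2]] <- TRUE
  ref_head <- matrix(0, n, 6)
  for (i in 1:n) {
    nb <- which(adj[i, ])
    lg <- (Q[i, ] %*% t(K[nb, , drop = FALSE])) / sqrt(6)
    w <- exp(lg - max(lg)); w <- w / sum(w)
    ref_head[i, ] <- as.numeric(w %*% V[nb, , drop = FALSE])
  }
  got_head <- attr(out, "cache")$O
  expect_equal(got_head, ref_head, tolerance = 1e-8)
})

test_that("attention rows are stochastic and support is restricted to neighbors", {
  cfg <- tiny_cfg()
  set.seed(5)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  g <- panel_mols()[[20]]   # largest panel molecule
  st <- project_inputs(g, par, cfg)
  out <- attention_layer(st, par$layers[[1]], cfg, keep_cache = TRUE)
  A <- attr(out, "cache")$A
  sums <- rowsum(A, st$edge_index[, 1])
  expect_true(all(abs(sums - 1) < 1e-6))
  # dense matrix built from the sparse weights: non-adjacent entries stay 0
  n <- st$n
  dense <- array(0, c(n, n, cfg$n_heads))
  for (r in seq_len(nrow(A))) {
    dense[st$edge_index[r, 1], st$edge_index[r, 2], ] <-
      dense[st$edge_index[r, 1], st$edge_index[r, 2], ] + A[r, ]
  }
  adj <- diag(n) > 0
  for (r in seq_len(nrow(g$edge_index))) adj[g$edge_index[r, 1], g$edge_index[r, 2]] <- TRUE
  expect_true(all(dense[!adj] == 0))
})

test_that("the L-layer encoder is permutation equivariant", {
  cfg <- encoder_config(embed_dim = 16, n_heads = 2, n_layers = 3,
                        dropout = 0, ffn_hidden = 32)
  set.seed(9)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  for (g in panel_mols()[c(3, 11, 20)]) {
    n <- nrow(g$atom_features)
    if (n < 2) next
    perm <- sample(n)
    raw <- list(node = g$atom_features, edge = g$edge_features, idx = g$edge_index)
    praw <- list(node = raw$node[order(perm), , drop = FALSE],
                 edge = raw$edge,
                 idx = if (nrow(raw$idx)) matrix(perm[raw$idx], ncol = 2) else raw$idx)
    base <- encode_graph(raw, par, cfg)
    permuted <- encode_graph(praw, par, cfg)
    # node i of the original sits at row perm[i] of the permuted graph
    expect_equal(permuted$node_emb, base$node_emb[order(perm), , drop = FALSE],
                 tolerance = 1e-8)
  }
})

test_that("the encoder composes layers and validates the layer count", {
  cfg <- tiny_cfg()
  set.seed(2)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  g <- panel_mols()[[3]]
  full <- encode_graph(g, par, cfg)
  manual <- project_inputs(g, par, cfg)
  for (l in 1:2) manual <- attention_layer(manual, par$layers[[l]], cfg)
  expect_equal(full$node_emb, manual$node_emb)
  cfg0 <- tiny_cfg(); cfg0$n_layers <- 0L
  expect_error(encode_graph(g, par, cfg0), class = "affipose_invalid_input")
  # 50-node random graph stays finite under default-style init
  set.seed(33)
  nn <- 50
  idx1 <- cbind(1:(nn - 1), 2:nn)
  raw <- list(node = matrix(rnorm(nn * 45, 0, 0.5), nn),
              edge = matrix(rnorm((nn - 1) * 2 * 12, 0, 0.5), 2 * (nn - 1)),
              idx = rbind(idx1, idx1[, 2:1]))
  out <- encode_graph(raw, par, cfg)
  expect_true(all(is.finite(out$node_emb)))
  expect_true(all(is.finite(out$edge_emb)))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- encoder_config(embed_dim = 8, n_heads = 2, n_layers = 2,
                        dropout = 0, ffn_hidden = 16)
  model <- tiny_model(seed = 42, d_emb = 12)
  model$config <- cfg
  set.seed(42)
  model$params <- list(
    mol_enc = init_encoder_params(cfg, mol_node_width(), mol_edge_width()),
    prot_enc = init_encoder_params(cfg, prot_node_width(), prot_edge_width()),
    head = init_head_params(cfg, 12, 12))
  s <- tiny_sample(12)
  loss_fn <- function(params) {
    m2 <- model; m2$params <- params
    fw <- forward_complex(m2, s$mol, s$prot, s$mol_emb, s$prot_emb)
    (fw$affinity - 7)^2 + (fw$rmsd_score - 2)^2
  }
  fw <- forward_complex(model, s$mol, s$prot, s$mol_emb, s$prot_emb,
                        keep_cache = TRUE)
  g <- backward_complex(model, fw, 2 * (fw$affinity - 7),
                        2 * (fw$rmsd_score - 2))
  flat_g <- affipose:::flatten_tree(g)
  flat_p <- affipose:::flatten_tree(model$params)
  bump <- function(p, path, k, delta) {
    key <- path[1]
    if (is.null(names(p)) || !key %in% names(p)) key <- as.integer(key)
    if (length(path) == 1) { p[[key]][k] <- p[[key]][k] + delta; return(p) }
    p[[key]] <- bump(p[[key]], path[-1], k, delta)
    p
  }
  set.seed(9)
  eps <- 1e-6
  for (nm in sample(names(flat_p), 25)) {
    k <- sample(length(flat_p[[nm]]), 1)
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    num <- (loss_fn(bump(model$params, path, k, eps)) -
              loss_fn(bump(model$params, path, k, -eps))) / (2 * eps)
    expect_equal(flat_g[[nm]][k], num, tolerance = 2e-3,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("gradients flow to every shared parameter tensor", {
  cfg <- tiny_cfg()
  set.seed(4)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  g <- panel_mols()[[3]]
  fw <- encode_graph(g, par, cfg, keep_cache = TRUE)
  # scalar loss on pooled node and edge embeddings (edge pooling reaches the
  # last layer's edge-update parameters, which a node-only loss cannot)
  dN <- matrix(1 / length(fw$node_emb), nrow(fw$node_emb), ncol(fw$node_emb))
  dE <- matrix(1 / length(fw$edge_emb), nrow(fw$edge_emb), ncol(fw$edge_emb))
  bk <- affipose:::encode_graph_backward(dN, dE, g, fw, par, cfg)
  flat <- affipose:::flatten_tree(bk$grads)
  for (nm in names(flat)) {
    expect_true(all(is.finite(flat[[nm]])), label = nm)
    expect_gt(max(abs(flat[[nm]])), 0, label = nm)
  }
})

test_that("checkpoints reload bit-exactly with a manifest", {
  cfg <- tiny_cfg()
  set.seed(10)
  par <- init_encoder_params(cfg, 45, 12)
  dir <- tempfile()
  save_checkpoint(par, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  par2 <- load_checkpoint(dir)
  expect_identical(par, par2)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_true("proj.Wn" %in% mf$tensor)
})

test_that("the additive edge-bias variant also satisfies row stochasticity", {
  cfg <- encoder_config(16, 2, 1, dropout = 0, ffn_hidden = 32,
                        edge_bias = "additive")
  set.seed(6)
  par <- init_encoder_params(cfg, mol_node_width(), mol_edge_width())
  st <- project_inputs(panel_mols()[[4]], par, cfg)
  out <- attention_layer(st, par$layers[[1]], cfg, keep_cache = TRUE)
  A <- attr(out, "cache")$A
  expect_true(all(abs(rowsum(A, st$edge_index[, 1]) - 1) < 1e-6))
})
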