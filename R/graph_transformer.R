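#' Edge-aware graph-transformer encoder
#'
#' The encoder stacks `n_layers` identical attention layers. In each layer,
#' per head, queries/keys/values are linear maps of the node embeddings; every
#' directed edge contributes a per-head scalar bias (a linear projection of
#' its edge embedding) that multiplies the scaled dot-product logit before a
#' softmax restricted to graph neighbours plus a self-loop. Node embeddings
#' are updated from the concatenated head outputs, edge embeddings from the
#' concatenated per-head attention weights; both pass through residual
#' connections and a feed-forward block applied to a layer-normalized input.
#'
#' @name graph_transformer
NULL

#' Encoder configuration
#'
#' @param embed_dim Embedding width d (default 128). Must be divisible by
#'   `n_heads`; the per-head width is `embed_dim / n_heads`.
#' @param n_heads Number of attention heads (default 8).
#' @param n_layers Number of stacked layers (default 10).
#' @param dropout Dropout rate on attention weights and feed-forward hidden
#'   activations (default 0.2; active only in training mode).
#' @param ffn_hidden Feed-forward hidden width (default `4 * embed_dim`).
#' @param edge_bias How the per-head edge scalar enters the attention logit:
#'   "multiplicative" (default, as the update rule is printed) or "additive".
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 128L, n_heads = 8L, n_layers = 10L,
                           dropout = 0.2, ffn_hidden = 4L * embed_dim,
                           edge_bias = c("multiplicative", "additive")) {
  if (embed_dim %% n_heads != 0) {
    ap_abort("embed_dim must be divisible by n_heads", "affipose_invalid_input")
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout = dropout,
                 ffn_hidden = as.integer(ffn_hidden),
                 d_head = as.integer(embed_dim / n_heads),
                 edge_bias = match.arg(edge_bias)),
            class = "encoder_config")
}

init_layer_params <- function(cfg) {
  d <- cfg$embed_dim; H <- cfg$n_heads; f <- cfg$ffn_hidden
  list(Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
       Wb = init_mat(d, H),
       Wo = init_mat(d, d),
       We_out = init_mat(H, d),
       ln_n_g = rep(1, d), ln_n_b = rep(0, d),
       ln_e_g = rep(1, d), ln_e_b = rep(0, d),
       ffn_n_W1 = init_mat(d, f), ffn_n_b1 = rep(0, f),
       ffn_n_W2 = init_mat(f, d), ffn_n_b2 = rep(0, d),
       ffn_e_W1 = init_mat(d, f), ffn_e_b1 = rep(0, f),
       ffn_e_W2 = init_mat(f, d), ffn_e_b2 = rep(0, d))
}

#' Initialize encoder parameters (fan-in uniform)
#'
#' @param cfg An [encoder_config()].
#' @param d_node_in,d_edge_in Raw feature widths (45/12 for molecules,
#'   31/6 for proteins).
#' @return Parameter tree (named nested list of matrices/vectors).
#' @export
init_encoder_params <- function(cfg, d_node_in, d_edge_in) {
  d <- cfg$embed_dim
  list(proj = list(Wn = init_mat(d_node_in, d), bn = rep(0, d),
                   We = init_mat(d_edge_in, d), be = rep(0, d),
                   e_self = init_vec(d, d_edge_in)),
       layers = lapply(seq_len(cfg$n_layers), function(l) init_layer_params(cfg)))
}

graph_raw_features <- function(graph) {
  if (inherits(graph, "mol_graph")) {
    list(node = graph$atom_features, edge = graph$edge_features,
         idx = graph$edge_index)
  } else if (inherits(graph, "prot_graph")) {
    list(node = graph$residue_features, edge = graph$edge_features,
         idx = graph$edge_index)
  } else if (is.list(graph) && !is.null(graph$node)) {
    graph
  } else {
    ap_abort("expected a mol_graph, prot_graph or raw feature list",
             "affipose_invalid_input")
  }
}

#' Project raw graph features into the embedding space
#'
#' Linear lift of the raw featurizer outputs into d-dimensional node and edge
#' embeddings. A self-loop is appended for every node; its edge embedding is
#' the learned `e_self` vector, after which self-loop edges update through the
#' layers exactly like bond/contact edges.
#'
#' @param graph A `mol_graph`, `prot_graph`, or raw list with `node`, `edge`,
#'   `idx` fields.
#' @param params Encoder parameter tree from [init_encoder_params()].
#' @param cfg An [encoder_config()].
#' @return A `graph_state`: `node_emb` \[n x d\], `edge_emb` \[m_aug x d\],
#'   `edge_index` (augmented, self-loops last), `is_self` flag vector.
#' @export
project_inputs <- function(graph, params, cfg) {
  raw <- graph_raw_features(graph)
  if (ncol(raw$node) != nrow(params$proj$Wn)) {
    ap_abort(sprintf("node feature width %d does not match projection (%d)",
                     ncol(raw$node), nrow(params$proj$Wn)),
             "affipose_dimension_error")
  }
  n <- nrow(raw$node)
  m_real <- nrow(raw$idx)
  if (m_real > 0 && ncol(raw$edge) != nrow(params$proj$We)) {
    ap_abort(sprintf("edge feature width %d does not match projection (%d)",
                     ncol(raw$edge), nrow(params$proj$We)),
             "affipose_dimension_error")
  }
  node_emb <- add_rowvec(raw$node %*% params$proj$Wn, params$proj$bn)
  edge_real <- if (m_real > 0) {
    add_rowvec(raw$edge %*% params$proj$We, params$proj$be)
  } else matrix(numeric(), 0, cfg$embed_dim)
  self_rows <- matrix(params$proj$e_self, n, cfg$embed_dim, byrow = TRUE)
  aug_idx <- rbind(raw$idx, cbind(seq_len(n), seq_len(n)))
  structure(list(node_emb = node_emb,
                 edge_emb = rbind(edge_real, self_rows),
                 edge_index = aug_idx,
                 is_self = c(rep(FALSE, m_real), rep(TRUE, n)),
                 n = n,
                 grp_split = split(seq_len(nrow(aug_idx)),
                                   factor(aug_idx[, 1], levels = seq_len(n)))),
            class = "graph_state")
}

project_inputs_backward <- function(dstate, graph, params) {
  raw <- graph_raw_features(graph)
  n <- nrow(raw$node)
  m_real <- nrow(raw$idx)
  dE <- dstate$edge_emb
  g <- list(Wn = crossprod(raw$node, dstate$node_emb),
            bn = colSums(dstate$node_emb),
            We = if (m_real > 0) crossprod(raw$edge, dE[seq_len(m_real), , drop = FALSE])
                 else matrix(0, nrow(params$proj$We), ncol(params$proj$We)),
            be = if (m_real > 0) colSums(dE[seq_len(m_real), , drop = FALSE])
                 else rep(0, length(params$proj$be)),
            e_self = colSums(dE[m_real + seq_len(n), , drop = FALSE]))
  g
}

dropout_mask <- function(nr, nc, p, training) {
  if (!training || p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sig
  list(y = add_rowvec(mul_rowvec(xhat, g), b), xhat = xhat, sig = sig)
}

layernorm_bwd <- function(dy, cache, g) {
  dxhat <- mul_rowvec(dy, g)
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sig
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

ffn_fwd <- function(x, W1, b1, W2, b2, p, training) {
  pre <- add_rowvec(x %*% W1, b1)
  h <- pmax(pre, 0)
  mask <- dropout_mask(nrow(h), ncol(h), p, training)
  hd <- apply_mask(h, mask)
  list(y = add_rowvec(hd %*% W2, b2), pre = pre, hd = hd, mask = mask)
}

ffn_bwd <- function(dy, x, cache, W1, W2) {
  dW2 <- crossprod(cache$hd, dy)
  db2 <- colSums(dy)
  dhd <- tcrossprod(dy, W2)
  dh <- apply_mask(dhd, cache$mask)
  dpre <- dh * (cache$pre > 0)
  dW1 <- crossprod(x, dpre)
  db1 <- colSums(dpre)
  list(dx = tcrossprod(dpre, W1), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# softmax within groups, numerically shifted by the per-group maximum
group_softmax <- function(logits, grp, n, grp_split) {
  gmax <- matrix(0, n, ncol(logits))
  for (h in seq_len(ncol(logits))) {
    lg <- logits[, h]
    gmax[, h] <- vapply(grp_split, function(rr) max(lg[rr]), 0)
  }
  e <- exp(logits - gmax[grp, , drop = FALSE])
  denom <- grp_rowsum(e, grp, n)
  e / denom[grp, , drop = FALSE]
}

row_max <- function(x) {
  out <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) out <- pmax(out, x[, j])
  out
}

#' One edge-aware multi-head attention layer
#'
#' @param state A `graph_state` from [project_inputs()] (or a previous layer).
#' @param lpar Layer parameter list (one entry of `params$layers`).
#' @param cfg An [encoder_config()].
#' @param training Logical; enables dropout.
#' @param keep_cache Logical; retain intermediates for backpropagation.
#' @return Updated `graph_state` (with `cache` attribute when requested).
#' @export
attention_layer <- function(state, lpar, cfg, training = FALSE, keep_cache = FALSE) {
  N <- state$node_emb; E <- state$edge_emb
  idx <- state$edge_index
  i_idx <- idx[, 1]; j_idx <- idx[, 2]
  n <- state$n; d <- cfg$embed_dim; H <- cfg$n_heads; dk <- cfg$d_head
  Q <- N %*% lpar$Wq; K <- N %*% lpar$Wk; V <- N %*% lpar$Wv
  S <- E %*% lpar$Wb                                   # per-head edge bias
  hmap <- rep(seq_len(H), each = dk)                   # feature col -> head
  prod_qk <- Q[i_idx, , drop = FALSE] * K[j_idx, , drop = FALSE]
  qk <- t(rowsum(t(prod_qk), hmap))                    # [m x H] per-head dots
  logits <- if (identical(cfg$edge_bias, "additive")) qk / sqrt(dk) + S
            else qk / sqrt(dk) * S
  A <- group_softmax(logits, i_idx, n, state$grp_split)
  amask <- dropout_mask(nrow(A), ncol(A), cfg$dropout, training)
  Ad <- apply_mask(A, amask)
  Adx <- Ad[, hmap, drop = FALSE]                      # head weight per column
  O <- grp_rowsum(Adx * V[j_idx, , drop = FALSE], i_idx, n)
  node_mh <- O %*% lpar$Wo
  edge_mh <- Ad %*% lpar$We_out
  N1 <- N + node_mh
  E1 <- E + edge_mh
  ln_n <- layernorm_fwd(N1, lpar$ln_n_g, lpar$ln_n_b)
  fn <- ffn_fwd(ln_n$y, lpar$ffn_n_W1, lpar$ffn_n_b1, lpar$ffn_n_W2,
                lpar$ffn_n_b2, cfg$dropout, training)
  N2 <- N1 + fn$y
  ln_e <- layernorm_fwd(E1, lpar$ln_e_g, lpar$ln_e_b)
  fe <- ffn_fwd(ln_e$y, lpar$ffn_e_W1, lpar$ffn_e_b1, lpar$ffn_e_W2,
                lpar$ffn_e_b2, cfg$dropout, training)
  E2 <- E1 + fe$y
  for (nm in c("N2", "E2")) {
    if (!all(is.finite(get(nm)))) {
      ap_abort(sprintf("non-finite values in attention layer tensor '%s'",
                       if (nm == "N2") "node_emb" else "edge_emb"),
               "affipose_numeric_failure", tensor = nm)
    }
  }
  out <- structure(list(node_emb = N2, edge_emb = E2, edge_index = idx,
                        is_self = state$is_self, n = n,
                        grp_split = state$grp_split),
                   class = "graph_state")
  if (keep_cache) {
    attr(out, "cache") <- list(N = N, E = E, Q = Q, K = K, V = V, S = S,
                               qk = qk, A = A, Ad = Ad, Adx = Adx,
                               amask = amask, O = O, N1 = N1, E1 = E1,
                               ln_n = ln_n, fn = fn, ln_e = ln_e, fe = fe,
                               attn = A)
  }
  out
}

attention_layer_backward <- function(dN2, dE2, state_in, cache, lpar, cfg) {
  idx <- state_in$edge_index
  i_idx <- idx[, 1]; j_idx <- idx[, 2]
  n <- state_in$n; d <- cfg$embed_dim; H <- cfg$n_heads; dk <- cfg$d_head
  g <- list()
  # node FFN branch
  fb <- ffn_bwd(dN2, cache$ln_n$y, cache$fn, lpar$ffn_n_W1, lpar$ffn_n_W2)
  g$ffn_n_W1 <- fb$dW1; g$ffn_n_b1 <- fb$db1
  g$ffn_n_W2 <- fb$dW2; g$ffn_n_b2 <- fb$db2
  lb <- layernorm_bwd(fb$dx, cache$ln_n, lpar$ln_n_g)
  g$ln_n_g <- lb$dg; g$ln_n_b <- lb$db
  dN1 <- dN2 + lb$dx
  # edge FFN branch
  fbe <- ffn_bwd(dE2, cache$ln_e$y, cache$fe, lpar$ffn_e_W1, lpar$ffn_e_W2)
  g$ffn_e_W1 <- fbe$dW1; g$ffn_e_b1 <- fbe$db1
  g$ffn_e_W2 <- fbe$dW2; g$ffn_e_b2 <- fbe$db2
  lbe <- layernorm_bwd(fbe$dx, cache$ln_e, lpar$ln_e_g)
  g$ln_e_g <- lbe$dg; g$ln_e_b <- lbe$db
  dE1 <- dE2 + lbe$dx
  # residuals
  dN <- dN1
  dE <- dE1
  # multi-head node path
  dO <- tcrossprod(dN1, lpar$Wo)
  g$Wo <- crossprod(cache$O, dN1)
  # edge update path
  dAd <- tcrossprod(dE1, lpar$We_out)
  g$We_out <- crossprod(cache$Ad, dE1)
  hmap <- rep(seq_len(H), each = dk)
  dO_i <- dO[i_idx, , drop = FALSE]
  dAd <- dAd + t(rowsum(t(dO_i * cache$V[j_idx, , drop = FALSE]), hmap))
  dV <- grp_rowsum(cache$Adx * dO_i, j_idx, n)
  dA <- apply_mask(dAd, cache$amask)
  # group softmax backward
  tmp <- cache$A * dA
  ssum <- grp_rowsum(tmp, i_idx, n)
  dlogits <- cache$A * (dA - ssum[i_idx, , drop = FALSE])
  if (identical(cfg$edge_bias, "additive")) {
    dqk <- dlogits / sqrt(dk)
    dS <- dlogits
  } else {
    dqk <- dlogits * cache$S / sqrt(dk)
    dS <- dlogits * cache$qk / sqrt(dk)
  }
  dE <- dE + tcrossprod(dS, lpar$Wb)
  g$Wb <- crossprod(cache$E, dS)
  dqkx <- dqk[, hmap, drop = FALSE]
  dQ <- grp_rowsum(dqkx * cache$K[j_idx, , drop = FALSE], i_idx, n)
  dK <- grp_rowsum(dqkx * cache$Q[i_idx, , drop = FALSE], j_idx, n)
  dN <- dN + tcrossprod(dQ, lpar$Wq) + tcrossprod(dK, lpar$Wk) +
    tcrossprod(dV, lpar$Wv)
  g$Wq <- crossprod(cache$N, dQ)
  g$Wk <- crossprod(cache$N, dK)
  g$Wv <- crossprod(cache$N, dV)
  list(dN = dN, dE = dE, grads = g)
}

#' Run the full L-layer encoder on a graph
#'
#' @inheritParams project_inputs
#' @param training Logical; enables dropout.
#' @param keep_cache Logical; retain every layer's intermediates (needed for
#'   backpropagation).
#' @return Final `graph_state`; with `keep_cache`, attribute `caches` holds
#'   the per-layer caches and `states` the per-layer inputs.
#' @export
encode_graph <- function(graph, params, cfg, training = FALSE, keep_cache = FALSE) {
  if (cfg$n_layers < 1) {
    ap_abort("encoder needs n_layers >= 1", "affipose_invalid_input")
  }
  state <- project_inputs(graph, params, cfg)
  states <- list(state)
  caches <- list()
  for (l in seq_len(cfg$n_layers)) {
    state <- attention_layer(state, params$layers[[l]], cfg,
                             training = training, keep_cache = keep_cache)
    if (keep_cache) {
      caches[[l]] <- attr(state, "cache")
      attr(state, "cache") <- NULL
      states[[l + 1]] <- state
    }
  }
  if (keep_cache) {
    attr(state, "caches") <- caches
    attr(state, "states") <- states
  }
  state
}

encode_graph_backward <- function(dN_final, dE_final, graph, fw_state, params, cfg) {
  caches <- attr(fw_state, "caches")
  states <- attr(fw_state, "states")
  L <- cfg$n_layers
  layer_grads <- vector("list", L)
  dN <- dN_final; dE <- dE_final
  if (is.null(dE)) dE <- matrix(0, nrow(fw_state$edge_emb), ncol(fw_state$edge_emb))
  for (l in rev(seq_len(L))) {
    bk <- attention_layer_backward(dN, dE, states[[l]], caches[[l]],
                                   params$layers[[l]], cfg)
    dN <- bk$dN; dE <- bk$dE
    layer_grads[[l]] <- bk$grads
  }
  dstate0 <- list(node_emb = dN, edge_emb = dE)
  proj_grads <- project_inputs_backward(dstate0, graph, params)
  list(grads = list(proj = proj_grads, layers = layer_grads))
}

# ---- checkpoint serialization ---------------------------------------------

#' Save / load a parameter checkpoint
#'
#' The checkpoint is a flat named-tensor archive (RDS, bit-exact round trip)
#' plus a JSON manifest listing tensor names and shapes.
#'
#' @param params Parameter tree (or full model, see [save_model()]).
#' @param path Directory to write `tensors.rds` and `manifest.json` into.
#' @export
save_checkpoint <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  flat <- flatten_tree(params)
  manifest <- lapply(names(flat), function(nm) {
    list(tensor = nm, shape = if (is.matrix(flat[[nm]])) dim(flat[[nm]])
         else length(flat[[nm]]))
  })
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  saveRDS(params, file.path(path, "tensors.rds"), version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  f <- file.path(path, "tensors.rds")
  if (!file.exists(f)) ap_abort(sprintf("no checkpoint at %s", path),
                                "affipose_invalid_input")
  readRDS(f)
}
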