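#' Cross-attention fusion and the multi-task prediction head
#'
#' Pretrained per-atom / per-residue embeddings query the graph-encoder
#' outputs through standard multi-head cross-attention (queries from the
#' embedding, keys and values from the encoder; residual from the projected
#' queries). The fused molecule rows M and protein rows P feed a sigmoid
#' pairwise gate A\[i, j\], a tanh pairwise interaction feature
#' J\[i, j\] = tanh(M_i * P_j) (elementwise product, a d-vector), and a single
#' shared latent X = sum over all atom-residue pairs of A\[i, j\] * J\[i, j\].
#' Two independent 4-layer MLP decoders map X to the binding affinity (linear
#' output) and the pose-RMSD score (softplus output, enforcing the physical
#' RMSD >= 0 range).
#'
#' @name interaction_head
NULL

init_mlp_params <- function(d_in, dims_hidden, d_out = 1L) {
  dims <- c(d_in, dims_hidden, d_out)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = init_mat(dims[l], dims[l + 1]), b = rep(0, dims[l + 1]))
  })
}

init_cross_params <- function(d_q_in, d) {
  list(Wq = init_mat(d_q_in, d), bq = rep(0, d),
       Wk = init_mat(d, d), Wv = init_mat(d, d), Wo = init_mat(d, d))
}

#' Initialize the fusion + decoder parameters
#'
#' @param cfg An [encoder_config()] (supplies d, heads, dropout).
#' @param d_u,d_e Pretrained embedding widths for molecules / proteins.
#' @return Parameter tree with `ca_mol`, `ca_prot`, `gate`, `mlp_aff`,
#'   `mlp_rmsd`.
#' @export
init_head_params <- function(cfg, d_u = 512L, d_e = 512L) {
  d <- cfg$embed_dim
  hidden <- c(d, max(4L, d %/% 2L), max(4L, d %/% 4L))
  list(ca_mol = init_cross_params(d_u, d),
       ca_prot = init_cross_params(d_e, d),
       gate = list(W_MA = init_mat(d, d), W_PA = init_mat(d, d)),
       mlp_aff = init_mlp_params(d, hidden),
       mlp_rmsd = init_mlp_params(d, hidden))
}

#' Cross-attention fusion of pretrained embeddings with encoder outputs
#'
#' @param H Embedding matrix \[n x d_u\], rows aligned 1:1 with encoder rows.
#' @param N_new Encoder node output \[n x d\].
#' @param par Cross-attention parameter list (`Wq`, `bq`, `Wk`, `Wv`, `Wo`).
#' @param cfg An [encoder_config()].
#' @param training Logical; enables attention dropout.
#' @param keep_cache Keep intermediates for backpropagation.
#' @return Fused matrix \[n x d\] (with `cache` attribute when requested).
#' @export
cross_attend <- function(H, N_new, par, cfg, training = FALSE, keep_cache = FALSE) {
  if (nrow(H) != nrow(N_new)) {
    ap_abort(sprintf("embedding rows (%d) do not align with encoder rows (%d)",
                     nrow(H), nrow(N_new)), "affipose_alignment_error")
  }
  d <- cfg$embed_dim; Hh <- cfg$n_heads; dk <- cfg$d_head
  Qp <- add_rowvec(H %*% par$Wq, par$bq)
  K <- N_new %*% par$Wk
  V <- N_new %*% par$Wv
  n <- nrow(H)
  O <- matrix(0, n, d)
  As <- vector("list", Hh); masks <- vector("list", Hh)
  for (h in seq_len(Hh)) {
    hc <- ((h - 1) * dk + 1):(h * dk)
    logits <- tcrossprod(Qp[, hc, drop = FALSE], K[, hc, drop = FALSE]) / sqrt(dk)
    A <- exp(logits - row_max(logits))
    A <- A / rowSums(A)
    mask <- dropout_mask(n, n, cfg$dropout, training)
    Ad <- apply_mask(A, mask)
    O[, hc] <- Ad %*% V[, hc, drop = FALSE]
    As[[h]] <- A; masks[h] <- list(mask)
  }
  Ao <- O %*% par$Wo
  out <- Qp + Ao
  if (keep_cache) {
    attr(out, "cache") <- list(H = H, N_new = N_new, Qp = Qp, K = K, V = V,
                               O = O, As = As, masks = masks)
  }
  out
}

cross_attend_backward <- function(dM, cache, par, cfg) {
  d <- cfg$embed_dim; Hh <- cfg$n_heads; dk <- cfg$d_head
  n <- nrow(dM)
  dQp <- dM                        # residual path
  dO <- tcrossprod(dM, par$Wo)
  gWo <- crossprod(cache$O, dM)
  dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (h in seq_len(Hh)) {
    hc <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$As[[h]]
    Ad <- apply_mask(A, cache$masks[[h]])
    dAd <- tcrossprod(dO[, hc, drop = FALSE], cache$V[, hc, drop = FALSE])
    dV[, hc] <- dV[, hc] + crossprod(Ad, dO[, hc, drop = FALSE])
    dA <- apply_mask(dAd, cache$masks[[h]])
    dlog <- A * (dA - rowSums(A * dA))
    dQp[, hc] <- dQp[, hc] + dlog %*% cache$K[, hc, drop = FALSE] / sqrt(dk)
    dK[, hc] <- dK[, hc] + crossprod(dlog, cache$Qp[, hc, drop = FALSE]) / sqrt(dk)
  }
  list(dH = tcrossprod(dQp, par$Wq),
       dN_new = tcrossprod(dK, par$Wk) + tcrossprod(dV, par$Wv),
       grads = list(Wq = crossprod(cache$H, dQp), bq = colSums(dQp),
                    Wk = crossprod(cache$N_new, dK),
                    Wv = crossprod(cache$N_new, dV),
                    Wo = gWo))
}

#' Pairwise atom-residue gate matrix
#'
#' `gate[i, j] = sigmoid( (W_MA ReLU(M_i)) . (W_PA ReLU(P_j)) )`. The matrix
#' has one row per molecular atom and one column per protein residue and is
#' exported unchanged for interpretability heatmaps.
#'
#' @param M Fused molecule matrix \[n_atoms x d\].
#' @param P Fused protein matrix \[n_res x d\].
#' @param par Gate parameters (`W_MA`, `W_PA`).
#' @param keep_cache Keep intermediates.
#' @return Gate matrix \[n_atoms x n_res\], entries strictly in (0, 1).
#' @export
pairwise_gate <- function(M, P, par, keep_cache = FALSE) {
  RM <- pmax(M, 0); RP <- pmax(P, 0)
  GM <- RM %*% par$W_MA
  GP <- RP %*% par$W_PA
  Z <- tcrossprod(GM, GP)
  A <- 1 / (1 + exp(-Z))
  if (keep_cache) attr(A, "cache") <- list(M = M, P = P, RM = RM, RP = RP,
                                           GM = GM, GP = GP)
  A
}

pairwise_gate_backward <- function(dA, A, cache, par) {
  dZ <- dA * A * (1 - A)
  dGM <- dZ %*% cache$GP
  dGP <- crossprod(dZ, cache$GM)
  dRM <- tcrossprod(dGM, par$W_MA)
  dRP <- tcrossprod(dGP, par$W_PA)
  list(dM = dRM * (cache$M > 0),
       dP = dRP * (cache$P > 0),
       grads = list(W_MA = crossprod(cache$RM, dGM),
                    W_PA = crossprod(cache$RP, dGP)))
}

#' Shared interaction latent
#'
#' `X = sum_i sum_j gate[i, j] * tanh(M_i * P_j)` where the product is
#' elementwise, so X is a single d-vector shared by both task decoders.
#'
#' @param M,P Fused matrices.
#' @param gate Gate matrix from [pairwise_gate()].
#' @param normalize If TRUE, divide by the number of atom-residue pairs
#'   (mean pooling, for size-invariance experiments); default FALSE keeps the
#'   plain double sum of the printed update rule.
#' @return Numeric vector of length d.
#' @export
joint_latent <- function(M, P, gate, normalize = FALSE) {
  d <- ncol(M)
  X <- numeric(d)
  for (i in seq_len(nrow(M))) {
    Ti <- tanh(P * matrix(M[i, ], nrow(P), d, byrow = TRUE))
    X <- X + colSums(gate[i, ] * Ti)
  }
  if (normalize) X <- X / (nrow(M) * nrow(P))
  X
}

joint_latent_backward <- function(dX, M, P, gate) {
  d <- ncol(M)
  dM <- matrix(0, nrow(M), d); dP <- matrix(0, nrow(P), d)
  dgate <- matrix(0, nrow(M), nrow(P))
  for (i in seq_len(nrow(M))) {
    pre <- P * matrix(M[i, ], nrow(P), d, byrow = TRUE)
    Ti <- tanh(pre)
    dgate[i, ] <- Ti %*% dX
    dpre <- (1 - Ti^2) * (gate[i, ] %o% dX)
    dM[i, ] <- colSums(dpre * P)
    dP <- dP + dpre * matrix(M[i, ], nrow(P), d, byrow = TRUE)
  }
  list(dM = dM, dP = dP, dgate = dgate)
}

mlp_fwd <- function(x, layers, keep_cache = FALSE) {
  h <- matrix(x, 1)
  acts <- list(h)
  L <- length(layers)
  for (l in seq_len(L)) {
    h <- sweep(h %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    if (l < L) h <- pmax(h, 0)
    acts[[l + 1]] <- h
  }
  if (keep_cache) list(y = h[1, ], acts = acts) else h[1, ]
}

mlp_bwd <- function(dy, layers, acts) {
  L <- length(layers)
  dh <- matrix(dy, 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) dh <- dh * (acts[[l + 1]] > 0)
    grads[[l]] <- list(W = crossprod(acts[[l]], dh), b = colSums(dh))
    dh <- tcrossprod(dh, layers[[l]]$W)
  }
  list(dx = dh[1, ], grads = grads)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Decode the shared latent into the two task outputs
#'
#' Two independent 4-layer MLPs read the same latent. The affinity output is
#' unbounded; the RMSD score passes through a softplus so it is nonnegative.
#'
#' @param latent d-vector from [joint_latent()].
#' @param par Head parameter tree (uses `mlp_aff`, `mlp_rmsd`).
#' @param keep_cache Keep intermediates.
#' @return List with `affinity` and `rmsd_score` (plus caches if requested).
#' @export
decode <- function(latent, par, keep_cache = FALSE) {
  fa <- mlp_fwd(latent, par$mlp_aff, keep_cache = TRUE)
  fr <- mlp_fwd(latent, par$mlp_rmsd, keep_cache = TRUE)
  pre_r <- fr$y
  out <- list(affinity = fa$y, rmsd_score = softplus(fr$y))
  if (keep_cache) {
    out$cache <- list(aff = fa, rmsd = fr, pre_rmsd = pre_r)
  }
  out
}

decode_backward <- function(d_aff, d_rmsd, par, cache) {
  ga <- mlp_bwd(d_aff, par$mlp_aff, cache$aff$acts)
  dpre <- d_rmsd * stats::plogis(cache$pre_rmsd)   # d softplus = sigmoid
  gr <- mlp_bwd(dpre, par$mlp_rmsd, cache$rmsd$acts)
  list(dx = ga$dx + gr$dx,
       grads = list(mlp_aff = ga$grads, mlp_rmsd = gr$grads))
}

#' Export a gate matrix as a labelled TSV heatmap table
#'
#' Rows are labelled by atom index + element, columns by residue index + name.
#'
#' @param gate Gate matrix.
#' @param mol A `mol_graph`.
#' @param prot A `prot_graph`.
#' @param path Output TSV file.
#' @export
write_gate_tsv <- function(gate, mol, prot, path) {
  rn <- sprintf("%d_%s", seq_len(nrow(gate)) - 1L, mol$atom_symbols)
  cn <- sprintf("%d_%s", seq_len(ncol(gate)) - 1L, prot$residue_names)
  df <- as.data.frame(gate)
  colnames(df) <- cn
  utils::write.table(cbind(atom = rn, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
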