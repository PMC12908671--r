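#' Full model: encoders + fusion + decoders
#'
#' @name model
NULL

#' Initialize a joint affinity/pose model
#'
#' @param cfg An [encoder_config()].
#' @param d_u,d_e Pretrained embedding dimensions.
#' @param seed Integer seed for parameter initialization.
#' @return An `affipose_model` (parameter tree + config).
#' @export
model_init <- function(cfg = encoder_config(), d_u = 512L, d_e = 512L,
                       seed = 1L) {
  set.seed(seed)
  params <- list(mol_enc = init_encoder_params(cfg, mol_node_width(), mol_edge_width()),
                 prot_enc = init_encoder_params(cfg, prot_node_width(), prot_edge_width()),
                 head = init_head_params(cfg, d_u, d_e))
  structure(list(params = params, config = cfg, d_u = d_u, d_e = d_e,
                 seed = seed),
            class = "affipose_model")
}

#' @export
print.affipose_model <- function(x, ...) {
  np <- sum(vapply(flatten_tree(x$params), length, 1L))
  cat(sprintf("<affipose_model d=%d heads=%d layers=%d (%s parameters)>\n",
              x$config$embed_dim, x$config$n_heads, x$config$n_layers,
              format(np, big.mark = ",")))
  invisible(x)
}

head_forward <- function(model, HU, HE, Nm, Np, training = FALSE,
                         keep_cache = FALSE) {
  cfg <- model$config; par <- model$params
  M <- cross_attend(HU, Nm, par$head$ca_mol, cfg, training, keep_cache)
  P <- cross_attend(HE, Np, par$head$ca_prot, cfg, training, keep_cache)
  gate <- pairwise_gate(M, P, par$head$gate, keep_cache)
  X <- joint_latent(M, P, gate)
  dec <- decode(X, par$head, keep_cache)
  out <- list(affinity = dec$affinity, rmsd_score = dec$rmsd_score,
              gate = strip_attr(gate))
  if (keep_cache) {
    out$cache <- list(M = strip_attr(M), P = strip_attr(P),
                      M_cache = attr(M, "cache"), P_cache = attr(P, "cache"),
                      gate = strip_attr(gate), gate_cache = attr(gate, "cache"),
                      X = X, dec = dec$cache)
  }
  out
}

head_backward <- function(model, cc, d_aff, d_rmsd, shared_only = FALSE) {
  cfg <- model$config; par <- model$params
  db <- decode_backward(d_aff, d_rmsd, par$head, cc$dec)
  jl <- joint_latent_backward(db$dx, cc$M, cc$P, cc$gate)
  gb <- pairwise_gate_backward(jl$dgate, cc$gate, cc$gate_cache, par$head$gate)
  cbm <- cross_attend_backward(jl$dM + gb$dM, cc$M_cache, par$head$ca_mol, cfg)
  cbp <- cross_attend_backward(jl$dP + gb$dP, cc$P_cache, par$head$ca_prot, cfg)
  list(dNm = cbm$dN_new, dNp = cbp$dN_new,
       grads = list(ca_mol = cbm$grads, ca_prot = cbp$grads, gate = gb$grads,
                    mlp_aff = if (shared_only)
                      tree_zeros_like(par$head$mlp_aff) else db$grads$mlp_aff,
                    mlp_rmsd = if (shared_only)
                      tree_zeros_like(par$head$mlp_rmsd) else db$grads$mlp_rmsd))
}

#' Forward pass on one molecule-protein complex
#'
#' @param model An `affipose_model`.
#' @param mol A `mol_graph` (pose coordinates).
#' @param prot A `prot_graph`.
#' @param mol_emb,prot_emb Embedding lists from an `embed_provider`
#'   (`per_atom` / `per_residue` row counts must match the graphs).
#' @param training Logical; enables dropout.
#' @param keep_cache Keep every intermediate for backpropagation.
#' @return List with `affinity`, `rmsd_score`, `gate` (and `cache`).
#' @export
forward_complex <- function(model, mol, prot, mol_emb, prot_emb,
                            training = FALSE, keep_cache = FALSE) {
  cfg <- model$config; par <- model$params
  HU <- mol_emb$per_atom
  HE <- prot_emb$per_residue
  n_atoms <- if (inherits(mol, "mol_graph")) nrow(mol$atom_features) else nrow(graph_raw_features(mol)$node)
  n_res <- if (inherits(prot, "prot_graph")) nrow(prot$residue_features) else nrow(graph_raw_features(prot)$node)
  if (nrow(HU) != n_atoms) {
    ap_abort(sprintf("molecule embedding rows (%d) != atom count (%d)",
                     nrow(HU), n_atoms), "affipose_alignment_error")
  }
  if (nrow(HE) != n_res) {
    ap_abort(sprintf("protein embedding rows (%d) != residue count (%d)",
                     nrow(HE), n_res), "affipose_alignment_error")
  }
  enc_m <- encode_graph(mol, par$mol_enc, cfg, training, keep_cache)
  enc_p <- encode_graph(prot, par$prot_enc, cfg, training, keep_cache)
  hf <- head_forward(model, HU, HE, enc_m$node_emb, enc_p$node_emb,
                     training, keep_cache)
  out <- list(affinity = hf$affinity, rmsd_score = hf$rmsd_score,
              gate = hf$gate)
  if (keep_cache) {
    out$cache <- c(hf$cache, list(enc_m = enc_m, enc_p = enc_p,
                                  mol = mol, prot = prot))
  }
  out
}

strip_attr <- function(x) { attributes(x) <- attributes(x)["dim"]; x }

#' Backward pass on one complex
#'
#' @param model An `affipose_model`.
#' @param fw Output of [forward_complex()] with `keep_cache = TRUE`.
#' @param d_aff,d_rmsd Upstream gradients on the two scalar outputs.
#' @param shared_only If TRUE, decoder gradients are omitted (used by the
#'   GradNorm shared-parameter norms).
#' @return Gradient tree congruent with `model$params` (decoder slots zero
#'   when `shared_only`).
#' @export
backward_complex <- function(model, fw, d_aff, d_rmsd, shared_only = FALSE) {
  cfg <- model$config; par <- model$params
  cc <- fw$cache
  hb <- head_backward(model, cc, d_aff, d_rmsd, shared_only)
  em <- encode_graph_backward(hb$dNm, NULL, cc$mol, cc$enc_m, par$mol_enc, cfg)
  ep <- encode_graph_backward(hb$dNp, NULL, cc$prot, cc$enc_p, par$prot_enc, cfg)
  list(mol_enc = em$grads, prot_enc = ep$grads, head = hb$grads)
}

# Block-diagonal concatenation of graphs for one batched encoder pass.
batch_graphs <- function(graphs) {
  raws <- lapply(graphs, graph_raw_features)
  ns <- vapply(raws, function(r) nrow(r$node), 0L)
  offs <- c(0L, cumsum(ns))
  idx <- do.call(rbind, lapply(seq_along(raws), function(k) {
    if (nrow(raws[[k]]$idx) == 0) matrix(integer(), 0, 2)
    else raws[[k]]$idx + offs[k]
  }))
  list(raw = list(node = do.call(rbind, lapply(raws, `[[`, "node")),
                  edge = do.call(rbind, lapply(raws, `[[`, "edge")),
                  idx = idx),
       slices = lapply(seq_along(ns), function(k) (offs[k] + 1L):offs[k + 1L]))
}

#' Predict affinity and RMSD score for a list of prepared samples
#'
#' @param model An `affipose_model`.
#' @param samples List of prepared samples (see [prepare_samples()]).
#' @return data.frame with complex_id, pose_id, affinity_hat, rmsd_hat.
#' @export
predict_samples <- function(model, samples) {
  rows <- lapply(samples, function(s) {
    fw <- forward_complex(model, s$mol, s$prot, s$mol_emb, s$prot_emb,
                          training = FALSE)
    data.frame(complex_id = s$complex_id, pose_id = s$pose_id,
               affinity_hat = fw$affinity, rmsd_hat = fw$rmsd_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attach stub/cached embeddings to complex records
#'
#' Embeddings are computed once per distinct molecule and protein and shared
#' across records.
#'
#' @param records List of `complex_record`s (see [label_pose_set()]).
#' @param provider An `embed_provider`.
#' @return List of samples, each with `mol`, `prot`, `mol_emb`, `prot_emb`,
#'   `affinity`, `rmsd`, `complex_id`, `pose_id`.
#' @export
prepare_samples <- function(records, provider) {
  mol_cache <- new.env(parent = emptyenv())
  prot_cache <- new.env(parent = emptyenv())
  lapply(records, function(r) {
    mk <- paste(r$mol$atom_symbols, collapse = "")
    if (is.null(mol_cache[[mk]])) mol_cache[[mk]] <- provider$embed_molecule(r$mol)
    pk <- r$prot$sequence %||% r$prot$source_id
    if (is.null(prot_cache[[pk]])) prot_cache[[pk]] <- provider$embed_protein(pk)
    list(mol = r$mol, prot = r$prot,
         mol_emb = mol_cache[[mk]], prot_emb = prot_cache[[pk]],
         affinity = r$affinity %||% NA_real_,
         rmsd = r$rmsd_label %||% NA_real_,
         complex_id = r$complex_id, pose_id = r$pose_id)
  })
}

#' Save / load a full model (parameters + configuration)
#'
#' @param model An `affipose_model`.
#' @param path Checkpoint directory.
#' @export
save_model <- function(model, path) {
  save_checkpoint(model$params, path)
  jsonlite::write_json(list(embed_dim = model$config$embed_dim,
                            n_heads = model$config$n_heads,
                            n_layers = model$config$n_layers,
                            dropout = model$config$dropout,
                            ffn_hidden = model$config$ffn_hidden,
                            d_u = model$d_u, d_e = model$d_e,
                            seed = model$seed),
                       file.path(path, "config.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfgj <- jsonlite::read_json(file.path(path, "config.json"), simplifyVector = TRUE)
  cfg <- encoder_config(cfgj$embed_dim, cfgj$n_heads, cfgj$n_layers,
                        cfgj$dropout, cfgj$ffn_hidden)
  structure(list(params = load_checkpoint(path), config = cfg,
                 d_u = cfgj$d_u, d_e = cfgj$d_e, seed = cfgj$seed),
            class = "affipose_model")
}
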