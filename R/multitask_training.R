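#' Multi-task training with GradNorm loss balancing
#'
#' The joint objective is `alpha1 * MSE(affinity) + alpha2 * MSE(rmsd)`, with
#' each MSE taken over the samples carrying that label. Task weights adapt by
#' GradNorm: per-task gradient norms on the shared (latent-producing)
#' parameters are pulled toward `mean(g) * r_k^asymmetry`, where `r_k` is the
#' task's inverse training rate (its loss relative to the initial loss,
#' normalized across tasks); after each update the weights are renormalized to
#' a fixed sum.
#'
#' @name multitask_training
NULL

#' Task weights for the joint loss
#'
#' @param alpha_affinity,alpha_rmsd Positive task weights.
#' @param gradnorm_asymmetry GradNorm asymmetry exponent (default 1.5).
#' @param renorm_sum Weights are renormalized to this sum after every update
#'   (default 2).
#' @param min_weight Lower clamp on each task weight after the update
#'   (default `0.1 * renorm_sum`). Prevents task starvation when one task
#'   carries an irreducible loss floor that GradNorm's inverse-rate term
#'   mistakes for slow progress.
#' @return A `task_weights` list.
#' @export
task_weights <- function(alpha_affinity = 1, alpha_rmsd = 1,
                         gradnorm_asymmetry = 1.5, renorm_sum = 2,
                         min_weight = 0.1 * renorm_sum) {
  if (alpha_affinity <= 0 || alpha_rmsd <= 0) {
    ap_abort("task weights must be positive", "affipose_invalid_input")
  }
  structure(list(alpha_affinity = alpha_affinity, alpha_rmsd = alpha_rmsd,
                 gradnorm_asymmetry = gradnorm_asymmetry,
                 renorm_sum = renorm_sum, min_weight = min_weight),
            class = "task_weights")
}

#' Joint masked MSE loss
#'
#' @param y,yhat Affinity labels and predictions.
#' @param z,zhat RMSD labels and predictions.
#' @param weights A [task_weights()].
#' @param mask_aff,mask_rmsd Logical vectors marking which samples carry each
#'   label; defaults to non-NA labels.
#' @param active Character vector of active tasks (both by default); a batch
#'   with zero unmasked samples for an active task is degenerate.
#' @return List with `total`, `loss_aff`, `loss_rmsd`, `n_aff`, `n_rmsd`.
#' @export
joint_loss <- function(y, yhat, z, zhat, weights = task_weights(),
                       mask_aff = !is.na(y), mask_rmsd = !is.na(z),
                       active = c("affinity", "rmsd")) {
  n_aff <- sum(mask_aff); n_rmsd <- sum(mask_rmsd)
  if (("affinity" %in% active && n_aff == 0) ||
      ("rmsd" %in% active && n_rmsd == 0)) {
    ap_abort("batch has zero labelled samples for an active task",
             "affipose_degenerate_batch")
  }
  loss_aff <- if (n_aff > 0) mean((y[mask_aff] - yhat[mask_aff])^2) else 0
  loss_rmsd <- if (n_rmsd > 0) mean((z[mask_rmsd] - zhat[mask_rmsd])^2) else 0
  a1 <- if ("affinity" %in% active) weights$alpha_affinity else 0
  a2 <- if ("rmsd" %in% active) weights$alpha_rmsd else 0
  list(total = a1 * loss_aff + a2 * loss_rmsd,
       loss_aff = loss_aff, loss_rmsd = loss_rmsd,
       n_aff = n_aff, n_rmsd = n_rmsd)
}

#' One GradNorm task-weight update
#'
#' `grad_norms[k]` must be the norm of the gradient of `alpha_k * L_k` with
#' respect to the shared parameters (so it is linear in `alpha_k`). Targets
#' are `mean(g) * r_k^asymmetry` with `r_k` the normalized inverse training
#' rate; one gradient step is taken on `sum_k |g_k - target_k|` and the
#' weights are renormalized to `renorm_sum`.
#'
#' @param weights A [task_weights()].
#' @param grad_norms Length-2 numeric (affinity, rmsd).
#' @param losses Length-2 current unweighted task losses.
#' @param initial_losses Length-2 task losses recorded at step 0.
#' @param lr_weight Step size on the task weights (default 0.025).
#' @return Updated `task_weights`.
#' @export
gradnorm_step <- function(weights, grad_norms, losses, initial_losses,
                          lr_weight = 0.025) {
  if (!all(is.finite(grad_norms))) {
    ap_abort("non-finite gradient norm in GradNorm update",
             "affipose_numeric_failure", tensor = "grad_norms")
  }
  alphas <- c(weights$alpha_affinity, weights$alpha_rmsd)
  ltilde <- losses / pmax(initial_losses, 1e-12)
  r <- ltilde / mean(ltilde)
  target <- mean(grad_norms) * r^weights$gradnorm_asymmetry
  # d|g_k - t_k|/d alpha_k with g_k linear in alpha_k (targets detached);
  # normalized by the mean norm so the step size is scale-free
  dalpha <- sign(grad_norms - target) * grad_norms / pmax(alphas, 1e-12)
  dalpha <- dalpha / max(mean(grad_norms), 1e-12)
  alphas <- alphas - lr_weight * dalpha
  alphas <- pmax(alphas, 1e-4)
  alphas <- alphas / sum(alphas) * weights$renorm_sum
  # anti-starvation clamp (exact for two tasks)
  lo <- weights$min_weight
  if (alphas[1] < lo) alphas <- c(lo, weights$renorm_sum - lo)
  if (alphas[2] < lo) alphas <- c(weights$renorm_sum - lo, lo)
  task_weights(alphas[1], alphas[2], weights$gradnorm_asymmetry,
               weights$renorm_sum, weights$min_weight)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 50).
#' @param max_epochs Maximum epochs (default 1000).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 30).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param single_task "none", "affinity_only" or "rmsd_only".
#' @param gradnorm_interval Update task weights every this many epochs
#'   (0 disables GradNorm; weights stay fixed).
#' @param lr_weight GradNorm weight step size.
#' @param val_fraction Fraction of the data held out for early stopping
#'   (0 disables).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 50L, max_epochs = 1000L,
                         early_stop_patience = 30L, seed = 1L,
                         single_task = c("none", "affinity_only", "rmsd_only"),
                         gradnorm_interval = 1L, lr_weight = 0.025,
                         val_fraction = 0) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 single_task = match.arg(single_task),
                 gradnorm_interval = as.integer(gradnorm_interval),
                 lr_weight = lr_weight,
                 val_fraction = val_fraction),
            class = "train_config")
}

# Adam on flat tensor lists (names from flatten_tree)
adam_init <- function(flat_params) {
  list(m = lapply(flat_params, function(x) x * 0),
       v = lapply(flat_params, function(x) x * 0), t = 0L)
}

adam_step_flat <- function(flat_params, flat_grads, state, lr, beta1 = 0.9,
                           beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  flat_grads <- flat_grads[names(flat_params)]  # align tensor order by name
  for (k in seq_along(flat_params)) {
    g <- flat_grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    flat_params[[k]] <- flat_params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = flat_params, state = state)
}

batch_grads <- function(model, samples, idx, weights, active,
                        shared_only_task = NULL) {
  # one batched encoder pass (block-diagonal graphs), per-sample heads
  cfg <- model$config; par <- model$params
  ss <- samples[idx]
  nb <- length(ss)
  n_aff <- sum(vapply(ss, function(s) !is.na(s$affinity), TRUE))
  n_rmsd <- sum(vapply(ss, function(s) !is.na(s$rmsd), TRUE))
  bm <- batch_graphs(lapply(ss, `[[`, "mol"))
  bp <- batch_graphs(lapply(ss, `[[`, "prot"))
  enc_m <- encode_graph(bm$raw, par$mol_enc, cfg, training = TRUE, keep_cache = TRUE)
  enc_p <- encode_graph(bp$raw, par$prot_enc, cfg, training = TRUE, keep_cache = TRUE)
  dNm <- matrix(0, nrow(enc_m$node_emb), cfg$embed_dim)
  dNp <- matrix(0, nrow(enc_p$node_emb), cfg$embed_dim)
  head_grads <- NULL
  y <- numeric(nb); yh <- numeric(nb); z <- numeric(nb); zh <- numeric(nb)
  for (k in seq_len(nb)) {
    s <- ss[[k]]
    hf <- head_forward(model, s$mol_emb$per_atom, s$prot_emb$per_residue,
                       enc_m$node_emb[bm$slices[[k]], , drop = FALSE],
                       enc_p$node_emb[bp$slices[[k]], , drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
    has_aff <- !is.na(s$affinity) && "affinity" %in% active
    has_rmsd <- !is.na(s$rmsd) && "rmsd" %in% active
    d_aff <- if (has_aff)
      weights$alpha_affinity * 2 * (hf$affinity - s$affinity) / max(n_aff, 1) else 0
    d_rmsd <- if (has_rmsd)
      weights$alpha_rmsd * 2 * (hf$rmsd_score - s$rmsd) / max(n_rmsd, 1) else 0
    if (!is.null(shared_only_task)) {
      if (shared_only_task == "affinity") d_rmsd <- 0 else d_aff <- 0
    }
    hb <- head_backward(model, hf$cache, d_aff, d_rmsd,
                        shared_only = !is.null(shared_only_task))
    dNm[bm$slices[[k]], ] <- hb$dNm
    dNp[bp$slices[[k]], ] <- hb$dNp
    hg <- flatten_tree(hb$grads, "head")
    if (is.null(head_grads)) head_grads <- hg
    else for (j in seq_along(head_grads)) head_grads[[j]] <- head_grads[[j]] + hg[[j]]
    y[k] <- s$affinity; yh[k] <- hf$affinity
    z[k] <- s$rmsd; zh[k] <- hf$rmsd_score
  }
  em <- encode_graph_backward(dNm, NULL, bm$raw, enc_m, par$mol_enc, cfg)
  ep <- encode_graph_backward(dNp, NULL, bp$raw, enc_p, par$prot_enc, cfg)
  grads <- c(flatten_tree(em$grads, "mol_enc"), flatten_tree(ep$grads, "prot_enc"),
             head_grads)
  list(grads = grads, y = y, yhat = yh, z = z, zhat = zh)
}

shared_sq_norm <- function(flat_grads) {
  # shared parameters: everything up to and including the joint latent
  # (both encoders, both cross-attentions, the gate); decoders are
  # task-specific and excluded
  keep <- !grepl("^head\\.mlp_", names(flat_grads))
  sum(vapply(flat_grads[keep], function(g) sum(g * g), 0))
}

#' Train the joint model
#'
#' Deterministic given `config$seed`: parameter initialization (if `model` is
#' NULL), batch shuffling and dropout all draw from the seeded R RNG. Returns
#' the trained model plus a per-epoch history of both task losses and the
#' task weights. Divergence (non-finite loss) aborts and returns the last
#' finite-loss state with `diverged = TRUE`.
#'
#' @param samples Prepared samples from [prepare_samples()].
#' @param model An `affipose_model`, or NULL to initialize from `config$seed`.
#' @param config A [train_config()].
#' @param weights Initial [task_weights()].
#' @param val_samples Optional validation samples for early stopping.
#' @param verbose Print per-epoch losses.
#' @return List with `model`, `history` (data.frame), `weights`, `diverged`.
#' @export
train <- function(samples, model = NULL, config = train_config(),
                  weights = task_weights(), val_samples = NULL,
                  verbose = FALSE) {
  if (length(samples) == 0) ap_abort("empty dataset", "affipose_invalid_input")
  set.seed(config$seed)
  if (is.null(model)) {
    cfg <- encoder_config()
    model <- model_init(cfg, ncol(samples[[1]]$mol_emb$per_atom),
                        ncol(samples[[1]]$prot_emb$per_residue),
                        seed = config$seed)
    set.seed(config$seed + 1L)
  }
  active <- switch(config$single_task,
                   none = c("affinity", "rmsd"),
                   affinity_only = "affinity",
                   rmsd_only = "rmsd")
  # a task with no labels anywhere in the dataset is inactive, so joint
  # training on affinity-only data reduces exactly to single-task training
  have_aff <- any(vapply(samples, function(s) !is.na(s$affinity), TRUE))
  have_rmsd <- any(vapply(samples, function(s) !is.na(s$rmsd), TRUE))
  active <- intersect(active, c("affinity", "rmsd")[c(have_aff, have_rmsd)])
  if (length(active) == 0) {
    ap_abort("no labelled samples for any active task", "affipose_degenerate_batch")
  }
  if (config$single_task == "affinity_only") weights$alpha_rmsd <- 0
  if (config$single_task == "rmsd_only") weights$alpha_affinity <- 0
  skeleton <- model$params
  flat_par <- flatten_tree(model$params)
  opt <- adam_init(flat_par)
  n <- length(samples)
  history <- list()
  # epoch-0 baseline: training loss under the initial parameters (eval mode)
  p0 <- predict_samples(model, samples)
  y0 <- vapply(samples, function(s) s$affinity, 0)
  z0 <- vapply(samples, function(s) s$rmsd, 0)
  l0 <- joint_loss(y0, p0$affinity_hat, z0, p0$rmsd_hat, weights, active = active)
  history[[1]] <- data.frame(epoch = 0, loss_total = l0$total,
                             loss_aff = l0$loss_aff, loss_rmsd = l0$loss_rmsd,
                             alpha_affinity = weights$alpha_affinity,
                             alpha_rmsd = weights$alpha_rmsd,
                             val_total = NA_real_)
  initial_losses <- NULL
  best_val <- Inf; best_params <- model$params; patience_left <- config$early_stop_patience
  last_good <- model$params
  diverged <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_aff <- 0; ep_rmsd <- 0; ep_naff <- 0; ep_nrmsd <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      bg <- batch_grads(model, samples, idx, weights, active)
      ls <- joint_loss(bg$y, bg$yhat, bg$z, bg$zhat, weights,
                       active = active)
      if (!is.finite(ls$total)) { diverged <- TRUE; break }
      last_good <- model$params
      # GradNorm on the first batch of scheduled epochs (both tasks active)
      if (length(active) == 2 && config$gradnorm_interval > 0 && bi == 1 &&
          (epoch - 1) %% config$gradnorm_interval == 0) {
        if (is.null(initial_losses)) {
          initial_losses <- c(ls$loss_aff, ls$loss_rmsd)
        }
        ga <- batch_grads(model, samples, idx, weights, active,
                          shared_only_task = "affinity")
        gr <- batch_grads(model, samples, idx, weights, active,
                          shared_only_task = "rmsd")
        gn <- sqrt(c(shared_sq_norm(ga$grads), shared_sq_norm(gr$grads)))
        weights <- gradnorm_step(weights, gn, c(ls$loss_aff, ls$loss_rmsd),
                                 initial_losses, config$lr_weight)
      }
      st <- adam_step_flat(flat_par, bg$grads, opt, config$lr)
      flat_par <- st$params
      opt <- st$state
      model$params <- unflatten_tree(flat_par, skeleton)
      ep_aff <- ep_aff + ls$loss_aff * ls$n_aff
      ep_rmsd <- ep_rmsd + ls$loss_rmsd * ls$n_rmsd
      ep_naff <- ep_naff + ls$n_aff
      ep_nrmsd <- ep_nrmsd + ls$n_rmsd
    }
    if (diverged) { model$params <- last_good; break }
    mean_aff <- if (ep_naff > 0) ep_aff / ep_naff else NA_real_
    mean_rmsd <- if (ep_nrmsd > 0) ep_rmsd / ep_nrmsd else NA_real_
    total <- sum(c(weights$alpha_affinity * mean_aff,
                   weights$alpha_rmsd * mean_rmsd), na.rm = TRUE)
    val_total <- NA_real_
    if (!is.null(val_samples)) {
      pv <- predict_samples(model, val_samples)
      vy <- vapply(val_samples, function(s) s$affinity, 0)
      vz <- vapply(val_samples, function(s) s$rmsd, 0)
      vl <- joint_loss(vy, pv$affinity_hat, vz, pv$rmsd_hat, weights,
                       active = active)
      val_total <- vl$total
      if (val_total < best_val - 1e-9) {
        best_val <- val_total; best_params <- model$params
        patience_left <- config$early_stop_patience
      } else {
        patience_left <- patience_left - 1L
      }
    }
    history[[epoch + 1]] <- data.frame(epoch = epoch,
                                   loss_total = total,
                                   loss_aff = mean_aff,
                                   loss_rmsd = mean_rmsd,
                                   alpha_affinity = weights$alpha_affinity,
                                   alpha_rmsd = weights$alpha_rmsd,
                                   val_total = val_total)
    if (verbose) {
      message(sprintf("epoch %3d total %.4f aff %.4f rmsd %.4f (a1 %.3f a2 %.3f)",
                      epoch, total, mean_aff, mean_rmsd,
                      weights$alpha_affinity, weights$alpha_rmsd))
    }
    if (!is.null(val_samples) && patience_left <= 0) {
      model$params <- best_params
      break
    }
  }
  list(model = model, history = do.call(rbind, history), weights = weights,
       diverged = diverged)
}
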