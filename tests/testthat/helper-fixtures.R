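# Shared fixtures, built once per test session.

.helper_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.helper_cache[[key]])) .helper_cache[[key]] <- force(expr)
  .helper_cache[[key]]
}

panel_mols <- function() memo("panel", make_toy_molecules(seed = 1))

helix8 <- function() memo("helix8", make_toy_protein(8, seed = 3, include_metal = FALSE))

helix_metal <- function() memo("helix_metal",
                               make_toy_protein(10, seed = 4, include_metal = TRUE))

tiny_cfg <- function(dropout = 0) {
  encoder_config(embed_dim = 16L, n_heads = 2L, n_layers = 2L,
                 dropout = dropout, ffn_hidden = 32L)
}

tiny_model <- function(seed = 42, d_emb = 12L, dropout = 0) {
  model_init(tiny_cfg(dropout), d_u = d_emb, d_e = d_emb, seed = seed)
}

# a small prepared sample (phenol vs 5-residue helix) for model-level tests
tiny_sample <- function(d_emb = 12L) {
  memo(paste0("sample", d_emb), {
    mol <- mol_graph_from_structure("Oc1ccccc1", source_id = "phenol")
    tp <- make_toy_protein(5, seed = 2, include_metal = FALSE)
    prov <- stub_provider(d_emb, d_emb, seed = 3)
    list(mol = mol, prot = tp$graph,
         mol_emb = prov$embed_molecule(mol),
         prot_emb = prov$embed_protein(tp$graph$sequence))
  })
}

# brute-force contact oracle: all atom pairs, strict cutoff
oracle_contact_pairs <- function(residues, cutoff = 10) {
  n <- length(residues)
  out <- matrix(integer(), 0, 2)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    mind <- Inf
    a <- residues[[i]]$coords; b <- residues[[j]]$coords
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      mind <- min(mind, sqrt(sum((a[p, ] - b[q, ])^2)))
    }
    if (mind < cutoff) out <- rbind(out, c(i, j), c(j, i))
  }
  out
}

sort_edges <- function(e) {
  if (nrow(e) == 0) return(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# random small protein-like residue set with scattered coordinates
random_residues <- function(n, seed, spread = 14) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- runif(3, 0, spread)
    k <- sample(2:4, 1)
    list(name = "ALA", atom_names = c("N", "CA", "C", "O")[seq_len(k)],
         coords = matrix(rep(base, each = k) + rnorm(k * 3, 0, 1.2), k, 3),
         is_metal = FALSE)
  })
}
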