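#' Pretrained-embedding provider contract
#'
#' Downstream fusion consumes per-atom molecule embeddings and per-residue
#' protein embeddings through a uniform provider interface, so that a
#' deterministic stub (no downloads, platform-reproducible) and cached
#' precomputed archives are interchangeable with real language-model adapters.
#' A provider is a list with fields `name`, `d_mol`, `d_prot`,
#' `embed_molecule(mol_graph)` and `embed_protein(seq)`.
#'
#' @name embed_providers
NULL

# ---- 32-bit integer hash PRNG (documented, platform-independent) -----------
# All arithmetic on doubles holding unsigned 32-bit values; multiplication is
# carried out in 16-bit limbs so every intermediate stays below 2^53.

u32_mul <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  lo <- a_lo * b_lo
  mid <- (a_lo * b_hi + a_hi * b_lo) %% 65536
  (lo + mid * 65536) %% 4294967296
}

u32_xor <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_lo), as.integer(b_lo)) +
    65536 * bitwXor(as.integer(a_hi), as.integer(b_hi))
}

u32_shr <- function(a, n) floor(a / 2^n)

# murmur3-style finalizer: avalanching mix of one 32-bit word
mix32 <- function(h) {
  h <- u32_xor(h, u32_shr(h, 16))
  h <- u32_mul(h, 2246822507)  # 0x85ebca6b
  h <- u32_xor(h, u32_shr(h, 13))
  h <- u32_mul(h, 3266489909)  # 0xc2b2ae35
  u32_xor(h, u32_shr(h, 16))
}

hash_token <- function(token) {
  h <- 2166136261  # FNV offset basis
  for (code in utf8ToInt(as.character(token))) {
    h <- u32_xor(h, code %% 4294967296)
    h <- u32_mul(h, 16777619)
  }
  h
}

hash_key <- function(token_code, position, seed, k) {
  h <- mix32((token_code + u32_mul(position %% 4294967296, 2654435761)) %% 4294967296)
  h <- mix32(u32_xor(h, u32_mul(seed %% 4294967296, 40503)))
  mix32((h + u32_mul(k, 2654435789)) %% 4294967296)
}

#' Deterministic stub embedding matrix
#'
#' Each row is a pseudo-random unit-norm vector keyed by
#' `(token, position, seed)` through a documented 32-bit integer-hash PRNG
#' (FNV-1a token folding + murmur-style avalanche, Box-Muller normals), so the
#' same key reproduces the same row on every platform and R session.
#'
#' @param tokens Character vector (atom symbols, residue letters, ...).
#' @param d Embedding dimension (>= 1).
#' @param seed Integer seed.
#' @return Matrix \[length(tokens) x d\] with unit-norm rows.
#' @export
stub_embedding <- function(tokens, d, seed = 1L) {
  if (d < 1) ap_abort("embedding dimension must be >= 1", "affipose_invalid_input")
  out <- matrix(0, length(tokens), d)
  for (i in seq_along(tokens)) {
    tc <- hash_token(tokens[i])
    z <- numeric(d)
    for (k in seq_len(d)) {
      u1 <- (hash_key(tc, i, seed, 2 * k - 1) + 0.5) / 4294967296
      u2 <- (hash_key(tc, i, seed, 2 * k) + 0.5) / 4294967296
      z[k] <- sqrt(-2 * log(u1)) * cos(2 * pi * u2)
    }
    out[i, ] <- z / vec_norm(z)
  }
  out
}

new_embed_provider <- function(name, d_mol, d_prot, embed_molecule, embed_protein) {
  structure(list(name = name, d_mol = d_mol, d_prot = d_prot,
                 embed_molecule = embed_molecule,
                 embed_protein = embed_protein),
            class = "embed_provider")
}

#' Deterministic stub provider
#'
#' Molecule rows are keyed by atom element symbols and positions; protein rows
#' by residue letters and positions. Pooled vectors are the row means. Default
#' dimension 512 matches the molecule-level output size of the pretrained
#' models the contract emulates.
#'
#' @param d_mol,d_prot Embedding dimensions.
#' @param seed Integer seed.
#' @return An `embed_provider`.
#' @export
stub_provider <- function(d_mol = 512L, d_prot = 512L, seed = 1L) {
  new_embed_provider(
    name = "stub",
    d_mol = d_mol, d_prot = d_prot,
    embed_molecule = function(mol) {
      per_atom <- stub_embedding(mol$atom_symbols, d_mol, seed)
      list(per_atom = per_atom, pooled = colMeans(per_atom))
    },
    embed_protein = function(seq) {
      tokens <- strsplit(seq, "")[[1]]
      per_residue <- stub_embedding(tokens, d_prot, seed)
      list(per_residue = per_residue, pooled = colMeans(per_residue))
    })
}

#' Save / load an embedding archive
#'
#' One archive per entity id: the matrix (RDS, bit-exact) plus a JSON sidecar
#' recording provider name, dimension and an md5 of the input key.
#'
#' @param emb Embedding list (`per_atom` or `per_residue` + `pooled`).
#' @param dir Cache directory.
#' @param id Entity identifier.
#' @param provider_name Recorded provenance string.
#' @param input_key String the sidecar hash is computed from.
#' @export
save_embedding <- function(emb, dir, id, provider_name = "stub", input_key = id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- emb$per_atom %||% emb$per_residue
  saveRDS(emb, file.path(dir, paste0(id, ".rds")), version = 2)
  tf <- tempfile(); writeLines(input_key, tf)
  jsonlite::write_json(list(provider = provider_name,
                            dim = ncol(mat),
                            rows = nrow(mat),
                            input_md5 = unname(tools::md5sum(tf))),
                       file.path(dir, paste0(id, ".json")), auto_unbox = TRUE)
  invisible(file.path(dir, paste0(id, ".rds")))
}

#' @rdname save_embedding
#' @export
load_embedding <- function(dir, id) {
  f <- file.path(dir, paste0(id, ".rds"))
  if (!file.exists(f)) {
    ap_abort(sprintf("no cached embedding for id '%s' in %s", id, dir),
             "affipose_provider_unavailable")
  }
  readRDS(f)
}

#' Cached-file provider reading precomputed embedding archives
#'
#' Molecule lookups use the graph `source_id`; protein lookups use the raw
#' sequence string as id. Swapping this for the stub changes no shapes or
#' downstream code paths.
#'
#' @param dir Cache directory written by [save_embedding()].
#' @param d_mol,d_prot Expected dimensions (checked on load).
#' @return An `embed_provider`.
#' @export
cached_provider <- function(dir, d_mol = 512L, d_prot = 512L) {
  new_embed_provider(
    name = "cached",
    d_mol = d_mol, d_prot = d_prot,
    embed_molecule = function(mol) load_embedding(dir, mol$source_id),
    embed_protein = function(seq) load_embedding(dir, seq))
}
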