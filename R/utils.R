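# Internal helpers shared across modules.

# Single package-wide divisor for all distance-valued features (Å -> ~[-2,2]).
DISTANCE_SCALE <- 10.0

ap_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "affipose_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ap_assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    ap_abort(sprintf("non-finite values in %s", what), "affipose_numeric_failure",
             tensor = what)
  }
  invisible(x)
}

one_hot <- function(value, levels, other = NULL) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  if (is.na(idx)) {
    if (is.null(other)) {
      ap_abort(sprintf("value '%s' not in {%s}", value,
                       paste(levels, collapse = ", ")),
               "affipose_invalid_input")
    }
    idx <- match(other, levels)
  }
  v[idx] <- 1
  v
}

decode_one_hot <- function(block, levels) {
  hot <- which(block == 1)
  if (length(hot) != 1L || !all(block[-hot] == 0)) {
    return(list(label = NA_character_, ok = FALSE))
  }
  list(label = levels[hot], ok = TRUE)
}

# Euclidean distance between two 3-vectors / rowwise matrices
vec_norm <- function(x) sqrt(sum(x^2))

pairwise_min_max_dist <- function(a, b) {
  # a [na x 3], b [nb x 3]; returns min and max inter-point distance
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  list(min = sqrt(min(d2)), max = sqrt(max(d2)))
}

# Dihedral angle (radians, in (-pi, pi]) of four points, atan2 formulation.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- vec_norm(b2)
  if (b2n < 1e-12 || vec_norm(n1) < 1e-12 || vec_norm(n2) < 1e-12) return(NA_real_)
  atan2(-sum(m1 * n2) / b2n, sum(n1 * n2))
}

# Sum rows of x into n groups given by grp (1..n); returns [n x ncol(x)].
grp_rowsum <- function(x, grp, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Recursive combine of two congruent parameter trees
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    nms <- names(a)
    names(out) <- nms
    by_name <- !is.null(nms) && !is.null(names(b)) && all(nzchar(nms))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[nms[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else f(a)
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)
tree_add <- function(a, b) tree_map2(`+`, a, b)

# Flatten a parameter tree to a named list of numeric arrays ("a.b.c" names)
flatten_tree <- function(a, prefix = NULL) {
  vals <- vector("list", 512L)
  keys <- character(512L)
  i <- 0L
  walk <- function(x, pre) {
    if (!is.list(x)) {
      i <<- i + 1L
      if (i > length(vals)) {
        length(vals) <<- 2L * length(vals)
        length(keys) <<- 2L * length(keys)
      }
      vals[[i]] <<- x
      keys[i] <<- pre
      return(invisible())
    }
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (k in seq_along(x)) {
      nm <- if (nzchar(nms[k])) nms[k] else as.character(k)
      walk(x[[k]], if (is.null(pre) || !nzchar(pre)) nm else paste(pre, nm, sep = "."))
    }
  }
  walk(a, prefix %||% "")
  out <- vals[seq_len(i)]
  names(out) <- keys[seq_len(i)]
  out
}

tree_dot <- function(a, b) {
  fa <- flatten_tree(a); fb <- flatten_tree(b)
  s <- 0
  for (i in seq_along(fa)) s <- s + sum(fa[[i]] * fb[[i]])
  s
}

tree_sq_norm <- function(a) tree_dot(a, a)

# row-broadcast helpers (faster than sweep in hot paths)
add_rowvec <- function(x, b) x + rep(b, each = nrow(x))
mul_rowvec <- function(x, g) x * rep(g, each = nrow(x))

# Rebuild a parameter tree from a flat named list, following a skeleton.
unflatten_tree <- function(flat, skeleton) {
  i <- 0L
  rebuild <- function(node) {
    if (!is.list(node)) {
      i <<- i + 1L
      return(flat[[i]])
    }
    out <- vector("list", length(node))
    names(out) <- names(node)
    for (k in seq_along(node)) out[[k]] <- rebuild(node[[k]])
    out
  }
  rebuild(skeleton)
}

# fan-in uniform initialization
init_mat <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}
init_vec <- function(n, fan_in = n) {
  lim <- 1 / sqrt(fan_in)
  stats::runif(n, -lim, lim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
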