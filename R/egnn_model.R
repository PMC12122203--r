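#' Model configuration for the fold-embedding network
#'
#' The embedder is a stack of `n_blocks` distance-based graph
#' message-passing blocks over the fully connected residue graph. Node
#' features start as sinusoidal positional encodings of width `node_dim`;
#' each block updates them from pairwise messages that see only the two node
#' features and the squared inter-residue distance, so the network is
#' invariant to rotations, translations and reflections of the input
#' coordinates (which are never updated). The final node features are
#' mean-pooled and linearly projected to an `embed_dim`-wide embedding;
#' three linear heads classify the embedding at the class (C),
#' architecture (CA) and topology (CAT) levels of a CATH-style hierarchy.
#'
#' @param n_blocks number of message-passing blocks (>= 2).
#' @param node_dim width of the positional-encoding node features.
#' @param hidden_dim hidden width of the edge/node update perceptrons.
#' @param out_dim output width of the edge/node update perceptrons.
#' @param embed_dim width of the final pooled embedding.
#' @param n_classes named integer vector `c(C=, CA=, CAT=)` of label counts
#'   per hierarchy level (CATH-scale defaults 5, 43, 1421).
#' @param max_len maximum residues per domain; longer traces are truncated
#'   with a warning.
#' @return an object of class `"fc_config"`.
#' @export
fc_config <- function(n_blocks = 2, node_dim = 128, hidden_dim = 128,
                      out_dim = 256, embed_dim = 128,
                      n_classes = c(C = 5, CA = 43, CAT = 1421),
                      max_len = 512) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (node_dim %% 2 != 0) stop("node_dim must be even (sin/cos pairs)")
  dims <- c(node_dim, hidden_dim, out_dim, embed_dim, max_len)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (!all(c("C", "CA", "CAT") %in% names(n_classes))) {
    stop("n_classes must name C, CA and CAT")
  }
  structure(
    list(n_blocks = as.integer(n_blocks), node_dim = as.integer(node_dim),
         hidden_dim = as.integer(hidden_dim), out_dim = as.integer(out_dim),
         embed_dim = as.integer(embed_dim),
         n_classes = vapply(n_classes[c("C", "CA", "CAT")], as.integer,
                            integer(1)),
         max_len = as.integer(max_len)),
    class = "fc_config"
  )
}

#' Sinusoidal positional encoding
#'
#' Row `p` (counted from 0) interleaves `sin(p / 10000^(2i/d))` and
#' `cos(p / 10000^(2i/d))` for `i = 0 .. d/2 - 1`.
#'
#' @param L number of positions.
#' @param d encoding width; must be even.
#' @return `L x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(L, d) {
  if (d %% 2 != 0) stop("positional encoding width must be even")
  if (L < 1) stop("L must be >= 1")
  p <- seq_len(L) - 1
  i <- seq_len(d / 2) - 1
  ang <- outer(p, 1 / 10000^(2 * i / d))
  out <- matrix(0, L, d)
  out[, seq(1, d, by = 2)] <- sin(ang)
  out[, seq(2, d, by = 2)] <- cos(ang)
  out
}

sigm <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigm(x)
dsilu <- function(x) {
  s <- sigm(x)
  s * (1 + x * (1 - s))
}
# derivative reusing a cached sigmoid
dsilu_s <- function(x, s) s * (1 + x * (1 - s))
# fast row-broadcast bias add
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Ordered-pair index for the fully connected residue graph: edge e runs
# from node J[e] into node I[e]; messages are aggregated by sum over I.
edge_index <- function(L) {
  I <- rep(seq_len(L), each = L - 1)
  J <- unlist(lapply(seq_len(L), function(i) seq_len(L)[-i]), use.names = FALSE)
  list(I = I, J = J)
}

# Core block computation on an explicit edge list (I <- J). Used both for
# one full graph (egnn_block) and for a block-diagonal minibatch graph.
block_core <- function(h, d2, ei, params, cache = FALSE) {
  Ein <- cbind(h[ei$I, , drop = FALSE], h[ei$J, , drop = FALSE], d2)
  A1 <- add_bias(Ein %*% params$We1, params$be1)
  s1 <- sigm(A1)
  Z1 <- A1 * s1
  A2 <- add_bias(Z1 %*% params$We2, params$be2)
  s2 <- sigm(A2)
  M <- A2 * s2
  S <- rowsum(M, ei$I)                      # sum over incoming edges
  dimnames(S) <- NULL
  Nin <- cbind(h, S)
  B1 <- add_bias(Nin %*% params$Wn1, params$bn1)
  sb <- sigm(B1)
  H1 <- B1 * sb
  hout <- add_bias(H1 %*% params$Wn2, params$bn2)
  if (cache) {
    attr(hout, "cache") <- list(h = h, ei = ei, Ein = Ein, A1 = A1, s1 = s1,
                                Z1 = Z1, A2 = A2, s2 = s2, Nin = Nin,
                                B1 = B1, sb = sb, H1 = H1)
  }
  hout
}

#' One graph message-passing block
#'
#' For every ordered residue pair `(i, j)` the edge perceptron computes a
#' message from `(h_i, h_j, |x_i - x_j|^2)`; messages into each node are
#' summed and the node perceptron maps `(h_i, sum_j m_ij)` to the updated
#' node features. Coordinates are not updated. Exposed mainly for testing;
#' [embed()] runs the full stack.
#'
#' @param h `L x k` node feature matrix.
#' @param x `L x 3` coordinate matrix.
#' @param params one element of `model$blocks` (weight matrices `We1`,
#'   `be1`, `We2`, `be2`, `Wn1`, `bn1`, `Wn2`, `bn2`).
#' @param cache if `TRUE`, also return intermediate activations (used by
#'   backpropagation).
#' @return updated `L x out_dim` node features (with a `"cache"` attribute
#'   when requested).
#' @export
egnn_block <- function(h, x, params, cache = FALSE) {
  L <- nrow(h)
  if (L < 2) stop("a block needs at least 2 nodes")
  assert_coords(x)
  ei <- edge_index(L)
  d2 <- rowSums((x[ei$I, , drop = FALSE] - x[ei$J, , drop = FALSE])^2)
  block_core(h, d2, ei, params, cache = cache)
}

# Forward pass over a minibatch of structures, treated as one
# block-diagonal graph (edges only within samples). Returns per-sample
# embeddings/logits as matrix rows.
fc_forward_multi <- function(coords_list, model, cache = FALSE) {
  cfg <- model$config
  Ls <- vapply(coords_list, nrow, integer(1))
  if (any(Ls < 2)) stop("each structure needs at least 2 residues")
  offs <- cumsum(c(0L, Ls[-length(Ls)]))
  x <- do.call(rbind, coords_list)
  h <- do.call(rbind, lapply(Ls, positional_encoding, d = cfg$node_dim))
  I <- integer(0); J <- integer(0)
  for (s in seq_along(Ls)) {
    ei <- edge_index(Ls[s])
    I <- c(I, ei$I + offs[s])
    J <- c(J, ei$J + offs[s])
  }
  ei <- list(I = I, J = J)
  d2 <- rowSums((x[I, , drop = FALSE] - x[J, , drop = FALSE])^2)
  caches <- if (cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    h <- block_core(h, d2, ei, model$blocks[[b]], cache = cache)
    if (cache) {
      caches[[b]] <- attr(h, "cache")
      attr(h, "cache") <- NULL
    }
  }
  groups <- rep(seq_along(Ls), Ls)
  pooled <- rowsum(h, groups) / Ls          # B x out_dim
  emb <- add_bias(pooled %*% model$proj$W, model$proj$b)
  logits <- lapply(model$heads, function(hd) add_bias(emb %*% hd$W, hd$b))
  list(embedding = emb, logits = logits, pooled = pooled, h_final = h,
       caches = caches, groups = groups, Ls = Ls)
}

# Single-structure forward pass (thin wrapper over the batched path).
fc_forward <- function(coords, model, cache = FALSE) {
  fw <- fc_forward_multi(list(coords), model, cache = cache)
  list(embedding = drop(fw$embedding), logits = lapply(fw$logits, drop),
       pooled = drop(fw$pooled), h_final = fw$h_final, caches = fw$caches,
       groups = fw$groups, Ls = fw$Ls)
}

#' Embed a domain structure
#'
#' Runs the message-passing stack on the domain's C-alpha trace and returns
#' the mean-pooled, linearly projected embedding. The embedding width is
#' fixed by the model regardless of domain length, and the value is
#' invariant to rigid motions and reflections of the input coordinates.
#'
#' @param domain a [domain_structure()].
#' @param model a trained or initialized model (see [initialize_model()]).
#' @return an object of class `"fc_embedding"`: `vector` (length
#'   `embed_dim`) and `domain_id`.
#' @export
embed <- function(domain, model) {
  coords <- truncate_coords(domain$ca_coords, model$config$max_len,
                            domain$domain_id)
  if (nrow(coords) < 5) stop("domain too short to embed (need >= 5 residues)")
  fw <- fc_forward(coords, model)
  if (!all(is.finite(fw$embedding))) stop("non-finite embedding")
  structure(list(vector = fw$embedding, domain_id = domain$domain_id),
            class = "fc_embedding")
}

truncate_coords <- function(coords, max_len, id) {
  assert_coords(coords)
  if (nrow(coords) > max_len) {
    warning(sprintf("domain %s has %d residues; truncating to max_len = %d",
                    id, nrow(coords), max_len))
    coords <- coords[seq_len(max_len), , drop = FALSE]
  }
  coords
}

#' Embed many domains into a matrix
#'
#' @param domains list of [domain_structure()]s.
#' @param model the embedding model.
#' @return `length(domains) x embed_dim` matrix, rows named by domain id.
#' @export
embed_domains <- function(domains, model) {
  out <- t(vapply(domains, function(d) embed(d, model)$vector,
                  numeric(model$config$embed_dim)))
  rownames(out) <- vapply(domains, `[[`, "", "domain_id")
  out
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Hierarchical fold classification of a domain
#'
#' Applies the three classification heads to the domain embedding. Each
#' head's logits pass through a softmax; per level the argmax label is
#' reported, and `NA` (abstain) when its probability falls below
#' `threshold`.
#'
#' @param domain a [domain_structure()].
#' @param model a trained model.
#' @param threshold confidence threshold below which the classifier
#'   abstains (default 0.9).
#' @return list with one element per level (`C`, `CA`, `CAT`), each holding
#'   `probs` (sums to 1), `label` (integer or `NA`) and `confidence`.
#' @export
predict_cat <- function(domain, model, threshold = 0.9) {
  coords <- truncate_coords(domain$ca_coords, model$config$max_len,
                            domain$domain_id)
  fw <- fc_forward(coords, model)
  out <- lapply(fw$logits, function(z) {
    p <- softmax(z)
    top <- which.max(p)
    list(probs = p, label = if (p[top] >= threshold) top else NA_integer_,
         confidence = p[top])
  })
  names(out) <- names(fw$logits)
  out
}

#' Model checkpoint fingerprint
#'
#' A short digest of the architecture and weights, stored in databases built
#' with the model so that searching with a different model can be detected.
#'
#' @param model a model object.
#' @return character fingerprint.
#' @export
model_fingerprint <- function(model) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  payload <- list(config = model$config, blocks = model$blocks,
                  proj = model$proj, heads = model$heads)
  saveRDS(payload, tmp, version = 3, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Save / load a model checkpoint
#'
#' @param model a model object.
#' @param path checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fc_model")) stop("not a model checkpoint: ", path)
  model
}

#' @export
print.fc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<fc_model> %d blocks, node %d, hidden %d, out %d, ",
                     "embed %d; heads C=%d CA=%d CAT=%d\n"),
              cfg$n_blocks, cfg$node_dim, cfg$hidden_dim, cfg$out_dim,
              cfg$embed_dim, cfg$n_classes["C"], cfg$n_classes["CA"],
              cfg$n_classes["CAT"]))
  invisible(x)
}
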