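# Shared fixtures. Small model configs keep the graph-network forward pass
# fast; geometry and search behaviour do not depend on the widths.

toy_config <- function(n_classes = c(C = 2, CA = 4, CAT = 8)) {
  fc_config(n_blocks = 2, node_dim = 32, hidden_dim = 32, out_dim = 32,
            embed_dim = 32, n_classes = n_classes, max_len = 64)
}

tiny_config <- function() {
  fc_config(n_blocks = 2, node_dim = 8, hidden_dim = 8, out_dim = 8,
            embed_dim = 8, n_classes = c(C = 2, CA = 2, CAT = 2),
            max_len = 256)
}

toy_model <- function(config = toy_config(), seed = 5, init_sd = 0.05) {
  initialize_model(config, fc_train_config(egnn_init_sd = init_sd),
                   seed = seed)
}

random_domain <- function(n = 30, id = "dom", seed = NULL) {
  with_seed(seed, {
    coords <- apply_rigid(make_helix(n), random_rotation(),
                          rnorm(3, sd = 10))
    coords <- coords + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    domain_structure(id, id, 0L, coords, paste(rep("A", n), collapse = ""))
  })
}

# Training fixture: 8 fold families x n_members, hierarchical labels
# C (2 classes) / CA (4) / CAT (8 = the families).
family_dataset <- function(n_members, templates, noise_sd = 1.0,
                           seed_base = 100) {
  data <- list()
  for (f in seq_along(templates)) {
    mem <- make_fold_family(templates[[f]], n_members, noise_sd = noise_sd,
                            seed = seed_base + f,
                            id_prefix = sprintf("s%d_%s", seed_base,
                                                templates[[f]]$family_id))
    for (m in mem) {
      data[[length(data) + 1]] <- labeled_domain(
        m, C = 1 + (f - 1) %/% 4, CA = 1 + (f - 1) %/% 2, CAT = f)
    }
  }
  data
}

# The trained toy model is expensive; train it lazily once per R session
# and cache it in tempdir() so every test file (helpers are re-sourced per
# file) reuses the same run.
get_toy_training <- function() {
  cache <- file.path(tempdir(), "foldsearch-toy-training.rds")
  if (file.exists(cache)) return(readRDS(cache))
  templates <- make_fold_templates(8, n_res = 36, seed = 42)
  data <- family_dataset(50, templates)
  tc <- fc_train_config(max_epochs = 150, seed = 17, patience = 40,
                        batch_size = 8)
  out <- list(fit = train(data, toy_config(), tc), templates = templates,
              data = data)
  saveRDS(out, cache)
  out
}

# independent oracle: enumerate all injective assignments by brute force
# over subsets and permutations
oracle_pairings <- function(tm, thr) {
  Q <- nrow(tm); H <- ncol(tm)
  if (H < Q) return(list())
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  subs <- utils::combn(H, Q, simplify = FALSE)
  out <- list()
  for (s in subs) for (p in perms(s)) {
    if (all(tm[cbind(seq_len(Q), p)] >= thr)) out[[length(out) + 1]] <- p
  }
  out
}

# Minimal db builder for retrieval logic tests: unit embeddings are given
# directly, records are placeholder domains.
stub_db <- function(emb, chain_ids = NULL, orders = NULL) {
  M <- nrow(emb)
  chain_ids <- chain_ids %||% sprintf("c%03d", seq_len(M))
  orders <- orders %||% rep(0L, M)
  records <- lapply(seq_len(M), function(i) {
    domain_structure(sprintf("d%03d", i), chain_ids[i], orders[i],
                     make_helix(6), "AAAAAA")
  })
  foldsearch:::new_fold_db(records, foldsearch:::normalize_rows(emb))
}

`%||%` <- foldsearch:::`%||%`
with_seed <- foldsearch:::with_seed
apply_rigid <- foldsearch:::apply_rigid
random_rotation_m <- function(seed = NULL) {
  foldsearch:::with_seed(seed, foldsearch:::random_rotation())
}
random_rotation <- foldsearch:::random_rotation
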