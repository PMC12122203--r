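#' Build a fold database from domains
#'
#' Embeds every domain with the model, unit-normalizes the embeddings (so
#' cosine similarity is a plain inner product) and packages them with the
#' domain records and the model fingerprint.
#'
#' @param domains list of [domain_structure()]s with unique ids.
#' @param model the embedding model.
#' @param metadata optional character vector of free-form per-domain
#'   metadata.
#' @return a `fold_db`.
#' @export
createdb <- function(domains, model, metadata = NULL) {
  ids <- vapply(domains, `[[`, "", "domain_id")
  if (anyDuplicated(ids)) {
    stop("duplicate domain ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(domains) == 0) {
    emb <- matrix(numeric(0), 0, model$config$embed_dim)
  } else {
    emb <- unname(normalize_rows(embed_domains(domains, model)))
  }
  new_fold_db(domains, emb, model_fingerprint(model), metadata = metadata)
}

#' Exhaustive top-k cosine retrieval
#'
#' Computes the cosine similarity of the query embedding to every database
#' row (inner product on unit vectors) and returns the `min(k, M)` highest,
#' in descending order; ties are broken by ascending database index.
#'
#' @param query an `fc_embedding` or bare numeric vector.
#' @param db a `fold_db`.
#' @param k number of hits requested.
#' @return data frame with columns `index` and `cosine`.
#' @export
topk_cosine <- function(query, db, k) {
  if (k < 1) stop("k must be >= 1")
  v <- if (inherits(query, "fc_embedding")) query$vector else query
  M <- nrow(db$embeddings)
  if (M == 0) return(data.frame(index = integer(0), cosine = numeric(0)))
  v <- v / sqrt(sum(v^2))
  # row-wise summation keeps identical rows bit-identical (BLAS gemv
  # rounding can depend on row position, breaking tie-breaks)
  cos <- rowSums(db$embeddings * rep(v, each = M))
  o <- order(-cos, seq_len(M))[seq_len(min(k, M))]
  data.frame(index = o, cosine = cos[o])
}

#' Batched exhaustive search for many queries
#'
#' Splits the query matrix into row batches and runs the same exhaustive
#' inner-product retrieval per batch; results are identical for any
#' `batch_size`.
#'
#' @param queries `N x d` matrix of query embeddings (rows need not be
#'   normalized).
#' @param db a `fold_db`.
#' @param k hits per query.
#' @param batch_size rows per batch.
#' @return list of `N` data frames as in [topk_cosine()].
#' @export
batched_search <- function(queries, db, k, batch_size = 1024) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  N <- nrow(queries)
  if (N == 0) return(list())
  out <- vector("list", N)
  starts <- seq(1, N, by = batch_size)
  for (s in starts) {
    rows <- s:min(s + batch_size - 1, N)
    Q <- queries[rows, , drop = FALSE]
    for (r in seq_along(rows)) {
      # score through the exact single-query path so results are
      # bit-identical for every batch size
      out[[rows[r]]] <- topk_cosine(Q[r, ], db, k)
    }
  }
  out
}

#' Single-domain search with TM-score validation
#'
#' Embeds the query, retrieves the top `k` database domains by cosine
#' similarity, aligns the query against each candidate with
#' [align_structures()] and reports both TM-score normalizations. Hits are
#' sorted by descending query-normalized TM-score; `tm_threshold`
#' optionally removes candidates below it.
#'
#' @param query a [domain_structure()].
#' @param db a `fold_db`.
#' @param model the embedding model (must match the database).
#' @param k candidates to validate (default 20).
#' @param tm_threshold optional minimum TM-score; `NULL` reports all `k`.
#' @param threshold_on which normalization the threshold applies to
#'   (`"tm_query"` or `"tm_target"`).
#' @param align_args list of extra arguments for [align_structures()].
#' @return data frame of class `"fc_hits"` with columns `query`, `target`,
#'   `target_chain`, `qlen`, `tlen`, `cosine`, `tm_query`, `tm_target`,
#'   `rank`.
#' @export
search_single <- function(query, db, model, k = 20, tm_threshold = NULL,
                          threshold_on = c("tm_query", "tm_target"),
                          align_args = list()) {
  threshold_on <- match.arg(threshold_on)
  cand <- topk_cosine(embed(query, model), db, k)
  hits <- lapply(seq_len(nrow(cand)), function(i) {
    rec <- db$records[[cand$index[i]]]
    al <- do.call(align_structures, c(list(query, rec), align_args))
    data.frame(query = query$domain_id, target = rec$domain_id,
               target_chain = rec$chain_id, qlen = n_residues(query),
               tlen = n_residues(rec), cosine = cand$cosine[i],
               tm_query = al$tm_query, tm_target = al$tm_target,
               stringsAsFactors = FALSE)
  })
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query = character(0), target = character(0),
               target_chain = character(0), qlen = integer(0),
               tlen = integer(0), cosine = numeric(0),
               tm_query = numeric(0), tm_target = numeric(0))
  if (!is.null(tm_threshold)) {
    hits <- hits[hits[[threshold_on]] >= tm_threshold, , drop = FALSE]
  }
  hits <- hits[order(-hits$tm_query), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  class(hits) <- c("fc_hits", "data.frame")
  hits
}

#' Write single-domain hits as TSV
#'
#' @param hits an `fc_hits` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
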