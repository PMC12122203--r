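#' Candidate-chain prefilter for multi-domain search
#'
#' Collects the database chains that contain a hit to any query domain in
#' the per-domain top-k lists, discards chains with fewer domains than the
#' query has, and retrieves *all* domains of each surviving chain (not only
#' those that appeared in the hit lists).
#'
#' @param per_domain_hits list (one per query domain) of [topk_cosine()]
#'   data frames.
#' @param db a `fold_db`.
#' @param n_query_domains number of domains in the query.
#' @return list of `chain_record`s: `chain_id` plus `domain_indices`
#'   (database rows ordered by `order_in_chain`).
#' @export
prefilter_chains <- function(per_domain_hits, db, n_query_domains) {
  hit_idx <- unique(unlist(lapply(per_domain_hits, `[[`, "index")))
  if (length(hit_idx) == 0) return(list())
  chain_ids <- vapply(db$records, `[[`, "", "chain_id")
  orders <- vapply(db$records, `[[`, integer(1), "order_in_chain")
  chains <- unique(chain_ids[hit_idx])
  out <- lapply(chains, function(cid) {
    idx <- which(chain_ids == cid)
    idx <- idx[order(orders[idx])]
    if (length(idx) < n_query_domains) return(NULL)
    structure(list(chain_id = cid, domain_indices = idx),
              class = "chain_record")
  })
  out[!vapply(out, is.null, TRUE)]
}

#' All-against-all TM-score matrix between query and candidate domains
#'
#' @param query_domains ordered list of query [domain_structure()]s.
#' @param chain_record one prefiltered `chain_record`.
#' @param db a `fold_db`.
#' @param align_args list of extra arguments for [align_structures()].
#' @return `Q x H` matrix of query-normalized TM-scores.
#' @export
all_vs_all_tm <- function(query_domains, chain_record, db,
                          align_args = list()) {
  H <- length(chain_record$domain_indices)
  Q <- length(query_domains)
  tm <- matrix(0, Q, H)
  for (q in seq_len(Q)) {
    for (h in seq_len(H)) {
      rec <- db$records[[chain_record$domain_indices[h]]]
      al <- do.call(align_structures, c(list(query_domains[[q]], rec),
                                        align_args))
      tm[q, h] <- al$tm_query
    }
  }
  tm
}

#' Enumerate injective query-hit domain pairings above a TM threshold
#'
#' A pairing assigns every query domain to a distinct hit-chain domain
#' using only matrix cells at or above `threshold`; an empty list means no
#' complete cover exists. Enumeration stops at `cap` pairings (tandem
#' repeats can explode combinatorially); when the cap is reached the result
#' is guaranteed to contain a maximum-total-TM complete assignment, found
#' by branch-and-bound.
#'
#' @param tm_matrix `Q x H` TM-score matrix from [all_vs_all_tm()].
#' @param threshold per-domain TM-score threshold (default 0.5).
#' @param cap maximum number of pairings to enumerate.
#' @return list of pairing data frames (`query_pos`, `hit_pos`, `tm`), with
#'   attribute `"truncated"` set when the cap was hit.
#' @export
enumerate_pairings <- function(tm_matrix, threshold = 0.5, cap = 10000) {
  Q <- nrow(tm_matrix); H <- ncol(tm_matrix)
  allowed <- lapply(seq_len(Q), function(q) which(tm_matrix[q, ] >= threshold))
  if (any(vapply(allowed, length, integer(1)) == 0) || H < Q) {
    out <- list()
    attr(out, "truncated") <- FALSE
    return(out)
  }
  res <- vector("list", cap)
  count <- 0
  truncated <- FALSE
  assign_h <- integer(Q)
  used <- rep(FALSE, H)
  rec <- function(q) {
    if (truncated) return()
    if (q > Q) {
      count <<- count + 1
      if (count <= cap) {
        res[[count]] <<- assign_h + 0L
      }
      if (count >= cap) truncated <<- TRUE
      return()
    }
    for (h in allowed[[q]]) {
      if (!used[h]) {
        used[h] <<- TRUE
        assign_h[q] <<- h
        rec(q + 1)
        used[h] <<- FALSE
        if (truncated) return()
      }
    }
  }
  rec(1)
  res <- res[seq_len(min(count, cap))]
  if (truncated) {
    best <- best_assignment(tm_matrix, allowed)
    if (!is.null(best) &&
        !any(vapply(res, function(a) all(a == best), logical(1)))) {
      res <- c(res, list(best))
    }
  }
  out <- lapply(res, function(a) {
    data.frame(query_pos = seq_len(Q), hit_pos = a,
               tm = tm_matrix[cbind(seq_len(Q), a)])
  })
  attr(out, "truncated") <- truncated
  out
}

# Branch-and-bound maximum-total-TM complete assignment.
best_assignment <- function(tm_matrix, allowed) {
  Q <- nrow(tm_matrix); H <- ncol(tm_matrix)
  row_max <- vapply(seq_len(Q), function(q)
    max(tm_matrix[q, allowed[[q]]]), numeric(1))
  best_val <- -Inf
  best_a <- NULL
  a <- integer(Q)
  used <- rep(FALSE, H)
  rec <- function(q, val) {
    if (q > Q) {
      if (val > best_val) { best_val <<- val; best_a <<- a + 0L }
      return()
    }
    if (val + sum(row_max[q:Q]) <= best_val) return()
    hs <- allowed[[q]]
    hs <- hs[order(-tm_matrix[q, hs])]
    for (h in hs) {
      if (!used[h]) {
        used[h] <<- TRUE; a[q] <<- h
        rec(q + 1, val + tm_matrix[q, h])
        used[h] <<- FALSE
      }
    }
  }
  rec(1, 0)
  best_a
}

#' Classify a domain pairing into a multi-domain match category
#'
#' Categories, from most to least restrictive:
#' `exact_mda` -- the hit chain has exactly the query's domain composition
#' and order, with no extra domains; `contiguous` -- query order preserved
#' and any extra hit domains lie only at the termini; `discontiguous` --
#' query order preserved but at least one unmatched hit domain sits between
#' consecutive matched positions; `unordered` -- all query domains matched,
#' in any order. The most restrictive satisfied label is returned.
#'
#' @param pairing a pairing data frame from [enumerate_pairings()].
#' @param n_hit_domains total number of domains in the hit chain.
#' @return one of `"exact_mda"`, `"contiguous"`, `"discontiguous"`,
#'   `"unordered"`.
#' @export
classify_mda <- function(pairing, n_hit_domains) {
  h <- pairing$hit_pos[order(pairing$query_pos)]
  Q <- length(h)
  ordered <- all(diff(h) > 0)
  if (!ordered) return("unordered")
  if (n_hit_domains == Q && identical(as.integer(h), seq_len(Q))) {
    return("exact_mda")
  }
  if (max(h) - min(h) == Q - 1) return("contiguous")
  "discontiguous"
}

category_rank <- function(category) {
  match(category, c("exact_mda", "contiguous", "discontiguous", "unordered"))
}

#' Multi-domain architecture search
#'
#' Finds database chains that match *all* domains of the query: per-domain
#' top-k cosine retrieval acts as a prefilter over chains, candidate chains
#' are compared all-against-all by TM-score, injective pairings above the
#' threshold are enumerated, and each hit chain is labelled with the most
#' restrictive category any of its pairings satisfies (ties between
#' pairings broken by higher mean TM). One hit row is reported per chain.
#'
#' @param query_domains ordered list of [domain_structure()]s, in their
#'   order along the query chain (user-supplied domain sets are treated as
#'   one chain in the order given).
#' @param db a `fold_db`.
#' @param model the embedding model.
#' @param k per-domain prefilter depth (default 100).
#' @param threshold per-domain TM-score threshold (default 0.5).
#' @param exact_only keep only `exact_mda` hits.
#' @param exclude_self drop the hit chain whose id equals the query chain
#'   id.
#' @param cap pairing enumeration cap per chain.
#' @param align_args list of extra arguments for [align_structures()].
#' @return list with `hits` (one data frame row per hit chain: category,
#'   pairing, per-pair and mean TM, ranked by category restrictiveness then
#'   mean TM) and `pairings` (per-chain list of all surviving pairings).
#' @export
search_multidomain <- function(query_domains, db, model, k = 100,
                               threshold = 0.5, exact_only = FALSE,
                               exclude_self = FALSE, cap = 10000,
                               align_args = list()) {
  Q <- length(query_domains)
  if (Q == 0) stop("no query domains")
  query_chain <- query_domains[[1]]$chain_id
  per_domain <- lapply(query_domains, function(d)
    topk_cosine(embed(d, model), db, k))
  cands <- prefilter_chains(per_domain, db, Q)
  if (exclude_self) {
    cands <- cands[vapply(cands, `[[`, "", "chain_id") != query_chain]
  }
  rows <- list()
  pairings_by_chain <- list()
  for (cr in cands) {
    tm <- all_vs_all_tm(query_domains, cr, db, align_args = align_args)
    prs <- enumerate_pairings(tm, threshold = threshold, cap = cap)
    if (length(prs) == 0) next
    cats <- vapply(prs, classify_mda, "", n_hit_domains = ncol(tm))
    means <- vapply(prs, function(p) mean(p$tm), numeric(1))
    best <- order(category_rank(cats), -means)[1]
    p <- prs[[best]]
    rows[[cr$chain_id]] <- data.frame(
      query_chain = query_chain, hit_chain = cr$chain_id,
      category = cats[best], n_query_domains = Q,
      n_hit_domains = ncol(tm),
      pairing = paste(sprintf("%d>%d", p$query_pos, p$hit_pos),
                      collapse = ";"),
      pair_tm = paste(sprintf("%.4f", p$tm), collapse = ";"),
      mean_tm = means[best], stringsAsFactors = FALSE)
    pairings_by_chain[[cr$chain_id]] <- prs
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_chain = character(0), hit_chain = character(0),
               category = character(0), n_query_domains = integer(0),
               n_hit_domains = integer(0), pairing = character(0),
               pair_tm = character(0), mean_tm = numeric(0))
  if (exact_only) hits <- hits[hits$category == "exact_mda", , drop = FALSE]
  hits <- hits[order(category_rank(hits$category), -hits$mean_tm), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, pairings = pairings_by_chain)
}

#' End-to-end search of whole chains
#'
#' For each query chain: segment with the supplied segmenter, then run the
#' multi-domain search on the resulting domains (a single-domain chain
#' falls through to [search_single()]). A failing segmentation is reported
#' for that chain without aborting the batch.
#'
#' @param chains list of [chain_structure()]s (or a single one).
#' @param db a `fold_db`.
#' @param model the embedding model.
#' @param segmenter function `chain -> segmentation`
#'   (e.g. [segment_single()], [segment_contact()], or a
#'   [segment_external()] closure).
#' @param k prefilter depth for multi-domain queries; also the validation
#'   depth for single-domain fallthrough.
#' @param threshold per-domain TM-score threshold.
#' @param ... further arguments passed to [search_multidomain()].
#' @return named list (per chain) with `segmentation` and either
#'   `multidomain` (a [search_multidomain()] result), `single` (an
#'   `fc_hits` frame) or `error` (message string).
#' @export
easy_search <- function(chains, db, model, segmenter = segment_single,
                        k = 100, threshold = 0.5, ...) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  out <- lapply(chains, function(chain) {
    seg <- tryCatch(segmenter(chain), error = function(e) e)
    if (inherits(seg, "error")) {
      return(list(segmentation = NULL, error = conditionMessage(seg)))
    }
    if (length(seg$domains) == 1) {
      hits <- search_single(seg$domains[[1]], db, model, k = min(k, 20),
                            tm_threshold = threshold)
      list(segmentation = seg, single = hits)
    } else {
      res <- search_multidomain(seg$domains, db, model, k = k,
                                threshold = threshold, ...)
      list(segmentation = seg, multidomain = res)
    }
  })
  names(out) <- vapply(chains, `[[`, "", "chain_id")
  out
}

#' Write multi-domain hits as TSV
#'
#' @param result a [search_multidomain()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_multidomain_tsv <- function(result, path) {
  utils::write.table(result$hits, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
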