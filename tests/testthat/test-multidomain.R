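pairing_df <- function(h, tm = 0.8) {
  data.frame(query_pos = seq_along(h), hit_pos = h, tm = tm)
}

test_that("match categories follow the four archetypes", {
  # query [A,B,C]: hit [A,B,C] exact; [X,A,B,C] contiguous;
  # [A,X,B,C] discontiguous; [B,A,C] unordered
  expect_equal(classify_mda(pairing_df(1:3), 3), "exact_mda")
  expect_equal(classify_mda(pairing_df(2:4), 4), "contiguous")
  expect_equal(classify_mda(pairing_df(c(1, 3, 4)), 4), "discontiguous")
  expect_equal(classify_mda(pairing_df(c(2, 1, 3)), 3), "unordered")
  # consecutive but with terminal extras on both sides
  expect_equal(classify_mda(pairing_df(c(2, 3)), 4), "contiguous")
  # order preserved, internal gap, plus terminal extras
  expect_equal(classify_mda(pairing_df(c(2, 5)), 6), "discontiguous")
  # single-domain query occupying the whole hit chain
  expect_equal(classify_mda(pairing_df(1), 1), "exact_mda")
})

test_that("every complete pairing receives exactly one category and the
           nesting is consistent", {
  set.seed(91)
  for (rep in 1:60) {
    H <- sample(1:5, 1)
    Q <- sample(seq_len(H), 1)
    h <- sample(H, Q)
    cat <- classify_mda(pairing_df(h), H)
    ordered <- all(diff(h) > 0)
    expect_true(cat %in% c("exact_mda", "contiguous", "discontiguous",
                           "unordered"))
    if (cat == "exact_mda") {
      # exact implies the contiguous predicate
      expect_true(ordered && max(h) - min(h) == Q - 1 && H == Q)
    }
    if (cat == "contiguous") expect_true(ordered && max(h) - min(h) == Q - 1)
    if (cat == "discontiguous") expect_true(ordered && max(h) - min(h) > Q - 1)
    if (cat == "unordered") expect_false(ordered)
  }
})

test_that("pairing enumeration equals the brute-force permutation oracle
           for Q,H <= 5", {
  set.seed(92)
  for (rep in 1:40) {
    Q <- sample(1:5, 1); H <- sample(Q:5, 1)
    tm <- matrix(runif(Q * H), Q, H)
    got <- enumerate_pairings(tm, threshold = 0.5)
    want <- oracle_pairings(tm, 0.5)
    key <- function(h) paste(h, collapse = ",")
    expect_setequal(vapply(got, function(p) key(p$hit_pos), ""),
                    vapply(want, key, ""))
  }
  # worked 2x2 cases
  both <- enumerate_pairings(matrix(0.9, 2, 2))
  expect_length(both, 2)
  one <- enumerate_pairings(rbind(c(0.9, 0.9), c(0.3, 0.9)))
  expect_length(one, 1)
  expect_equal(one[[1]]$hit_pos, c(1, 2))
  none <- enumerate_pairings(rbind(c(0.9, 0.9), c(0.3, 0.2)))
  expect_length(none, 0)
})

test_that("the enumeration cap keeps a maximum-total-TM assignment", {
  tm <- matrix(0.6, 5, 6)
  tm[cbind(1:5, 1:5)] <- 0.95          # unique best assignment
  capped <- enumerate_pairings(tm, threshold = 0.5, cap = 10)
  expect_true(attr(capped, "truncated"))
  totals <- vapply(capped, function(p) sum(p$tm), numeric(1))
  expect_equal(max(totals), 5 * 0.95, tolerance = 1e-12)
  full <- enumerate_pairings(tm, threshold = 0.5, cap = 1e5)
  expect_false(attr(full, "truncated"))
  expect_length(full, 6 * 5 * 4 * 3 * 2)
})

test_that("chain prefilter keeps whole chains with enough domains", {
  emb <- diag(8)
  chain_ids <- c("x", "x", "x", "y", "y", "z", "z", "z")
  orders <- c(2L, 0L, 1L, 1L, 0L, 0L, 1L, 2L)
  db <- stub_db(emb, chain_ids, orders)
  hits <- list(data.frame(index = c(2L, 4L), cosine = c(.9, .8)),
               data.frame(index = 6L, cosine = .7),
               data.frame(index = 1L, cosine = .6))
  out <- prefilter_chains(hits, db, n_query_domains = 3)
  ids <- vapply(out, `[[`, "", "chain_id")
  expect_setequal(ids, c("x", "z"))       # y has 2 < 3 domains
  x <- out[[which(ids == "x")]]
  # all domains of the chain, ordered by order_in_chain
  expect_equal(x$domain_indices, c(2L, 3L, 1L))
  expect_length(prefilter_chains(list(data.frame(index = integer(0),
                                                 cosine = numeric(0))),
                                 db, 2), 0)
})

test_that("multi-domain search recovers a planted chain as an exact match
           and is order-invariant for hit permutations", {
  model <- toy_model(seed = 93, init_sd = 0.05)
  tpl <- make_fold_templates(3, n_res = 60, seed = 94)
  mk <- function(i, tag) make_fold_family(
    tpl[[i]], 1, noise_sd = 0.5, seed = 200 + i,
    id_prefix = paste0(tag, i))[[1]]
  qd <- lapply(1:3, mk, tag = "q")
  query <- make_multidomain_chain(qd, chain_id = "probe")
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (p in perms) {
    hd <- lapply(p, mk, tag = "h")
    hit <- make_multidomain_chain(hd, chain_id = "hitchain")
    db <- createdb(c(query$domains, hit$domains), model)
    res <- search_multidomain(query$domains, db, model, k = 10,
                              threshold = 0.5)
    expect_setequal(res$hits$hit_chain, c("probe", "hitchain"))
    self <- res$hits[res$hits$hit_chain == "probe", ]
    expect_equal(self$category, "exact_mda")
    expect_equal(self$mean_tm, 1, tolerance = 1e-6)
    other <- res$hits[res$hits$hit_chain == "hitchain", ]
    expect_equal(other$category,
                 if (identical(p, 1:3)) "exact_mda" else "unordered")
    # excluding self-hits leaves only the permuted chain
    res2 <- search_multidomain(query$domains, db, model, k = 10,
                               exclude_self = TRUE)
    expect_equal(res2$hits$hit_chain, "hitchain")
  }
})

test_that("easy-search degenerates to single-domain search for one-domain
           chains and reports segmentation failures per chain", {
  model <- toy_model(seed = 95, init_sd = 0.05)
  tpl <- make_fold_templates(2, n_res = 50, seed = 96)
  d1 <- make_fold_family(tpl[[1]], 1, noise_sd = 0.5, seed = 7)[[1]]
  one <- make_multidomain_chain(list(d1), chain_id = "solo")
  db <- createdb(list(d1), model)
  res <- easy_search(one$chain, db, model, segmenter = segment_single,
                     threshold = 0.3)
  expect_named(res, "solo")
  expect_false(is.null(res$solo$single))
  expect_equal(res$solo$single$target[1], d1$domain_id)
  # failing segmenter is reported, not thrown
  bad <- easy_search(one$chain, db, model,
                     segmenter = function(chain) stop("boom"))
  expect_equal(bad$solo$error, "boom")
})
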