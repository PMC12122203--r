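#' Chain segmentation contract and baseline segmenters
#'
#' A segmenter is any function mapping a [chain_structure()] to a
#' `segmentation` object: a per-residue assignment vector (`0` marks
#' non-domain residues, NDR; positive integers index domains in order of
#' first residue) plus the derived ordered list of [domain_structure()]s.
#' Neural segmentation networks are deliberately external to this package;
#' [segment_external()] adapts any such tool through a simple per-residue
#' TSV contract, while [segment_single()] and [segment_contact()] are
#' self-contained baselines.
#'
#' @name segmentation
NULL

new_segmentation <- function(chain, assignments) {
  L <- n_residues(chain)
  assignments <- as.integer(assignments)
  if (length(assignments) != L) {
    stop("assignments must label every residue")
  }
  labs <- sort(unique(assignments[assignments > 0]))
  # renumber domains by order of first residue
  firsts <- vapply(labs, function(l) which(assignments == l)[1], integer(1))
  labs <- labs[order(firsts)]
  remap <- integer(max(c(assignments, 0L)) + 1L)
  remap[labs + 1L] <- seq_along(labs)
  assignments <- ifelse(assignments > 0, remap[assignments + 1L], 0L)
  seq1 <- strsplit(chain$sequence, "")[[1]]
  domains <- lapply(seq_along(labs), function(k) {
    idx <- which(assignments == k)
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    ranges <- lapply(runs, function(r) {
      c(chain$residue_numbers[r[1]], chain$residue_numbers[r[length(r)]])
    })
    domain_structure(
      domain_id = sprintf("%s_d%02d", chain$chain_id, k),
      chain_id = chain$chain_id,
      order_in_chain = k - 1L,
      ca_coords = chain$ca_coords[idx, , drop = FALSE],
      sequence = paste(seq1[idx], collapse = ""),
      residue_ranges = unname(ranges)
    )
  })
  structure(list(chain_id = chain$chain_id, assignments = assignments,
                 domains = domains),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s: %d domains, %d NDR of %d residues\n",
              x$chain_id, length(x$domains), sum(x$assignments == 0),
              length(x$assignments)))
  invisible(x)
}

#' @describeIn segmentation trivial baseline: the whole chain is one domain,
#'   no NDR.
#' @param chain a [chain_structure()].
#' @return a `segmentation` object.
#' @export
segment_single <- function(chain) {
  if (n_residues(chain) < 5) stop("chain too short to segment")
  new_segmentation(chain, rep(1L, n_residues(chain)))
}

#' @describeIn segmentation deterministic contact-graph baseline. Builds the
#'   C-alpha contact graph (pairs within `cutoff` Angstrom and at least
#'   `min_seq_sep` apart in sequence), takes its connected components as
#'   candidate domains, marks residues with no long-range contacts as NDR,
#'   and merges components smaller than `min_domain_len` into the
#'   sequence-adjacent component they touch most.
#' @param min_domain_len minimum residues per domain.
#' @param cutoff contact distance cutoff (Angstrom).
#' @param min_seq_sep minimum sequence separation for a contact.
#' @export
segment_contact <- function(chain, min_domain_len = 30, cutoff = 8,
                            min_seq_sep = 4) {
  L <- n_residues(chain)
  if (L < 5) stop("chain too short to segment")
  D <- as.matrix(stats::dist(chain$ca_coords))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  adj <- (D <= cutoff) & (sep >= min_seq_sep)
  has_contact <- rowSums(adj) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  assignments <- ifelse(has_contact, comp, 0L)
  # merge small clusters into the neighbouring cluster they contact most;
  # clusters with no contacts to others become NDR
  repeat {
    sizes <- table(assignments[assignments > 0])
    if (length(sizes) <= 1) break      # never dissolve the last cluster
    small <- names(sizes)[sizes < min_domain_len]
    if (length(small) == 0) break
    lab <- as.integer(small[which.min(sizes[small])])
    idx <- which(assignments == lab)
    touch <- colSums(adj[idx, , drop = FALSE])
    cand <- assignments[touch > 0]
    cand <- cand[cand > 0 & cand != lab]
    if (length(cand) > 0) {
      tgt <- as.integer(names(which.max(table(cand))))
    } else {
      # no spatial neighbour: absorb into nearest domain along the sequence
      others <- which(assignments > 0 & assignments != lab)
      if (length(others) == 0) { assignments[idx] <- 0L; next }
      nearest <- others[which.min(vapply(others, function(o)
        min(abs(o - idx)), numeric(1)))]
      tgt <- assignments[nearest]
    }
    assignments[idx] <- tgt
  }
  sizes <- table(assignments[assignments > 0])
  if (length(sizes) == 0 || max(sizes) < min_domain_len) {
    # no credible domain core (e.g. a rod-like chain): one whole-chain domain
    return(segment_single(chain))
  }
  new_segmentation(chain, assignments)
}

#' @describeIn segmentation adapter for an external segmentation tool. The
#'   adapter is configured with either `fun`, an R function
#'   `chain -> data.frame(residue, label)`, or `command`, an executable that
#'   is given a C-alpha PDB file path and must print one `residue<TAB>label`
#'   line per residue (`label` `0` or `NDR` for non-domain residues). Any
#'   malformed line raises an adapter error naming it.
#' @param adapter_config list with `fun` or `command` as described.
#' @export
segment_external <- function(chain, adapter_config) {
  if (is.null(adapter_config$fun) && is.null(adapter_config$command)) {
    stop("external segmenter not configured: need `fun` or `command`")
  }
  if (!is.null(adapter_config$fun)) {
    out <- adapter_config$fun(chain)
    lines <- sprintf("%s\t%s", out[[1]], out[[2]])
  } else {
    cmd <- adapter_config$command
    if (!file.exists(cmd) && Sys.which(cmd) == "") {
      stop("external segmenter executable not found: ", cmd)
    }
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    write_pdb_ca(chain, tmp)
    lines <- suppressWarnings(system2(cmd, shQuote(tmp), stdout = TRUE))
  }
  parse_assignment_lines(chain, lines)
}

parse_assignment_lines <- function(chain, lines) {
  lines <- lines[nzchar(trimws(lines))]
  L <- n_residues(chain)
  if (length(lines) != L) {
    stop(sprintf("segmenter output has %d lines, expected %d residues",
                 length(lines), L))
  }
  assignments <- integer(L)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(parts) != 2) {
      stop("malformed segmenter output line ", i, ": '", lines[i], "'")
    }
    res <- suppressWarnings(as.integer(parts[1]))
    lab <- if (toupper(parts[2]) == "NDR") 0L else
      suppressWarnings(as.integer(parts[2]))
    if (is.na(res) || is.na(lab)) {
      stop("malformed segmenter output line ", i, ": '", lines[i], "'")
    }
    pos <- match(res, chain$residue_numbers)
    if (is.na(pos)) {
      stop("segmenter output line ", i, " names unknown residue ", res)
    }
    assignments[pos] <- lab
  }
  new_segmentation(chain, assignments)
}
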