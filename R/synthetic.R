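#' Synthetic C-alpha structure generators
#'
#' Idealized alpha-helix and extended-strand C-alpha traces, fold-family
#' templates assembled from them, noisy family members, and multi-domain
#' chains with known segmentation. These stand in for experimentally
#' determined domains so that embedding, training, search and multi-domain
#' classification can all be exercised offline with known ground truth.
#'
#' `make_helix()` uses the standard alpha-helix C-alpha parameterization
#' (rise 1.5 A per residue, radius 2.3 A, 100 degrees per turn), which gives
#' consecutive C-alpha distances of ~3.8 A.
#'
#' @param n_res number of residues.
#' @param rise rise per residue along the helix axis (Angstrom).
#' @param radius helix radius (Angstrom).
#' @param turn rotation per residue (degrees).
#' @return `n_res x 3` coordinate matrix.
#' @export
make_helix <- function(n_res, rise = 1.5, radius = 2.3, turn = 100) {
  if (n_res < 4) stop("a helix needs at least 4 residues")
  p <- seq_len(n_res) - 1
  th <- p * turn * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * p)
}

#' @rdname make_helix
#' @param step axial step per residue for the zigzag strand (Angstrom).
#' @param amp lateral zigzag amplitude (Angstrom).
#' @export
make_strand <- function(n_res, step = 3.3, amp = 0.95) {
  if (n_res < 2) stop("a strand needs at least 2 residues")
  p <- seq_len(n_res) - 1
  cbind(step * p, amp * (-1)^p, rep(0, n_res))
}

# Append element coords to a growing trace so that the join step is ~3.8 A.
# The element is randomly rotated; its first residue is placed 3.8 A from
# the current terminus along a direction pointing away from the body centroid.
append_element <- function(coords, element) {
  element <- sweep(element, 2, element[1, ], "-")   # first residue at origin
  element <- element %*% random_rotation()
  if (is.null(coords)) return(element)
  last <- coords[nrow(coords), ]
  cen <- colMeans(coords)
  u <- last - cen
  if (sqrt(sum(u^2)) < 1e-6) u <- stats::rnorm(3)
  u <- unit_vector(u + 0.5 * stats::rnorm(3))
  rbind(coords, sweep(element, 2, last + 3.8 * u, "+"))
}

#' Generate structurally distinct fold-family templates
#'
#' Each template is a seeded random assembly of 2-4 helix/strand elements
#' with random packing directions, so different families have distinct
#' global shapes while all obey chain geometry (consecutive C-alpha
#' distances ~3.8 A).
#'
#' @param n_families number of templates.
#' @param n_res residues per template; the default (100) is a typical
#'   domain length, and long enough that the TM-score of 1-Angstrom-noise
#'   family members stays well above the between-family background.
#' @param seed integer seed; templates are fully determined by
#'   `(seed, n_families, n_res)`.
#' @return list of `fold_template` objects: `family_id`, `ca_coords`,
#'   `generator_params`.
#' @export
make_fold_templates <- function(n_families = 8, n_res = 100, seed = 1) {
  if (n_res < 12) stop("templates need at least 12 residues (2 elements)")
  with_seed(seed, {
    lapply(seq_len(n_families), function(f) {
      # partition n_res into 2-4 segments of >= 6 residues; cap the
      # element count by what the length can hold
      max_elem <- min(4, n_res %/% 6)
      n_elem <- if (max_elem == 2) 2L else sample(2:max_elem, 1)
      repeat {
        cuts <- sort(sample(seq(6, n_res - 6), n_elem - 1))
        lens <- diff(c(0, cuts, n_res))
        if (all(lens >= 6)) break
      }
      types <- sample(c("helix", "strand"), n_elem, replace = TRUE)
      coords <- NULL
      for (e in seq_len(n_elem)) {
        el <- if (types[e] == "helix") make_helix(lens[e]) else make_strand(lens[e])
        coords <- append_element(coords, el)
      }
      structure(
        list(family_id = sprintf("fam%02d", f), ca_coords = coords,
             generator_params = list(n_elem = n_elem, lens = lens,
                                     types = types, seed = seed)),
        class = "fold_template"
      )
    })
  })
}

#' Sample noisy members of a fold family
#'
#' Members are the template trace plus independent per-atom Gaussian noise,
#' followed by a random rigid motion (rotation + translation), emulating
#' within-family structural variation.
#'
#' @param template a `fold_template`.
#' @param n_members number of members to draw.
#' @param noise_sd per-coordinate Gaussian noise standard deviation
#'   (Angstrom).
#' @param seed optional seed for reproducible families.
#' @param id_prefix prefix for member domain ids.
#' @return list of [domain_structure()] objects; each carries its
#'   `family_id` as an attribute.
#' @export
make_fold_family <- function(template, n_members, noise_sd = 1.0, seed = NULL,
                             id_prefix = template$family_id) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    L <- nrow(template$ca_coords)
    lapply(seq_len(n_members), function(m) {
      x <- template$ca_coords +
        matrix(stats::rnorm(3 * L, sd = noise_sd), ncol = 3)
      x <- apply_rigid(x, random_rotation(), stats::rnorm(3, sd = 20))
      d <- domain_structure(
        domain_id = sprintf("%s_m%03d", id_prefix, m),
        chain_id = sprintf("%s_m%03d", id_prefix, m),
        order_in_chain = 0L,
        ca_coords = x,
        sequence = random_sequence(L)
      )
      attr(d, "family_id") <- template$family_id
      d
    })
  })
}

#' Assemble domains into a multi-domain chain with known segmentation
#'
#' Domains are connected in the given order by extended linkers whose
#' residues step 3.8 A along the outward direction, so the whole chain obeys
#' C-alpha geometry; each subsequent domain is rigidly translated to the
#' linker end. Linker residues are the ground-truth non-domain residues
#' (NDR).
#'
#' @param domains ordered list of [domain_structure()] objects.
#' @param linker_len number of linker residues between consecutive domains.
#'   The spatial separation between consecutive domains scales with
#'   `linker_len` (span `(linker_len + 1) * 3.8` A).
#' @param chain_id id for the assembled chain.
#' @return list with elements `chain` ([chain_structure()]), `segmentation`
#'   (ground truth, see [segment_single()] for the class) and `domains`
#'   (the input domains repositioned, with chain provenance filled in).
#' @export
make_multidomain_chain <- function(domains, linker_len = 5, chain_id = "synth") {
  if (length(domains) < 1) stop("need at least one domain")
  coords <- NULL
  seqs <- character(0)
  assignments <- integer(0)
  placed <- vector("list", length(domains))
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    x <- d$ca_coords
    x <- sweep(x, 2, x[1, ], "-")
    if (is.null(coords)) {
      start <- c(0, 0, 0)
    } else {
      last <- coords[nrow(coords), ]
      u <- unit_vector(last - colMeans(coords) + 1e-8)
      # linker: linker_len NDR residues stepping 3.8 A along u
      link <- t(vapply(seq_len(linker_len),
                       function(j) last + 3.8 * j * u, numeric(3)))
      coords <- rbind(coords, link)
      seqs <- c(seqs, paste(rep("G", linker_len), collapse = ""))
      assignments <- c(assignments, rep(0L, linker_len))
      start <- last + 3.8 * (linker_len + 1) * u
    }
    x <- sweep(x, 2, start, "+")
    from <- nrow(coords %||% matrix(0, 0, 3)) + 1L
    coords <- rbind(coords, x)
    seqs <- c(seqs, d$sequence)
    assignments <- c(assignments, rep(i, nrow(x)))
    pd <- d
    pd$ca_coords <- x
    pd$chain_id <- chain_id
    pd$order_in_chain <- i - 1L
    pd$residue_ranges <- list(c(from, from + nrow(x) - 1L))
    placed[[i]] <- pd
  }
  L <- nrow(coords)
  chain <- chain_structure(chain_id, coords, paste(seqs, collapse = ""),
                           seq_len(L))
  seg <- new_segmentation(chain, assignments)
  list(chain = chain, segmentation = seg, domains = placed)
}

#' Build a multi-domain architecture benchmark with known match categories
#'
#' For a query architecture of three families `(A, B, C)` this constructs a
#' query chain and one database chain per match archetype:
#' `exact_mda` `[A,B,C]`; a second exact-composition chain with a different
#' 3D arrangement (`exact_rearranged`); `contiguous` `[X,A,B,C]` (extra
#' terminal domain); `discontiguous` `[A,X,B,C]` (insertion between matched
#' domains); `unordered` `[B,A,C]`; and `too_few_domains` `[A,B]`, which the
#' chain-size prefilter must eliminate. Every domain instance is a fresh
#' noisy member of its family, so matches rely on structural similarity, not
#' identity.
#'
#' @param templates list of at least 4 `fold_template`s; the first three are
#'   the query architecture, the fourth supplies insertions.
#' @param noise_sd member noise (Angstrom).
#' @param seed seed for member sampling.
#' @param linker_len linker length used in chain assembly.
#' @return list with `query` (a `make_multidomain_chain()` result) and
#'   `db_chains`, a named list of such results keyed by ground-truth label.
#' @export
make_mda_benchmark <- function(templates, noise_sd = 0.8, seed = 1,
                               linker_len = 5) {
  if (length(templates) < 4) stop("need at least 4 fold templates")
  with_seed(seed, {
    fam <- function(i, tag) {
      make_fold_family(templates[[i]], 1, noise_sd = noise_sd,
                       id_prefix = paste0(tag, "_", templates[[i]]$family_id))[[1]]
    }
    archetypes <- list(
      exact_mda         = c(1, 2, 3),
      exact_rearranged  = c(1, 2, 3),
      contiguous        = c(4, 1, 2, 3),
      discontiguous     = c(1, 4, 2, 3),
      unordered         = c(2, 1, 3),
      too_few_domains   = c(1, 2)
    )
    query <- make_multidomain_chain(
      lapply(c(1, 2, 3), fam, tag = "query"),
      linker_len = linker_len, chain_id = "query"
    )
    db_chains <- lapply(names(archetypes), function(nm) {
      make_multidomain_chain(
        lapply(archetypes[[nm]], fam, tag = nm),
        linker_len = linker_len, chain_id = nm
      )
    })
    names(db_chains) <- names(archetypes)
    list(query = query, db_chains = db_chains)
  })
}

#' Write a C-alpha-only PDB file
#'
#' Emits standard fixed-column ATOM records (one CA atom per residue) so
#' synthetic structures can round-trip through [read_chain()].
#'
#' @param x a `chain_structure` or `domain_structure`.
#' @param path output file path.
#' @param chain one-character PDB chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(x, path, chain = "A") {
  L <- nrow(x$ca_coords)
  seq1 <- strsplit(x$sequence, "")[[1]]
  resno <- if (!is.null(x$residue_numbers)) x$residue_numbers else seq_len(L)
  aa3 <- vapply(seq1, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r)) "UNK" else r
  }, "")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(L), aa3, chain, resno,
    x$ca_coords[, 1], x$ca_coords[, 2], x$ca_coords[, 3]
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
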