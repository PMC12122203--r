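#' Read one chain's C-alpha trace from a PDB file
#'
#' Parses ATOM records (via bio3d), selects C-alpha atoms of the requested
#' chain, keeps the first alternate location when several exist, and skips
#' residues that lack a C-alpha atom (reporting them via `message()`).
#' HETATM records are ignored; non-standard residues map to `"X"`.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier; `NULL` takes the first chain in the
#'   file.
#' @return a [chain_structure()].
#' @export
read_chain <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressMessages(suppressWarnings(
    bio3d::read.pdb(path, verbose = FALSE)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[!is.na(at$chain) & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("chain ", chain_id, " not found in ", path)
  all_res <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha atoms for chain ", chain_id,
                          " in ", path)
  # first altloc per residue (file order)
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  skipped <- setdiff(all_res, ca$resno)
  if (length(skipped) > 0) {
    message("read_chain: residues lacking a C-alpha skipped in chain ",
            chain_id, ": ", paste(skipped, collapse = ", "))
  }
  seq1 <- vapply(ca$resid, function(r) {
    a <- suppressWarnings(bio3d::aa321(r))
    if (is.na(a) || !(a %in% AA1)) "X" else a
  }, "")
  chain_structure(
    chain_id = chain_id,
    ca_coords = cbind(ca$x, ca$y, ca$z),
    sequence = paste(seq1, collapse = ""),
    residue_numbers = ca$resno
  )
}

#' Cut a domain out of a chain
#'
#' Selects residues by 1-based inclusive author-numbered ranges,
#' concatenating the segments in range order (a discontinuous domain keeps
#' its `residue_ranges`).
#'
#' @param chain a [chain_structure()].
#' @param ranges list of `c(start, end)` author-numbered ranges.
#' @param domain_id id for the new domain.
#' @param order 0-based order of the domain along its chain.
#' @return a [domain_structure()].
#' @export
extract_domain <- function(chain, ranges, domain_id, order = 0L) {
  if (length(ranges) == 0) stop("empty range selection")
  starts <- vapply(ranges, `[`, numeric(1), 1)
  ends <- vapply(ranges, `[`, numeric(1), 2)
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-length(ends)]) && length(ranges) > 1) {
    stop("overlapping residue ranges")
  }
  idx <- integer(0)
  for (r in ranges) {
    sel <- which(chain$residue_numbers >= r[1] & chain$residue_numbers <= r[2])
    if (length(sel) == 0) {
      stop(sprintf("range %d-%d selects no residues of chain %s",
                   r[1], r[2], chain$chain_id))
    }
    if (r[1] < min(chain$residue_numbers) || r[2] > max(chain$residue_numbers)) {
      stop(sprintf("range %d-%d outside chain %s (residues %d-%d)",
                   r[1], r[2], chain$chain_id, min(chain$residue_numbers),
                   max(chain$residue_numbers)))
    }
    idx <- c(idx, sel)
  }
  seq1 <- strsplit(chain$sequence, "")[[1]]
  domain_structure(
    domain_id = domain_id, chain_id = chain$chain_id,
    order_in_chain = order,
    ca_coords = chain$ca_coords[idx, , drop = FALSE],
    sequence = paste(seq1[idx], collapse = ""),
    residue_ranges = ranges
  )
}

#' Read domain definitions from a TSV file
#'
#' Expected columns: `domain_id`, `chain_id`, `order_in_chain` (0-based)
#' and `ranges` (e.g. `"1-50;61-110"`, author numbering). `path_column`
#' optionally names a column of PDB paths to cut the domains from.
#'
#' @param tsv_path TSV file path.
#' @param pdb_dir directory holding `<chain_id>.pdb` files (used when the
#'   TSV has no explicit path column).
#' @param path_column optional name of a PDB-path column.
#' @return list of [domain_structure()]s.
#' @export
read_domain_tsv <- function(tsv_path, pdb_dir = dirname(tsv_path),
                            path_column = NULL) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("domain_id", "chain_id", "order_in_chain", "ranges")
  if (!all(need %in% names(tab))) {
    stop("domain TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    p <- if (!is.null(path_column)) tab[[path_column]][i] else
      file.path(pdb_dir, paste0(tab$chain_id[i], ".pdb"))
    chain <- read_chain(p, tab$chain_id[i])
    ranges <- lapply(strsplit(tab$ranges[i], ";")[[1]], function(r) {
      as.integer(strsplit(r, "-")[[1]])
    })
    extract_domain(chain, ranges, tab$domain_id[i],
                   as.integer(tab$order_in_chain[i]))
  })
}

# ---- database container ---------------------------------------------------

new_fold_db <- function(records, embeddings, model_fingerprint = "",
                        metadata = NULL) {
  if (length(records) != nrow(embeddings)) {
    stop("record count and embedding rows disagree")
  }
  if (nrow(embeddings) > 0) {
    nrm <- sqrt(rowSums(embeddings^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("embedding rows must be unit-norm")
    }
  }
  metadata <- metadata %||% rep("", length(records))
  structure(list(records = records, embeddings = embeddings,
                 embed_dim = ncol(embeddings),
                 model_fingerprint = model_fingerprint,
                 metadata = metadata),
            class = "fold_db")
}

#' @export
print.fold_db <- function(x, ...) {
  cat(sprintf("<fold_db> %d domains, embedding dim %d, fingerprint %s\n",
              length(x$records), x$embed_dim,
              substr(x$model_fingerprint, 1, 8)))
  invisible(x)
}

encode_ranges <- function(ranges) {
  paste(vapply(ranges, function(r) paste0(r[1], "-", r[2]), ""),
        collapse = ";")
}

decode_ranges <- function(s) {
  lapply(strsplit(s, ";")[[1]], function(r) as.integer(strsplit(r, "-")[[1]]))
}

#' Write / read a fold database on disk
#'
#' The container is a directory holding a plain-text index
#' (`index.tsv`: id, chain, order, length, sequence, ranges, metadata), a
#' JSON header (`meta.json`: record count, embedding width, model
#' fingerprint) and two raw little-endian double blocks (`embeddings.bin`,
#' `coords.bin`), so a write/read round trip is bit-exact.
#'
#' @param db a `fold_db` (from [createdb()]).
#' @param path directory path for the container.
#' @param model optional model whose fingerprint is compared against the
#'   stored one on read; a mismatch raises a warning.
#' @return `write_db()` returns `path` invisibly; `read_db()` returns the
#'   `fold_db`.
#' @export
write_db <- function(db, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  idx <- data.frame(
    domain_id = vapply(db$records, `[[`, "", "domain_id"),
    chain_id = vapply(db$records, `[[`, "", "chain_id"),
    order_in_chain = vapply(db$records, `[[`, integer(1), "order_in_chain"),
    length = vapply(db$records, n_residues, integer(1)),
    sequence = vapply(db$records, `[[`, "", "sequence"),
    ranges = vapply(db$records, function(r) encode_ranges(r$residue_ranges), ""),
    metadata = db$metadata,
    stringsAsFactors = FALSE
  )
  utils::write.table(idx, file.path(path, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_records = length(db$records), embed_dim = db$embed_dim,
         model_fingerprint = db$model_fingerprint),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  con <- file(file.path(path, "embeddings.bin"), "wb")
  writeBin(as.vector(t(db$embeddings)), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(path, "coords.bin"), "wb")
  for (r in db$records) {
    writeBin(as.vector(t(r$ca_coords)), con, size = 8, endian = "little")
  }
  close(con)
  invisible(path)
}

#' @rdname write_db
#' @export
read_db <- function(path, model = NULL) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  idx_path <- file.path(path, "index.tsv")
  idx <- utils::read.delim(idx_path, stringsAsFactors = FALSE,
                           colClasses = c(domain_id = "character",
                                          chain_id = "character",
                                          sequence = "character",
                                          ranges = "character",
                                          metadata = "character"))
  M <- meta$n_records
  d <- meta$embed_dim
  if (nrow(idx) != M) stop("index/record count mismatch in ", path)
  con <- file(file.path(path, "embeddings.bin"), "rb")
  emb <- readBin(con, "double", n = M * d, size = 8, endian = "little")
  close(con)
  embeddings <- matrix(emb, nrow = M, ncol = d, byrow = TRUE)
  con <- file(file.path(path, "coords.bin"), "rb")
  records <- vector("list", M)
  for (i in seq_len(M)) {
    L <- idx$length[i]
    xyz <- readBin(con, "double", n = 3 * L, size = 8, endian = "little")
    records[[i]] <- domain_structure(
      domain_id = idx$domain_id[i], chain_id = idx$chain_id[i],
      order_in_chain = idx$order_in_chain[i],
      ca_coords = matrix(xyz, ncol = 3, byrow = TRUE),
      sequence = idx$sequence[i],
      residue_ranges = decode_ranges(idx$ranges[i])
    )
  }
  close(con)
  db <- new_fold_db(records, embeddings, meta$model_fingerprint,
                    metadata = idx$metadata)
  if (!is.null(model)) {
    fp <- model_fingerprint(model)
    if (!identical(fp, db$model_fingerprint)) {
      warning("database was built with a different model (fingerprint ",
              substr(db$model_fingerprint, 1, 8), " != ",
              substr(fp, 1, 8), ")")
    }
  }
  db
}
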