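#' Chain and domain structure containers
#'
#' `chain_structure()` holds the C-alpha trace of one protein chain:
#' coordinates, one-letter sequence and author residue numbering.
#' `domain_structure()` holds a single (possibly discontinuous) domain cut
#' from a chain, together with its provenance: the parent chain id and its
#' 0-based position among that chain's domains (`order_in_chain`), which the
#' multi-domain search relies on.
#'
#' @param chain_id,domain_id identifier strings.
#' @param ca_coords numeric `L x 3` matrix of C-alpha coordinates (Angstrom).
#' @param sequence length-`L` one-letter amino-acid string (non-standard
#'   residues as `"X"`).
#' @param residue_numbers integer vector of author residue numbers,
#'   strictly increasing.
#' @param order_in_chain 0-based integer index of the domain along its chain.
#' @param residue_ranges list of `c(start, end)` 1-based inclusive author
#'   ranges, sorted and non-overlapping.
#' @return an object of class `"chain_structure"` or `"domain_structure"`.
#' @export
chain_structure <- function(chain_id, ca_coords, sequence, residue_numbers) {
  assert_coords(ca_coords, "ca_coords")
  L <- nrow(ca_coords)
  if (nchar(sequence) != L) {
    stop("sequence length must equal the number of coordinate rows")
  }
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != L) {
    stop("residue_numbers must have one entry per residue")
  }
  if (L > 1 && any(diff(residue_numbers) <= 0)) {
    warning("residue numbers are not strictly increasing in chain ", chain_id)
  }
  structure(
    list(chain_id = as.character(chain_id), ca_coords = ca_coords,
         sequence = sequence, residue_numbers = residue_numbers),
    class = "chain_structure"
  )
}

#' @rdname chain_structure
#' @export
domain_structure <- function(domain_id, chain_id, order_in_chain, ca_coords,
                             sequence, residue_ranges = NULL) {
  assert_coords(ca_coords, "ca_coords")
  L <- nrow(ca_coords)
  if (L < 5) stop("domain ", domain_id, " has fewer than 5 residues")
  if (nchar(sequence) != L) {
    stop("sequence length must equal the number of coordinate rows")
  }
  if (is.null(residue_ranges)) residue_ranges <- list(c(1L, L))
  starts <- vapply(residue_ranges, `[`, numeric(1), 1)
  ends   <- vapply(residue_ranges, `[`, numeric(1), 2)
  if (any(ends < starts)) stop("residue range with end < start")
  if (length(starts) > 1) {
    o <- order(starts)
    if (any(starts[o][-1] <= ends[o][-length(ends)])) {
      stop("residue ranges overlap")
    }
    residue_ranges <- residue_ranges[o]
  }
  structure(
    list(domain_id = as.character(domain_id),
         chain_id = as.character(chain_id),
         order_in_chain = as.integer(order_in_chain),
         ca_coords = ca_coords, sequence = sequence,
         residue_ranges = residue_ranges),
    class = "domain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s: %d residues (%d-%d)\n", x$chain_id,
              nrow(x$ca_coords), x$residue_numbers[1],
              x$residue_numbers[length(x$residue_numbers)]))
  invisible(x)
}

#' @export
print.domain_structure <- function(x, ...) {
  rng <- paste(vapply(x$residue_ranges,
                      function(r) paste0(r[1], "-", r[2]), ""),
               collapse = ",")
  cat(sprintf("<domain_structure> %s (chain %s, #%d): %d residues [%s]\n",
              x$domain_id, x$chain_id, x$order_in_chain,
              nrow(x$ca_coords), rng))
  invisible(x)
}

#' Number of residues in a structure
#' @param x a `chain_structure` or `domain_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(x) nrow(x$ca_coords)
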