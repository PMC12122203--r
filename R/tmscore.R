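#' Kabsch superposition
#'
#' Least-squares rigid superposition of `P` onto `Q` (rows correspond),
#' restricted to proper rotations: a reflection is never returned, so
#' mirror-image point sets retain a positive RMSD.
#'
#' @param P,Q numeric `N x 3` matrices with `N >= 3`; row `i` of `P`
#'   corresponds to row `i` of `Q`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3; the
#'   superposed coordinates are `P %*% rotation + translation`), `rmsd` and
#'   `degenerate` (`TRUE` when the point set is essentially collinear and
#'   the rotation is not unique).
#' @export
kabsch <- function(P, Q) {
  assert_coords(P, "P"); assert_coords(Q, "Q")
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of rows")
  if (nrow(P) < 3) stop("superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  scale <- max(sv$d[1], 1e-12)
  degenerate <- sv$d[2] / scale < 1e-8
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = drop(cq - cp %*% R), rmsd = rmsd,
       degenerate = degenerate)
}

#' TM-score distance scale and score
#'
#' `tm_d0()` is the standard length-dependent scale
#' `1.24 * (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom for short
#' normalization lengths (`L <= 21`). `tm_score()` evaluates
#' `(1/L_norm) * sum(1 / (1 + (d_i/d0)^2))` over aligned-pair distances; an
#' empty alignment scores 0.
#'
#' @param L_norm normalization length.
#' @param d numeric vector of aligned-pair distances (Angstrom).
#' @return a distance in Angstrom (`tm_d0`) or a score in `[0, 1]`
#'   (`tm_score`).
#' @export
tm_d0 <- function(L_norm) {
  if (L_norm < 16) return(0.5)
  max(0.5, 1.24 * (L_norm - 15)^(1 / 3) - 1.8)
}

#' @rdname tm_d0
#' @export
tm_score <- function(d, L_norm) {
  if (length(d) == 0) return(0)
  d0 <- tm_d0(L_norm)
  sum(1 / (1 + (d / d0)^2)) / L_norm
}

# Semi-global Needleman-Wunsch on a similarity matrix S (gap penalty per
# gapped column, free end gaps). Returns the matched index pairs.
nw_align <- function(S, gap = -0.6) {
  n <- nrow(S); m <- ncol(S)
  H <- matrix(0, n + 1, m + 1)
  Tb <- matrix(0L, n + 1, m + 1)    # 1 diag, 2 up (gap in B), 3 left
  for (i in seq_len(n)) {
    Hi1 <- H[i, ]
    Hi <- H[i + 1, ]
    Ti <- Tb[i + 1, ]
    for (j in seq_len(m)) {
      diag <- Hi1[j] + S[i, j]
      up <- Hi1[j + 1] + if (j == m) 0 else gap
      left <- Hi[j] + if (i == n) 0 else gap
      if (diag >= up && diag >= left) {
        Hi[j + 1] <- diag; Ti[j + 1] <- 1L
      } else if (up >= left) {
        Hi[j + 1] <- up; Ti[j + 1] <- 2L
      } else {
        Hi[j + 1] <- left; Ti[j + 1] <- 3L
      }
    }
    H[i + 1, ] <- Hi
    Tb[i + 1, ] <- Ti
  }
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    t <- Tb[i + 1, j + 1]
    if (t == 1L) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (t == 2L) {
      i <- i - 1
    } else if (t == 3L) {
      j <- j - 1
    } else {
      if (i >= j) i <- i - 1 else j <- j - 1
    }
  }
  cbind(pi, pj, deparse.level = 0)
}

#' Sequence-independent structural alignment with TM-scores
#'
#' A simplified TM-align-style aligner: gapless seed threadings at several
#' offsets are each refined by iterating (superpose on the currently
#' aligned residue pairs, rebuild the alignment by dynamic programming on
#' the TM-score similarity matrix `1 / (1 + d^2/d0^2)`) until the aligned
#' set is stable or `max_iter` rounds. The best alignment over all seeds is
#' scored under both chain-length normalizations. The DP scale `d0` uses
#' the shorter chain, making the procedure symmetric in its inputs.
#'
#' An external TM-align binary can be substituted via `external`, a
#' function `(A, B) -> list(tm_query=, tm_target=)`; the internal aligner
#' is used whenever it is `NULL`.
#'
#' @param A,B [domain_structure()]s (or any object with `ca_coords`), both
#'   with at least 5 residues.
#' @param gap DP gap penalty per gapped column.
#' @param max_iter refinement iterations per seed.
#' @param n_seeds number of gapless seed offsets.
#' @param external optional external-aligner adapter (see above).
#' @return object of class `"fc_alignment"`: `pairs` (m x 2, strictly
#'   increasing in both columns), `rotation`, `translation`, `tm_query`
#'   (normalized by `length(A)`), `tm_target` (by `length(B)`),
#'   `rmsd_aligned`, `n_aligned`.
#' @export
align_structures <- function(A, B, gap = -0.6, max_iter = 20, n_seeds = 7,
                             external = NULL) {
  a <- A$ca_coords; b <- B$ca_coords
  la <- nrow(a); lb <- nrow(b)
  if (la < 5 || lb < 5) stop("alignment needs at least 5 residues per input")
  if (!is.null(external)) return(external(A, B))
  d0s <- tm_d0(min(la, lb))
  minov <- min(5, la, lb)
  offs <- unique(round(seq(-(lb - minov), la - minov,
                           length.out = max(3, n_seeds))))
  offs <- unique(c(0L, offs))
  best <- NULL
  for (off in offs) {
    i0 <- max(1, 1 + off); i1 <- min(la, lb + off)
    if (i1 - i0 + 1 < 3) next
    pairs <- cbind(i0:i1, (i0:i1) - off)
    seen <- character(0)
    for (it in seq_len(max_iter)) {
      if (nrow(pairs) < 3) break
      kb <- kabsch(a[pairs[, 1], , drop = FALSE],
                   b[pairs[, 2], , drop = FALSE])
      am <- apply_rigid(a, kb$rotation, kb$translation)
      Dsq <- outer(rowSums(am^2), rowSums(b^2), "+") - 2 * tcrossprod(am, b)
      Dsq[Dsq < 0] <- 0
      S <- 1 / (1 + Dsq / d0s^2)
      sc <- sum(S[pairs]) / min(la, lb)
      key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, pairs = pairs, kb = kb, Dsq = Dsq)
      }
      if (key %in% seen) break
      seen <- c(seen, key)
      pairs <- nw_align(S, gap = gap)
    }
  }
  if (is.null(best)) stop("no seed alignment possible (degenerate inputs)")
  pairs <- best$pairs
  kb <- kabsch(a[pairs[, 1], , drop = FALSE], b[pairs[, 2], , drop = FALSE])
  am <- apply_rigid(a[pairs[, 1], , drop = FALSE], kb$rotation,
                    kb$translation)
  d <- sqrt(rowSums((am - b[pairs[, 2], , drop = FALSE])^2))
  structure(
    list(pairs = pairs, rotation = kb$rotation, translation = kb$translation,
         tm_query = tm_score(d, la), tm_target = tm_score(d, lb),
         rmsd_aligned = kb$rmsd, n_aligned = nrow(pairs)),
    class = "fc_alignment")
}

#' @export
print.fc_alignment <- function(x, ...) {
  cat(sprintf(paste0("<fc_alignment> %d pairs, TM (query) %.3f, ",
                     "TM (target) %.3f, RMSD %.2f A\n"),
              x$n_aligned, x$tm_query, x$tm_target, x$rmsd_aligned))
  invisible(x)
}
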