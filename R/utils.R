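# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded fixture generation does
#' not perturb the caller's random stream.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Row-wise L2 normalization; zero rows are left untouched (with a warning
# upstream where that matters).
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Uniform random rotation matrix (quaternion method), det +1.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Apply a rigid motion to an L x 3 coordinate matrix (row-vector convention).
apply_rigid <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(coords %*% rotation, 2, translation, "+")
}

assert_coords <- function(x, name = "coords") {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric L x 3 matrix", name))
  }
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", name))
  invisible(x)
}

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

random_sequence <- function(n) paste(sample(AA1, n, replace = TRUE), collapse = "")
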