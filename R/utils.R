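# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All generators route their randomness through
# this so no function touches global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-unit sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 10007 + as.double(index) * 97 + 1) %% 2147483647)
}

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

# Coerce an image stack (S x S x n array, single matrix, or list of matrices)
# into an n x (S*S) matrix of vectorised images (column-major pixel order).
as_image_matrix <- function(images, image_size) {
  if (is.list(images)) images <- simplify2array(images)
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("images must be an S x S x n array, a matrix, or a list of matrices",
         call. = FALSE)
  d <- dim(images)
  if (d[1] != image_size || d[2] != image_size)
    stop(sprintf("images are %dx%d but the pyramid expects %dx%d",
                 d[1], d[2], image_size, image_size), call. = FALSE)
  if (!all(is.finite(images)))
    stop("images contain non-finite pixel values", call. = FALSE)
  m <- t(matrix(images, nrow = d[1] * d[2], ncol = d[3]))
  rownames(m) <- dimnames(images)[[3]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
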