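#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))  # keep derived seeds in 32-bit range
  expr
}

#' Derive child seeds from a master seed
#'
#' Deterministic fan-out of one master seed into `n` independent seeds,
#' all below 2^31, used so that every stochastic stage of the pipeline is
#' reproducible from a single integer.
#'
#' @param seed Master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Population standard deviation across the rows (channels) of each column.
# This is the global field power of one sample when the input is an
# average-referenced channels x samples matrix.
col_pop_sd <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, mu)^2))
}

# Center a matrix of maps (rows) and scale each row to unit L2 norm.
# Rows with zero norm raise an error: an all-zero topography carries no
# spatial information and cannot be normalized.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < .Machine$double.eps * 100)) {
    stop("all-zero (or constant) topography cannot be normalized", call. = FALSE)
  }
  maps / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
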