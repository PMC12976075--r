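# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state afterwards. All randomised operations in the package go through
#' this, so results are reproducible and composable.
#'
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive independent sub-seeds from a master seed
#'
#' @param seed Master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopifnot_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  }
  invisible(TRUE)
}

# Quantise real values to 8-bit integers with the round-half-to-even
# tie-breaking rule (base round()), clipping to [0, 255].
quantise_u8 <- function(x) {
  pmin(pmax(round(x), 0), 255)
}

# Map a [H,W] or [H,W,C] array of 0..255 values to png-writable [0,1].
u8_to_unit <- function(x) x / 255

unit_to_u8 <- function(x) quantise_u8(x * 255)

as_hw_matrix <- function(x, what = "image") {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 1) {
    return(array(x, dim(x)[1:2]))
  }
  stop(sprintf("%s must be a single-channel matrix", what), call. = FALSE)
}
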