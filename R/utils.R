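#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state afterwards,
#' so library functions never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' A single master seed reproduces an entire run: every stage draws its own
#' seed deterministically from the master seed and a stage tag, keeping the
#' result strictly below 2^31.
#'
#' @param master Integer master seed.
#' @param tag Character stage label.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(as.double(utf8ToInt(tag)) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((abs(master) %% 2147483646 * 48271 + h) %% 2147483646 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
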