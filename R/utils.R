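#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Derive a stage seed from a global seed
#'
#' One global seed determines every stage seed through a fixed affine map,
#' kept below 2^31 so the result is a valid R integer.
#'
#' @param global_seed integer global seed.
#' @param stage stage name, one of the pipeline stage labels.
#' @return integer seed for the stage.
#' @export
derive_seed <- function(global_seed, stage) {
  offsets <- c(simulate = 1L, segment = 2L, fuse = 3L, survival = 4L,
               ewc = 5L, bayesopt = 6L, explain = 7L, split = 8L, cv = 9L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(global_seed) * 31L + offsets[[stage]]) %% 2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  invisible(x)
}

## Collect validation failures and raise them together, naming each field.
validate_fields <- function(checks) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad))
    stop("invalid configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

logit <- function(p) log(p) - log1p(-p)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

## Row-wise softmax for a matrix of logits.
softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1L, max))
  z / rowSums(z)
}
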