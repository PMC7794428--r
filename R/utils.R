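#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls are reproducible
#' without disturbing the caller's RNG stream.
#'
#' @param seed integer seed, or NA to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Euclidean norm of rows of a two-column matrix
#' @keywords internal
row_norm <- function(m) sqrt(m[, 1]^2 + m[, 2]^2)

#' Empty detections table (canonical column layout)
#' @keywords internal
empty_detections <- function() {
  data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
             area_um2 = numeric(0), intensity = numeric(0))
}
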