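#' @keywords internal
"_PACKAGE"

# Canonical group labels: two parents and the hybrid.
GROUPS <- c("MH", "MA", "F4")

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the session stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stopf("'%s' must be in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0)
    stopf("'%s' must be a %s integer", name,
          if (positive) "positive" else "non-negative")
  invisible(as.integer(x))
}

check_group <- function(group) {
  if (!all(group %in% GROUPS))
    stopf("group labels must be in {%s}", paste(GROUPS, collapse = ", "))
  invisible(group)
}
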