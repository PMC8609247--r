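#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (e.g. the k-means
#' trajectory partition) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(structure(class = c("embedsep_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input(what, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) stop_input(what, " contains non-finite values")
  invisible(x)
}

# Shortest-round-trip style serialization: 17 significant digits preserve
# doubles exactly on re-parse.
format_coord <- function(x) sprintf("%.17g", x)
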