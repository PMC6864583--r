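#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor kmeans pf plogis predict runif sd setNames
#'   uniroot var
#' @importFrom utils head read.csv write.csv
NULL

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Structured error helper: all package errors carry class "mtqsar_error"
# plus a specific subclass so callers can test for them.
mtq_stop <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "mtqsar_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locate the obabel executable once per session.
obabel_path <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      p <- Sys.which("obabel")
      if (!nzchar(p)) {
        mtq_stop("mtqsar_missing_tool", "OpenBabel ('obabel') not found on PATH")
      }
      cached <<- unname(p)
    }
    cached
  }
})

run_obabel <- function(args) {
  out <- suppressWarnings(system2(obabel_path(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  list(output = out, status = status)
}
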