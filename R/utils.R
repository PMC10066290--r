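#' @keywords internal
"_PACKAGE"

## Labelled error helper: every contract violation in the package raises a
## condition whose class carries the module and error kind, so callers (and
## tests) can distinguish contract errors from incidental failures.
fm_stop <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("fangmark_", kind), "fangmark_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fm_assert <- function(cond, kind, msg, ...) {
  if (!isTRUE(cond)) fm_stop(kind, msg, ...)
  invisible(TRUE)
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream (generator functions take explicit seeds; the global stream
## must stay untouched so pipelines remain replayable stage by stage).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' One global seed deterministically yields an independent seed for each named
#' pipeline stage (hash of stage name folded with the global seed), so any
#' stochastic stage can be replayed in isolation.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "synth")
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ## fold multiplicatively mod a prime below 2^31 to decorrelate stages
  as.integer((as.numeric(global_seed) * 2654435761 + h * 40503) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
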