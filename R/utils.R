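# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is restored on exit).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_invalid <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Processing presets
#'
#' Named parameter sets mirroring the two benchmark acquisition settings:
#' `"ecgid-like"` (500 Hz sampling, 256-sample beat windows) and
#' `"ptb-like"` (1000 Hz sampling, 200-sample beat windows).
#'
#' @param name Preset name, `"ecgid-like"` or `"ptb-like"`.
#' @return A list with elements `name`, `fs` (Hz) and `L` (window length in
#'   samples).
#' @export
ecg_preset <- function(name = c("ecgid-like", "ptb-like")) {
  name <- match.arg(name)
  switch(name,
    "ecgid-like" = list(name = name, fs = 500,  L = 256L),
    "ptb-like"   = list(name = name, fs = 1000, L = 200L)
  )
}
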