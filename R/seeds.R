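# Seed handling: every randomized operation takes an explicit seed, set
# locally so package calls never disturb the caller's RNG stream.

local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv))
  } else {
    bquote(assign(".Random.seed", .(old), envir = .GlobalEnv))
  }
  do.call("on.exit", list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(seed)
}

#' Derive a per-stage seed from a master seed
#'
#' One master seed fans out to independent per-stage seeds by a stable
#' polynomial hash of the stage name, so each pipeline stage is
#' reproducible on its own while the end-to-end run stays a pure function
#' of the master seed.
#'
#' @param master integer master seed.
#' @param stage stage name, e.g. `"simulate"` or `"simulate:img02"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stage_seed(1, "simulate")
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L)
  m <- 2147483629  # largest prime < 2^31; keeps arithmetic exact in doubles
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% m
  as.integer((abs(master) %% m * 48271 + h) %% m)
}
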