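#' Derive a reproducible sub-seed for a named random stream
#'
#' All generators in the package draw from streams derived from one master
#' seed, so that e.g. reference construction and read simulation stay
#' reproducible independently of how many draws each consumes.
#'
#' @param seed master integer seed.
#' @param tag character stream label.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483629 # prime below 2^31
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  s <- ((abs(seed) %% m) * 48271 + h + 1) %% m
  as.integer(s + 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
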