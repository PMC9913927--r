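#' Derive a reproducible sub-stream seed
#'
#' Stable integer hash of a global seed plus a stage label, so that every
#' stage/repeat of a study draws from its own reproducible stream.  The hash
#' is a djb2-style accumulation modulo 2^31 - 1, implemented in double
#' arithmetic so it is exact and platform independent.
#'
#' @param seed integer global seed.
#' @param ... label components (stage name, repeat index, ...), coerced to
#'   character and joined with "/".
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(7, "INIT", 1)
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)),
                 collapse = "/")
  h <- as.double(as.integer(seed)) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}
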