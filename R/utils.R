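#' Derive a reproducible child seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (subset ids, replicate numbers, GCM codes, ...) into a 32-bit integer
#' seed. Adding new labels to a run never perturbs seeds derived for other
#' label combinations, so e.g. adding variable subsets leaves existing
#' replicate splits untouched.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character, "")),
             collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
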