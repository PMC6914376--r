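#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnbinom rnorm runif setNames
#' @importFrom utils read.table write.table head tail
NULL

stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "nbsval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# key uniquely identifying a biallelic variant (allele-level matching)
variant_key <- function(v) {
  paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
}
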