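`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Natural (mixed numeric-aware) sort
#'
#' Orders character strings so that embedded integers compare numerically:
#' `run_2` sorts before `run_10`. Used when ingesting scenario output files
#' whose names carry run numbers.
#'
#' @param x character vector.
#' @return `x` in natural order.
#' @examples
#' mixed_sort(c("run_10", "run_2", "run_1"))
#' @export
mixed_sort <- function(x) {
  x[mixed_order(x)]
}

#' @rdname mixed_sort
#' @return for `mixed_order`, the ordering permutation.
#' @export
mixed_order <- function(x) {
  # pad every digit run to fixed width so lexicographic order is numeric order
  keys <- vapply(as.character(x), function(s) {
    m <- gregexpr("[0-9]+", s)[[1]]
    if (m[1] == -1L) return(s)
    parts <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    padded <- sprintf("%020d", as.numeric(parts))
    out <- s
    for (i in rev(seq_along(parts))) {
      start <- m[i]
      stop <- m[i] + attr(m, "match.length")[i] - 1L
      out <- paste0(substr(out, 1L, start - 1L), padded[i],
                    substring(out, stop + 1L))
    }
    out
  }, character(1), USE.NAMES = FALSE)
  order(keys, x)
}

stop_fl <- function(...) stop(sprintf(...), call. = FALSE)
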