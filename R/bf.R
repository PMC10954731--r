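#' Boolean functions as truth-table output vectors
#'
#' A \code{boolfn} stores a k-input Boolean function as the output column of
#' its truth table.  Row index \code{r} (0-based) encodes the input assignment
#' whose bits, read most-significant-first, are \code{(x_1, ..., x_k)}; so row
#' 0 is the all-zero assignment and row \code{2^k - 1} is all-ones.  The bias
#' \code{P} of a function is the number of 1s in the output vector: the number
#' of regulator configurations that switch the target gene on.
#'
#' @param outputs output column, either a 0/1 vector of length \code{2^k} or a
#'   bit string such as \code{"0001"} (row 0 first).
#' @param k number of inputs; inferred from \code{length(outputs)} when
#'   missing.  \code{k = 0} (a constant with no inputs) is representable so
#'   that network files with frozen nodes can be handled, but constants are
#'   rejected by all classification operations.
#' @return an object of class \code{boolfn} with fields \code{k},
#'   \code{outputs} (integer 0/1) and \code{bias}.
#' @examples
#' boolfn("0001")        # two-input AND, bias 1
#' boolfn(c(0, 1, 1, 0)) # XOR
#' @export
boolfn <- function(outputs, k = NULL) {
  if (is.character(outputs)) {
    stopifnot(length(outputs) == 1L, grepl("^[01]+$", outputs))
    outputs <- as.integer(strsplit(outputs, "")[[1]])
  }
  outputs <- as.integer(outputs)
  if (any(is.na(outputs)) || any(outputs < 0L | outputs > 1L))
    stop("outputs must be a 0/1 vector or bit string")
  n <- length(outputs)
  k_inferred <- as.integer(round(log2(n)))
  if (2^k_inferred != n)
    stop("length(outputs) must be a power of two, got ", n)
  if (is.null(k)) k <- k_inferred
  if (k != k_inferred)
    stop("k = ", k, " inconsistent with ", n, " output rows")
  if (k > 20L) stop("truth-table representation capped at k = 20 inputs")
  structure(list(k = as.integer(k), outputs = outputs,
                 bias = sum(outputs)),
            class = "boolfn")
}

#' @export
print.boolfn <- function(x, ...) {
  cat(sprintf("Boolean function: k = %d, bias = %d\n", x$k, x$bias))
  if (x$k <= 6)
    cat("outputs:", paste(x$outputs, collapse = ""), "\n")
  invisible(x)
}

#' @export
format.boolfn <- function(x, ...) paste(x$outputs, collapse = "")

bf_key <- function(f) paste(f$outputs, collapse = "")

#' @rdname boolfn
#' @param f a \code{boolfn}.
#' @export
is_boolfn <- function(f) inherits(f, "boolfn")

.check_bf <- function(f) {
  if (!is_boolfn(f)) stop("expected a boolfn object")
  invisible(f)
}

#' Bias (number of 1-outputs) of a Boolean function
#'
#' @param f a \code{boolfn}.
#' @return integer count of 1s in the output vector.
#' @export
bf_bias <- function(f) {
  .check_bf(f)
  sum(f$outputs)
}

# value of input i (1-based, x_1 most significant) across all rows of a
# k-input truth table, as an integer 0/1 vector of length 2^k (memoized:
# the constructive enumerators call this in tight loops)
.input_col_cache <- new.env(parent = emptyenv())
.input_column <- function(k, i) {
  key <- paste0(k, ".", i)
  col <- .input_col_cache[[key]]
  if (is.null(col)) {
    r <- 0:(2^k - 1)
    col <- (r %/% 2^(k - i)) %% 2L
    .input_col_cache[[key]] <- col
  }
  col
}

#' Evaluate a function on one input assignment
#'
#' @param f a \code{boolfn}.
#' @param x 0/1 vector of length \code{k}, ordered \code{x_1, ..., x_k}.
#' @return 0 or 1.
#' @export
bf_eval <- function(f, x) {
  .check_bf(f)
  stopifnot(length(x) == f$k, all(x %in% c(0L, 1L)))
  r <- sum(x * 2^((f$k - 1):0))
  f$outputs[r + 1L]
}
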