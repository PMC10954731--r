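# Elementary operations on truth tables: input negation, permutation,
# complementation, restriction, essentiality and unateness.  Negation
# and permutation preserve the bias P; complementation maps P to
# 2^k - P.

#' Negate a subset of inputs
#'
#' @param f a \code{\link{boolfn}}.
#' @param which integer vector of input indices to negate (may be empty).
#' @return a \code{boolfn} with the same bias.
#' @export
bf_negate <- function(f, which) {
  .check_bf(f)
  which <- as.integer(which)
  if (length(which) > 0L &&
      (any(which < 1L) || any(which > f$k) || anyDuplicated(which)))
    stop("negate indices must be distinct values in 1..k")
  if (length(which) == 0L) return(f)
  mask <- sum(2^(f$k - which))
  r <- 0:(2^f$k - 1)
  boolfn(f$outputs[bitwXor(r, mask) + 1L], f$k)
}

#' Permute the inputs of a function
#'
#' The result \code{g} satisfies \code{g(x_1, ..., x_k) =
#' f(x_perm[1], ..., x_perm[k])}: input slot \code{i} of \code{f} reads the
#' value of variable \code{perm[i]}.  Swapping two variables in a Boolean
#' expression corresponds to the transposition permutation.
#'
#' @param f a \code{\link{boolfn}}.
#' @param perm a permutation of \code{1:k}.
#' @return a \code{boolfn} with the same bias.
#' @export
bf_permute <- function(f, perm) {
  .check_bf(f)
  perm <- as.integer(perm)
  if (length(perm) != f$k || anyDuplicated(perm) ||
      any(perm < 1L) || any(perm > f$k))
    stop("perm must be a bijection on 1..k")
  k <- f$k
  r <- 0:(2^k - 1)
  src <- integer(2^k)
  for (i in seq_len(k)) {
    bit <- (r %/% 2^(k - perm[i])) %% 2L
    src <- src + bit * 2^(k - i)
  }
  boolfn(f$outputs[src + 1L], k)
}

#' Complement a function
#'
#' Flips every output bit; equivalently, negates all variables and swaps AND
#' with OR in the expression.  Maps bias \code{P} to \code{2^k - P}.
#'
#' @param f a \code{\link{boolfn}}.
#' @export
bf_complement <- function(f) {
  .check_bf(f)
  boolfn(1L - f$outputs, f$k)
}

#' Apply an input transform
#'
#' Dispatcher over the three elementary operations.
#'
#' @param f a \code{\link{boolfn}}.
#' @param mode one of \code{"negate"}, \code{"permute"}, \code{"complement"}.
#' @param negate_set inputs to negate (negate mode).
#' @param permutation bijection on \code{1:k} (permute mode).
#' @export
bf_transform <- function(f, mode = c("negate", "permute", "complement"),
                         negate_set = integer(0), permutation = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         negate = bf_negate(f, negate_set),
         permute = bf_permute(f, permutation),
         complement = bf_complement(f))
}

#' Restrict an input to a fixed value
#'
#' Returns the half-table obtained by setting input \code{i} to \code{v}; the
#' remaining inputs keep their relative order.  Restricting the only input of
#' a 1-input function yields a 0-input constant.
#'
#' @param f a \code{\link{boolfn}} with \code{k >= 1}.
#' @param i input index in \code{1..k}.
#' @param v fixed bit, 0 or 1.
#' @return a \code{boolfn} with \code{k - 1} inputs.
#' @export
bf_restrict <- function(f, i, v) {
  .check_bf(f)
  if (f$k < 1L) stop("cannot restrict a 0-input constant")
  if (i < 1L || i > f$k) stop("input index out of range: ", i)
  stopifnot(v %in% c(0L, 1L))
  boolfn(f$outputs[.restrict_rows(f$k, i, v)], f$k - 1L)
}

# row indices (1-based) of the half-table with x_i = v, memoized
.restrict_cache <- new.env(parent = emptyenv())
.restrict_rows <- function(k, i, v) {
  key <- paste0(k, ".", i, ".", v)
  rows <- .restrict_cache[[key]]
  if (is.null(rows)) {
    r <- 0:(2^k - 1)
    rows <- which((r %/% 2^(k - i)) %% 2L == v)
    .restrict_cache[[key]] <- rows
  }
  rows
}

# fast path used by the classifiers: outputs vector in, vector out
.restrict_outputs <- function(out, k, i, v) out[.restrict_rows(k, i, v)]

#' Essential inputs of a function
#'
#' Input \code{i} is essential when the two half-tables at \code{x_i = 0} and
#' \code{x_i = 1} differ; otherwise it is a dummy.  NCF classification
#' requires all inputs to be essential.
#'
#' @param f a \code{\link{boolfn}}.
#' @return integer vector of essential input indices (possibly empty).
#' @export
essential_inputs <- function(f) {
  .check_bf(f)
  if (f$k == 0L) return(integer(0))
  ess <- vapply(seq_len(f$k), function(i) {
    !identical(.restrict_outputs(f$outputs, f$k, i, 0L),
               .restrict_outputs(f$outputs, f$k, i, 1L))
  }, logical(1))
  which(ess)
}

#' Unate direction of each input
#'
#' An input is positive (activating) when the output is non-decreasing in it
#' over all contexts of the other inputs, negative (inhibiting) when
#' non-increasing, dummy when both, and non-unate otherwise.  For NCFs the
#' unate direction coincides with the literal sign in the nested expression,
#' which is what makes sign-conformity checks on truth tables equivalent to
#' sign rules on expressions.
#'
#' @param f a \code{\link{boolfn}}.
#' @return character vector of length \code{k} over
#'   \code{c("positive", "negative", "non-unate", "dummy")}.
#' @export
unate_directions <- function(f) {
  .check_bf(f)
  vapply(seq_len(f$k), function(i) {
    lo <- .restrict_outputs(f$outputs, f$k, i, 0L)
    hi <- .restrict_outputs(f$outputs, f$k, i, 1L)
    up <- all(hi >= lo)
    down <- all(hi <= lo)
    if (up && down) "dummy"
    else if (up) "positive"
    else if (down) "negative"
    else "non-unate"
  }, character(1))
}
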