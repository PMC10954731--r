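# Exact counting of NCFs and chain functions.
#
# Per-bias counts follow the multinomial formulas
#   |NCF|_{k,P}  = 2^k k! / (m_1! ... m_last!)
#   |ChF0|_{k,P} = k! (1 + m_last) / (m_1! ... m_last!)
# with the layer sizes m_i determined by (k, P).  Totals over odd P
# are computed without iterating over the 2^{k-1} odd biases: odd
# biases correspond two-to-one to compositions of k whose last part is
# >= 2 (the operator string may start with AND or OR), so with
#   A(k) = sum over such compositions of the multinomial coefficient
#   W(k) = same sum weighted by (1 + m_last)
# one has |NCF|_k = 2^{k+1} A(k), |ChF0|_k = 2 W(k), and the constant
# C(k) = 2^k |ChF0|_k / |NCF|_k = W(k) / A(k).  A and W satisfy the
# head-part recursion
#   A(j) = sum_{m=1}^{j-2} C(j,m) A(j-m) + 1          (j >= 2)
#   W(j) = sum_{m=1}^{j-2} C(j,m) W(j-m) + (1 + j)
# seeded by the single-layer composition (j).  All arithmetic is exact
# (internal big integers); doubles appear only at presentation.

.count_cache <- new.env(parent = emptyenv())

# big-integer binomial table rows 0..n (Pascal), cached
.big_binomials <- function(n) {
  key <- paste0("binom.", n)
  tab <- .count_cache[[key]]
  if (!is.null(tab)) return(tab)
  tab <- vector("list", n + 1L)
  tab[[1L]] <- list(big(1))
  if (n >= 1L) {
    for (j in 1:n) {
      row <- vector("list", j + 1L)
      prev <- tab[[j]]
      row[[1L]] <- big(1)
      row[[j + 1L]] <- big(1)
      if (j >= 2L) for (m in 2:j)
        row[[m]] <- big_add(prev[[m - 1L]], prev[[m]])
      tab[[j + 1L]] <- row
    }
  }
  .count_cache[[key]] <- tab
  tab
}

.big_binom <- function(n, m) .big_binomials(n)[[n + 1L]][[m + 1L]]

# multinomial coefficient k! / prod(parts!) as a big integer
.big_multinomial <- function(k, parts) {
  out <- big(1)
  r <- k
  for (m in parts) {
    out <- big_mul(out, .big_binom(r, m))
    r <- r - m
  }
  out
}

# A(j), W(j) for j = 2..k (lists of bigint), cached per max k
.comp_dp <- function(k) {
  stopifnot(k >= 2L)
  key <- paste0("dp.", k)
  got <- .count_cache[[key]]
  if (!is.null(got)) return(got)
  A <- vector("list", k)
  W <- vector("list", k)
  for (j in 2:k) {
    a <- big(1)            # single-layer composition (j)
    w <- big(1 + j)
    if (j >= 3L) {
      for (m in 1:(j - 2L)) {
        cb <- .big_binom(j, m)
        a <- big_add(a, big_mul(cb, A[[j - m]]))
        w <- big_add(w, big_mul(cb, W[[j - m]]))
      }
    }
    A[[j]] <- a
    W[[j]] <- w
  }
  out <- list(A = A, W = W)
  .count_cache[[key]] <- out
  out
}

.count_result <- function(k, P, class, count) {
  structure(list(k = as.integer(k), P = P, class = class, count = count),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("|%s| k = %d%s: %s\n", x$class, x$k,
              if (is.null(x$P)) " (total over odd P)" else paste0(", P = ", x$P),
              big_to_string(x$count)))
  invisible(x)
}

#' @export
as.character.count_result <- function(x, ...) big_to_string(x$count)

#' @export
as.double.count_result <- function(x, ...) big_to_double(x$count)

#' Count nested canalyzing functions
#'
#' With a bias, applies the multinomial formula
#' \code{2^k k! / prod(m_i!)}; without one, sums over all odd biases via the
#' layer-composition recursion (equivalently, doubles the sum over odd
#' \code{P < 2^(k-1)}, by complement symmetry).
#'
#' @param k number of inputs (\code{k <= 50} when \code{P} is given,
#'   \code{k <= 200} otherwise).
#' @param P optional odd bias.
#' @return a \code{count_result}; the exact count is in \code{$count} (big
#'   integer), convertible with \code{as.character} / \code{as.numeric}.
#' @examples
#' count_ncf(4, 5)   # 192
#' count_ncf(4)      # 736
#' @export
count_ncf <- function(k, P = NULL) {
  stopifnot(k >= 1L)
  if (!is.null(P)) {
    ls <- layers_from_bias(k, P)
    cnt <- big_mul(big_pow2(k), .big_multinomial(k, ls$layer_sizes))
    return(.count_result(k, P, "NCF", cnt))
  }
  stopifnot(k <= 200L)
  if (k == 1L) return(.count_result(1L, NULL, "NCF", big(2)))
  dp <- .comp_dp(k)
  .count_result(k, NULL, "NCF", big_mul(big_pow2(k + 1L), dp$A[[k]]))
}

#' Count chain functions
#'
#' Chain-0 and chain-1 classes have equal cardinality for every \code{(k,P)}
#' (negating all variables maps one onto the other bijectively).  The
#' generalized class \code{CHFU} is their disjoint union for \code{k >= 3};
#' for \code{k <= 2} every NCF is a generalized chain function, so the CHFU
#' count equals the NCF count.
#'
#' @param k number of inputs.
#' @param P optional odd bias.
#' @param class \code{"CHF0"}, \code{"CHF1"} or \code{"CHFU"}.
#' @return a \code{count_result}.
#' @examples
#' count_chain(6, 7, "CHF0")  # 80
#' count_chain(3, class = "CHFU")  # 52
#' @export
count_chain <- function(k, P = NULL, class = c("CHF0", "CHF1", "CHFU")) {
  class <- match.arg(class)
  stopifnot(k >= 1L)
  if (k == 1L) {
    cnt <- big(2)  # {x, !x}; the summation formulas presume k >= 2
    return(.count_result(1L, P, class, cnt))
  }
  if (!is.null(P)) {
    ls <- layers_from_bias(k, P)
    per <- big_mul_small(.big_multinomial(k, ls$layer_sizes), 1 + ls$m_last)
    if (class == "CHFU") {
      per <- if (k <= 2L) {
        m <- big_mul(big_pow2(k), .big_multinomial(k, ls$layer_sizes))
        m
      } else big_mul_small(per, 2)
    }
    return(.count_result(k, P, class, per))
  }
  stopifnot(k <= 200L)
  if (class == "CHFU" && k == 2L)
    return(.count_result(2L, NULL, "CHFU", count_ncf(2L)$count))
  dp <- .comp_dp(k)
  tot <- big_mul_small(dp$W[[k]], 2)
  if (class == "CHFU") tot <- big_mul_small(tot, 2)
  .count_result(k, NULL, class, tot)
}

#' Fraction of chain-0 (or chain-1) functions among NCFs at a given bias
#'
#' The ratio \code{|ChF0|_{k,P} / |NCF|_{k,P}} collapses to the closed form
#' \code{(1 + m_last) / 2^k}: it depends on the bias only through the size of
#' the last layer.
#'
#' @param k number of inputs.
#' @param P odd bias.
#' @return list with exact \code{numerator}, \code{denominator} and the
#'   floating \code{value}.
#' @examples
#' fraction_chain_in_ncf(3, 1)  # (1+3)/8 = 1/2
#' @export
fraction_chain_in_ncf <- function(k, P) {
  ls <- layers_from_bias(k, P)
  list(k = as.integer(k), P = P,
       numerator = 1L + ls$m_last,
       denominator = 2^k,
       value = (1 + ls$m_last) / 2^k)
}

#' The constant C relating the chain fraction of NCFs to 1/2^k
#'
#' The chain-0 share of NCFs factorizes as \code{|ChF0|_k / |NCF|_k =
#' C(k) / 2^k} with \code{C(k)} a ratio of two composition sums that is
#' bounded by \code{3 <= C(k) <= k + 1} and converges rapidly in \code{k}.
#' Computed with exact big-integer arithmetic via the composition dynamic
#' programme (never by iterating over the \code{2^(k-1)} odd biases).
#'
#' @param k number of inputs, \code{2 <= k <= 200}.
#' @param digits decimal digits rendered after the point.
#' @return list with big-integer \code{numerator} and \code{denominator} of
#'   the exact rational, the decimal rendering \code{value_str}, and the
#'   double \code{value}.
#' @examples
#' chain_fraction_constant(2)$value   # 3
#' chain_fraction_constant(3)$value   # 3.25
#' @export
chain_fraction_constant <- function(k, digits = 20L) {
  stopifnot(k >= 2L, k <= 200L)
  dp <- .comp_dp(k)
  num <- dp$W[[k]]
  den <- dp$A[[k]]
  str <- big_ratio_decimal(num, den, digits = digits)
  list(k = as.integer(k), numerator = num, denominator = den,
       value_str = str, value = as.numeric(str))
}

# double-precision ratio |class|_k / |NCF|_k, any k <= 200
chain_ncf_ratio <- function(k, class = c("CHF0", "CHF1", "CHFU")) {
  class <- match.arg(class)
  if (k <= 2L) return(1)   # every NCF is a generalized chain function
  C <- chain_fraction_constant(k)$value
  if (class == "CHFU") 2 * C / 2^k else C / 2^k
}

# ---- exhaustive enumeration (the brute-force oracle generator) -----------

# all ways to assign 1..k to layers with the given sizes (order within a
# layer irrelevant); returns list of lists of integer vectors
.layer_assignments <- function(k, sizes) {
  rec <- function(remaining, sizes) {
    if (length(sizes) == 0L) return(list(list()))
    m <- sizes[1L]
    out <- list()
    sel <- utils::combn(length(remaining), m, simplify = FALSE)
    for (idx in sel) {
      head_set <- remaining[idx]
      for (tail in rec(remaining[-idx], sizes[-1L]))
        out[[length(out) + 1L]] <- c(list(head_set), tail)
    }
    out
  }
  rec(seq_len(k), sizes)
}

#' Enumerate every member of a function class
#'
#' Materializes the full, deduplicated list of k-input functions in a class.
#' Used as the enumeration oracle against the closed-form counts and as the
#' sampling pool for the synthetic-data generators.  Capacity-limited:
#' enumerating NCFs beyond \code{k = 8} (or chains beyond \code{k = 10})
#' is refused.
#'
#' @param k number of inputs.
#' @param class \code{"NCF"}, \code{"CHF0"}, \code{"CHF1"} or \code{"CHFU"}.
#' @return list of \code{\link{boolfn}} objects.
#' @export
enumerate_class <- function(k, class = c("NCF", "CHF0", "CHF1", "CHFU")) {
  class <- match.arg(class)
  stopifnot(k >= 1L)
  cap <- if (class == "NCF") 8L else 10L
  if (k > cap)
    stop("enumeration of ", class, " is capped at k = ", cap,
         "; use the counting formulas instead")
  if (k == 1L) return(list(boolfn(c(0L, 1L)), boolfn(c(1L, 0L))))
  if (class == "CHFU") {
    pool <- c(enumerate_class(k, "CHF0"), enumerate_class(k, "CHF1"))
    keys <- vapply(pool, bf_key, character(1))
    return(pool[!duplicated(keys)])
  }
  seen <- new.env(parent = emptyenv(), size = 4096L)
  out <- vector("list", 0L)
  add <- function(f) {
    key <- bf_key(f)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <<- f
    }
  }
  odd_P <- seq(1L, 2^k - 1L, by = 2L)
  for (P in odd_P) {
    ls <- layers_from_bias(k, P)
    assigns <- .layer_assignments(k, ls$layer_sizes)
    if (class == "NCF") {
      sign_grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
      for (lay in assigns)
        for (s in seq_len(nrow(sign_grid)))
          add(build_ncf("NCF", k, P, layers = lay,
                        signs = sign_grid[s, ]))
    } else {
      for (lay in assigns) {
        add(build_ncf(class, k, P, layers = lay))
        for (d in lay[[length(lay)]])
          add(build_ncf(class, k, P, layers = lay, deviant = d))
      }
    }
  }
  out
}
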