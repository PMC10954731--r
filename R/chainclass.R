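# Canalyzing structure recovery and the chain-function classes.
#
# A nested canalyzing function (NCF) can be peeled input by input: at
# each stage some input has a canalyzing value that fixes the output,
# and the recursion continues on the restriction to the non-canalyzing
# value.  Chain-0 functions are NCFs admitting a peeling whose first
# k-1 canalyzing input values are all 0 (the last input canalyzes in
# both values); chain-1 functions are the dual class with value 1.
# Within a layer every input canalyzes simultaneously, so greedy
# lowest-index peeling is equivalent to exhaustive search over peel
# orders; an exhaustive oracle (.classify_search) is retained for
# small k and exercised in the tests.

#' Canalyzing input/value/output triples
#'
#' A triple \code{(i, a, b)} is listed when fixing input \code{i} to value
#' \code{a} forces the output to \code{b}, i.e. the restriction of \code{f}
#' at \code{x_i = a} is the constant \code{b}.  Constant functions return an
#' empty set by convention.
#'
#' @param f a \code{\link{boolfn}} with \code{k >= 1}.
#' @return data frame with columns \code{input}, \code{value}, \code{output}.
#' @export
canalyzing_pairs <- function(f) {
  .check_bf(f)
  empty <- data.frame(input = integer(0), value = integer(0),
                      output = integer(0))
  if (f$k == 0L) return(empty)
  out <- f$outputs
  if (all(out == out[1L])) return(empty)
  res <- list()
  for (i in seq_len(f$k)) {
    for (v in 0:1) {
      half <- .restrict_outputs(out, f$k, i, v)
      if (all(half == half[1L]))
        res[[length(res) + 1L]] <- c(i, v, half[1L])
    }
  }
  if (length(res) == 0L) return(empty)
  m <- do.call(rbind, res)
  data.frame(input = m[, 1L], value = m[, 2L], output = m[, 3L])
}

# canalyzing (i, v, b) triples on a raw outputs vector
.canalyzing_raw <- function(out, k) {
  res <- list()
  if (all(out == out[1L])) return(res)
  for (i in seq_len(k)) {
    for (v in 0:1) {
      half <- .restrict_outputs(out, k, i, v)
      if (all(half == half[1L]))
        res[[length(res) + 1L]] <- c(i, v, half[1L])
    }
  }
  res
}

# Greedy peeling.  values: NULL for any canalyzing value (generic NCF
# test), or 0/1 to force the first k-1 canalyzing values (chain test).
# Returns list(sigma, a, b) on success, NULL otherwise.
.peel <- function(out, k, value = NULL) {
  if (k < 1L) return(NULL)
  orig <- seq_len(k)
  sigma <- integer(k); a <- integer(k); b <- integer(k)
  kk <- k
  while (kk > 1L) {
    cand <- .canalyzing_raw(out, kk)
    if (!is.null(value))
      cand <- Filter(function(tr) tr[2L] == value, cand)
    if (length(cand) == 0L) return(NULL)
    tr <- cand[[1L]]                       # lowest input index first
    pos <- k - kk + 1L
    sigma[pos] <- orig[tr[1L]]
    a[pos] <- tr[2L]
    b[pos] <- tr[3L]
    out <- .restrict_outputs(out, kk, tr[1L], 1L - tr[2L])
    orig <- orig[-tr[1L]]
    kk <- kk - 1L
  }
  if (out[1L] == out[2L]) return(NULL)     # residual constant: dummy input
  sigma[k] <- orig[1L]
  if (k >= 2L) {
    # last input canalyzes in both values; pick the value whose canalyzed
    # output continues the previous layer, so runs of b delimit layers
    a[k] <- which(out == b[k - 1L]) - 1L
    b[k] <- b[k - 1L]
  } else {
    a[1L] <- 1L
    b[1L] <- out[2L]
  }
  list(sigma = sigma, a = a, b = b)
}

.form_from_peel <- function(f, peel) {
  k <- f$k
  runs <- rle(peel$b)
  structure_ <- layers_from_bias(k, f$bias)
  list(sigma = peel$sigma,
       a = peel$a,
       b = peel$b,
       signs = ifelse(peel$a == peel$b, 1L, -1L),
       structure = structure_)
}

#' Recover the nested canalyzing form of a function
#'
#' Greedily peels canalyzing inputs (lowest index first); succeeds iff all
#' \code{k} inputs get peeled and the final 1-input residual is non-constant.
#' Functions with dummy inputs, constants and non-NCFs return \code{NULL}.
#'
#' @param f a \code{\link{boolfn}}.
#' @return \code{NULL}, or a list with \code{sigma} (peel order, original
#'   input indices), canalyzing values \code{a}, canalyzed outputs \code{b},
#'   literal \code{signs} (+1 for \code{x}, -1 for \code{!x}) and
#'   \code{structure} (see \code{\link{layers_from_bias}}).
#' @export
ncf_decompose <- function(f) {
  .check_bf(f)
  if (f$k == 0L) return(NULL)
  if (f$bias %% 2L == 0L) return(NULL)     # NCFs have odd bias
  peel <- .peel(f$outputs, f$k)
  if (is.null(peel)) return(NULL)
  form <- .form_from_peel(f, peel)
  # peeled layer sizes must match the bias-derived layer structure
  if (!identical(as.integer(rle(peel$b)$lengths),
                 as.integer(form$structure$layer_sizes)))
    return(NULL)
  form
}

#' Classify a function into the chain / NCF classes
#'
#' Labels: \code{CHF0} (chain-0), \code{CHF1} (chain-1), \code{CHF_BOTH}
#' (both, possible only for \code{k <= 2}), \code{NCF_NON_CHFU} (nested
#' canalyzing but not a generalized chain function) and \code{NOT_NCF}.
#' A 1-input non-constant function is \code{CHF_BOTH}: its only input
#' canalyzes in both values, which is the sole defining clause at
#' \code{k = 1}.  Constants and functions with dummy inputs are
#' \code{NOT_NCF}.
#'
#' @param f a \code{\link{boolfn}}.
#' @return list with \code{label} and, when the function is an NCF,
#'   \code{form} (from the class-specific peeling).
#' @export
classify_bf <- function(f) {
  .check_bf(f)
  lab <- .classify_outputs(f$outputs, f$k)
  form <- NULL
  if (lab$label != "NOT_NCF")
    form <- .form_from_peel(f, lab$peel)
  list(label = lab$label, form = form)
}

.classify_outputs <- function(out, k) {
  if (k == 0L) return(list(label = "NOT_NCF"))
  if (sum(out) %% 2L == 0L) return(list(label = "NOT_NCF"))
  if (k == 1L) {
    if (out[1L] == out[2L]) return(list(label = "NOT_NCF"))
    return(list(label = "CHF_BOTH", peel = .peel(out, k)))
  }
  p0 <- .peel(out, k, value = 0L)
  p1 <- .peel(out, k, value = 1L)
  if (!is.null(p0) && !is.null(p1))
    return(list(label = "CHF_BOTH", peel = p0))
  if (!is.null(p0)) return(list(label = "CHF0", peel = p0))
  if (!is.null(p1)) return(list(label = "CHF1", peel = p1))
  pn <- .peel(out, k)
  if (!is.null(pn)) {
    # guard against pathological peels whose layer sizes disagree with the
    # bias (cannot happen for true NCFs)
    ls <- tryCatch(layers_from_bias(k, sum(out)), error = function(e) NULL)
    if (!is.null(ls) &&
        identical(as.integer(rle(pn$b)$lengths),
                  as.integer(ls$layer_sizes)))
      return(list(label = "NCF_NON_CHFU", peel = pn))
    return(list(label = "NOT_NCF"))
  }
  list(label = "NOT_NCF")
}

# Exhaustive peel-order oracle: is there ANY peel sequence whose first
# k-1 canalyzing values all equal `value` (or any values when NULL),
# ending in a non-constant residual?  Exponential; used in tests for
# small k to guard the greedy production path.
.peel_search <- function(out, k, value = NULL) {
  if (k == 1L) return(out[1L] != out[2L])
  cand <- .canalyzing_raw(out, k)
  if (!is.null(value)) cand <- Filter(function(tr) tr[2L] == value, cand)
  for (tr in cand) {
    rest <- .restrict_outputs(out, k, tr[1L], 1L - tr[2L])
    if (.peel_search(rest, k - 1L, value)) return(TRUE)
  }
  FALSE
}

.classify_search <- function(f) {
  out <- f$outputs; k <- f$k
  if (k == 0L || sum(out) %% 2L == 0L) return("NOT_NCF")
  if (k == 1L) return(if (out[1L] != out[2L]) "CHF_BOTH" else "NOT_NCF")
  c0 <- .peel_search(out, k, 0L)
  c1 <- .peel_search(out, k, 1L)
  if (c0 && c1) return("CHF_BOTH")
  if (c0) return("CHF0")
  if (c1) return("CHF1")
  if (.peel_search(out, k)) return("NCF_NON_CHFU")
  "NOT_NCF"
}

#' Layer structure determined by the bias
#'
#' For a k-input NCF the first \code{k - 1} bits of the k-bit binary form of
#' the (odd) bias \code{P}, read most-significant-first, encode the operator
#' sequence of the nested expression (0 for AND, 1 for OR); the layer sizes
#' are the run lengths of that sequence with the final run extended by one
#' (the last variable carries no operator).  \code{P = 1} or
#' \code{P = 2^k - 1} gives a single layer of size \code{k}.
#'
#' @param k number of inputs (\code{1 <= k <= 50} so that \code{P} is exactly
#'   representable as a double).
#' @param P odd bias, \code{1 <= P <= 2^k - 1}.
#' @return list with \code{k}, \code{P}, \code{operators} (character, length
#'   \code{k - 1}, values \code{"AND"}/\code{"OR"}), \code{layer_sizes},
#'   \code{layer_number} and \code{m_last}.
#' @examples
#' layers_from_bias(4, 5)  # operators AND,OR,AND; layers 1,1,2
#' layers_from_bias(6, 7)  # layers 3,3
#' @export
layers_from_bias <- function(k, P) {
  stopifnot(k >= 1L, k <= 50L)
  if (P %% 2L == 0L)
    stop("bias P must be odd: NCFs have odd bias (got P = ", P, ")")
  if (P < 1 || P > 2^k - 1)
    stop("bias P must lie in [1, 2^k - 1]")
  bits <- (P %/% 2^((k - 1):0)) %% 2L
  if (k == 1L) {
    return(list(k = 1L, P = P, operators = character(0),
                layer_sizes = 1L, layer_number = 1L, m_last = 1L))
  }
  ops <- bits[seq_len(k - 1L)]
  runs <- rle(ops)
  sizes <- runs$lengths
  sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  list(k = as.integer(k), P = P,
       operators = ifelse(runs$values == 0L, "AND", "OR")[
         rep(seq_along(runs$lengths), runs$lengths)][seq_len(k - 1L)],
       op_bits = ops,
       layer_sizes = as.integer(sizes),
       layer_number = length(sizes),
       m_last = as.integer(sizes[length(sizes)]))
}

#' Build an NCF or chain function constructively
#'
#' Assembles the truth table of the nested expression determined by
#' \code{(k, P)}: the operator sequence comes from the binary form of the
#' bias, variables are assigned to layers by \code{layers}, and literal signs
#' are either forced by the class (chain functions: in a chain-0 a positive
#' literal precedes every AND and a negative literal every OR; chain-1 is the
#' mirror image) or given explicitly (class \code{"NCF"}).  For chain classes
#' at most one variable of the last layer may carry the deviant (opposite)
#' sign.
#'
#' @param class \code{"NCF"}, \code{"CHF0"} or \code{"CHF1"}.
#' @param k,P inputs and odd bias.
#' @param layers list of integer vectors assigning original input indices to
#'   layers (defaults to identity order); sizes must match
#'   \code{layers_from_bias(k, P)}.
#' @param signs for \code{"NCF"}: vector of +1/-1 literal signs per position.
#' @param deviant for chain classes: original index of the one last-layer
#'   variable with flipped sign, or \code{NULL}.
#' @return a \code{\link{boolfn}} with bias \code{P}.
#' @examples
#' # x1 & x2 & x3 & (!x4 | !x5 | x6): deviant x6, the paper-style 6-input
#' # chain-0 of bias 7
#' f2 <- build_ncf("CHF0", 6, 7, deviant = 6)
#' @export
build_ncf <- function(class = c("NCF", "CHF0", "CHF1"), k, P,
                      layers = NULL, signs = NULL, deviant = NULL) {
  class <- match.arg(class)
  ls <- layers_from_bias(k, P)
  if (is.null(layers)) {
    bounds <- cumsum(ls$layer_sizes)
    layers <- mapply(function(a, b) seq.int(a, b),
                     c(1L, utils::head(bounds, -1L) + 1L), bounds,
                     SIMPLIFY = FALSE)
  }
  if (!identical(as.integer(lengths(layers)), ls$layer_sizes) ||
      !setequal(unlist(layers), seq_len(k)))
    stop("layers must partition 1..k with sizes matching the bias")
  sigma <- unlist(layers)
  bits <- (P %/% 2^((k - 1):0)) %% 2L
  ops <- if (k >= 2L) bits[seq_len(k - 1L)] else integer(0)
  pos_op <- if (k >= 2L) c(ops, ops[k - 1L]) else 0L  # operator context per position
  if (class == "NCF") {
    if (is.null(signs) || length(signs) != k || !all(signs %in% c(-1L, 1L)))
      stop("class NCF requires a +1/-1 sign vector of length k")
    sgn <- as.integer(signs)
    if (!is.null(deviant)) stop("deviant applies only to chain classes")
  } else {
    base <- if (class == "CHF0") ifelse(pos_op == 0L, 1L, -1L)
            else ifelse(pos_op == 0L, -1L, 1L)
    sgn <- base
    if (!is.null(deviant)) {
      last_layer <- layers[[length(layers)]]
      if (!(deviant %in% last_layer))
        stop("deviant variable must belong to the last layer")
      pos <- which(sigma == deviant)
      sgn[pos] <- -sgn[pos]
    }
  }
  # evaluate the nested expression over all rows
  val <- NULL
  for (i in rev(seq_len(k))) {
    col <- .input_column(k, sigma[i])
    if (sgn[i] < 0L) col <- 1L - col
    if (is.null(val)) val <- col
    else val <- if (ops[i] == 0L) col * val else pmax(col, val)
  }
  f <- boolfn(as.integer(val), k)
  if (f$bias != P)
    stop("internal error: built function has bias ", f$bias, " != ", P)
  f
}

#' Render a nested canalyzing form as a Boolean expression
#'
#' Emits the nested-parenthesis normal form with layers regrouped, e.g.
#' \code{"x1 & x2 & (!x3 | x4)"}.
#'
#' @param form a form as returned by \code{\link{ncf_decompose}} or
#'   \code{\link{classify_bf}}.
#' @param names optional variable names (default \code{x1..xk}).
#' @return a character scalar.
#' @export
ncf_expression <- function(form, names = NULL) {
  k <- length(form$sigma)
  if (is.null(names)) names <- paste0("x", seq_len(k))
  lits <- ifelse(form$signs > 0L, names[form$sigma],
                 paste0("!", names[form$sigma]))
  sizes <- form$structure$layer_sizes
  bounds <- cumsum(sizes)
  starts <- c(1L, utils::head(bounds, -1L) + 1L)
  op_bits <- if (k >= 2L) (form$structure$P %/% 2^((k - 1):0)) %% 2L else 0L
  nlay <- length(sizes)
  # operator of layer j = the operator bit at the layer's first position
  opch <- vapply(seq_len(nlay), function(j) {
    if (k == 1L) " & "
    else if (op_bits[min(starts[j], k - 1L)] == 0L) " & " else " | "
  }, character(1))
  txt <- paste(lits[starts[1L]:bounds[1L]], collapse = opch[1L])
  for (j in seq_len(nlay)[-1L]) {
    seg <- paste(lits[starts[j]:bounds[j]], collapse = opch[j])
    txt <- paste0(txt, opch[j - 1L], "(", seg)  # join uses the outer layer's operator
  }
  paste0(txt, strrep(")", nlay - 1L))
}
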