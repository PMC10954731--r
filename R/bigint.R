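# Minimal non-negative big-integer arithmetic on base-1e7 limbs
# (little-endian numeric vectors).  Every intermediate product or
# carry stays below 2^53, so plain doubles are exact throughout.
# Only what the exact counting formulas need: add, subtract, compare,
# multiply, divide by a small integer, and decimal rendering.

.BIG_BASE <- 1e7

big <- function(n) {
  if (inherits(n, "bigint")) return(n)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n), n < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, n %% .BIG_BASE)
    n <- floor(n / .BIG_BASE)
    if (n == 0) break
  }
  structure(limbs, class = "bigint")
}

.big_trim <- function(x) {
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  structure(x, class = "bigint")
}

big_is_zero <- function(x) length(x) == 1L && x[1L] == 0

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  av <- c(unclass(a), numeric(n - length(a)))
  bv <- c(unclass(b), numeric(n - length(b)))
  s <- av + bv
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .BIG_BASE) 1 else 0
    if (carry) s[i] <- s[i] - .BIG_BASE
  }
  if (carry) s <- c(s, 1)
  .big_trim(s)
}

# a - b, requires a >= b
big_sub <- function(a, b) {
  stopifnot(big_cmp(a, b) >= 0L)
  n <- length(a)
  av <- unclass(a)
  bv <- c(unclass(b), numeric(n - length(b)))
  d <- av - bv
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BIG_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  .big_trim(d)
}

# sign of a - b: -1L, 0L, 1L
big_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la > lb) 1L else -1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

# multiply by an ordinary integer 0 <= s <= ~9e8
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == floor(s), s <= 9e8)
  if (s == 0 || big_is_zero(a)) return(big(0))
  p <- unclass(a) * s
  carry <- 0
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    v <- p[i] + carry
    out[i] <- v %% .BIG_BASE
    carry <- floor(v / .BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% .BIG_BASE)
    carry <- floor(carry / .BIG_BASE)
  }
  .big_trim(out)
}

# full schoolbook product; limb products <= (1e7-1)^2 < 2^47, carries
# are propagated limb-by-limb so partial sums never overflow
big_mul <- function(a, b) {
  if (big_is_zero(a) || big_is_zero(b)) return(big(0))
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb)
  for (i in seq_len(la)) {
    carry <- 0
    ai <- a[i]
    for (j in seq_len(lb)) {
      v <- out[i + j - 1L] + ai * b[j] + carry
      out[i + j - 1L] <- v %% .BIG_BASE
      carry <- floor(v / .BIG_BASE)
    }
    k <- i + lb
    while (carry > 0) {
      v <- out[k] + carry
      out[k] <- v %% .BIG_BASE
      carry <- floor(v / .BIG_BASE)
      k <- k + 1L
    }
  }
  .big_trim(out)
}

# exact division by a small integer (0 remainder enforced unless
# remainder = TRUE, in which case list(q, r) is returned)
big_div_small <- function(a, s, remainder = FALSE) {
  stopifnot(s >= 1, s == floor(s), s <= 9e8)
  n <- length(a)
  q <- numeric(n)
  r <- 0
  for (i in rev(seq_len(n))) {
    cur <- r * .BIG_BASE + a[i]
    q[i] <- floor(cur / s)
    r <- cur %% s
  }
  q <- .big_trim(q)
  if (remainder) return(list(q = q, r = r))
  if (r != 0) stop("big_div_small: division is not exact")
  q
}

big_pow2 <- function(e) {
  out <- big(1)
  while (e >= 29) {           # 2^29 < 9e8
    out <- big_mul_small(out, 2^29)
    e <- e - 29
  }
  if (e > 0) out <- big_mul_small(out, 2^e)
  out
}

big_to_string <- function(x) {
  limbs <- rev(unclass(x))
  head <- format(limbs[1L], scientific = FALSE)
  if (length(limbs) == 1L) return(head)
  paste0(head, paste(sprintf("%07d", limbs[-1L]), collapse = ""))
}

big_to_double <- function(x) {
  v <- 0
  for (i in rev(seq_along(x))) {
    v <- v * .BIG_BASE + x[i]
    if (!is.finite(v)) return(Inf)
  }
  v
}

#' @export
format.bigint <- function(x, ...) big_to_string(x)

#' @export
print.bigint <- function(x, ...) {
  cat(big_to_string(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) big_to_string(x)

# decimal string from a positive decimal-string input (for file IO)
big_from_string <- function(s) {
  s <- gsub("^\\s+|\\s+$", "", s)
  stopifnot(grepl("^[0-9]+$", s))
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  nch <- nchar(s)
  starts <- rev(seq(nch, 1L, by = -7L))
  limbs <- rev(vapply(starts, function(e) {
    b <- max(1L, e - 6L)
    as.numeric(substr(s, b, e))
  }, numeric(1)))
  .big_trim(limbs)
}

# quotient num/den rendered as a decimal string with `digits` digits
# after the point (long division; den > 0, num/den assumed modest in
# integer part)
big_ratio_decimal <- function(num, den, digits = 20L) {
  stopifnot(!big_is_zero(den))
  # integer part by repeated doubling subtraction (binary long division)
  ipart <- 0
  work <- num
  # find largest shift
  while (big_cmp(work, den) >= 0L) {
    mult <- den
    q <- 1
    repeat {
      dbl <- big_add(mult, mult)
      if (big_cmp(dbl, work) > 0L) break
      mult <- dbl
      q <- q * 2
    }
    work <- big_sub(work, mult)
    ipart <- ipart + q
  }
  digs <- character(digits)
  for (d in seq_len(digits)) {
    work <- big_mul_small(work, 10)
    q <- 0
    while (big_cmp(work, den) >= 0L) {
      work <- big_sub(work, den)
      q <- q + 1
    }
    digs[d] <- as.character(q)
  }
  paste0(format(ipart, scientific = FALSE), ".", paste(digs, collapse = ""))
}
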