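# Shared fixtures and tiny independent oracles used across the suite.

# outputs vector of the function encoded by integer `v` (row 0 = most
# significant bit of the 2^k-bit value)
outputs_of_int <- function(v, k) {
  n <- 2^k
  as.integer((v %/% 2^((n - 1):0)) %% 2)
}

# brute-force class tally over all 2^(2^k) truth tables
tally_all_functions <- function(k) {
  tally <- c(NCF = 0L, CHF0 = 0L, CHF1 = 0L, CHFU = 0L, NON = 0L)
  for (v in 0:(2^(2^k) - 1)) {
    lab <- ncfchain:::.classify_outputs(outputs_of_int(v, k), k)$label
    if (lab != "NOT_NCF") tally["NCF"] <- tally["NCF"] + 1L
    if (lab %in% c("CHF0", "CHF_BOTH")) tally["CHF0"] <- tally["CHF0"] + 1L
    if (lab %in% c("CHF1", "CHF_BOTH")) tally["CHF1"] <- tally["CHF1"] + 1L
    if (lab %in% c("CHF0", "CHF1", "CHF_BOTH")) tally["CHFU"] <- tally["CHFU"] + 1L
    if (lab == "NCF_NON_CHFU") tally["NON"] <- tally["NON"] + 1L
  }
  tally
}

# brute-force monotonicity oracle: unate direction from all 2^k * k
# adjacent-assignment pairs
unate_oracle <- function(f) {
  k <- f$k
  vapply(seq_len(k), function(i) {
    up <- TRUE; down <- TRUE
    for (r in 0:(2^k - 1)) {
      if ((r %/% 2^(k - i)) %% 2 == 0) {
        lo <- f$outputs[r + 1]
        hi <- f$outputs[r + 2^(k - i) + 1]
        if (hi < lo) up <- FALSE
        if (hi > lo) down <- FALSE
      }
    }
    if (up && down) "dummy" else if (up) "positive"
    else if (down) "negative" else "non-unate"
  }, character(1))
}

random_boolfn <- function(k) boolfn(sample(c(0L, 1L), 2^k, replace = TRUE), k)

# 2-node toggle: x1' = !x2, x2' = !x1
toggle_model <- function() {
  boolean_model(c("A", "B"), list(A = "B", B = "A"),
                list(A = boolfn(c(1L, 0L)), B = boolfn(c(1L, 0L))))
}

# self-activating single gene (two fixed points 0 and 1)
identity_gene <- function() {
  boolean_model("A", list(A = "A"), list(A = boolfn(c(0L, 1L))))
}

key_set <- function(fns) {
  e <- new.env(parent = emptyenv(), size = max(16L, length(fns)))
  for (f in fns) e[[paste(f$outputs, collapse = "")]] <- TRUE
  e
}
has_key <- function(set, f) !is.null(set[[paste(f$outputs, collapse = "")]])
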