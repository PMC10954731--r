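# Dataset summaries and relative-enrichment statistics.
#
# For an englobing type T (e.g. NCF) and sub-type T_s (e.g. chain-1),
# the relative enrichment at a given input count is
#   E_R = (f_s1 / f_1) / (f_s0 / f_0)
# with f_s1, f_1 the dataset fractions of T_s and T and f_s0, f_0 the
# theoretical fractions among all k-input functions.  Significance is
# the inclusive upper binomial tail of the T_s count among the T
# members, at success probability f_R = |T_s|_k / |T|_k (exact counts,
# not sampled estimates).  No multiple-testing correction is applied.

#' Assemble a collection of Boolean-function records
#'
#' @param model_id character vector of source model identifiers.
#' @param node character vector of node (gene) names.
#' @param fn list of \code{\link{boolfn}} objects.
#' @return data frame with columns \code{model_id}, \code{node}, \code{k}
#'   and list-column \code{fn}.
#' @export
bf_records <- function(model_id, node, fn) {
  stopifnot(length(model_id) == length(node), length(node) == length(fn))
  lapply(fn, .check_bf)
  k <- vapply(fn, function(f) f$k, integer(1))
  if (any(k < 1L | k > 20L))
    stop("records must have 1 <= k <= 20 inputs")
  data.frame(model_id = model_id, node = node, k = k,
             fn = I(fn), stringsAsFactors = FALSE)
}

.record_labels <- function(records) {
  cache <- new.env(parent = emptyenv())
  vapply(records$fn, function(f) {
    key <- paste0(f$k, ":", bf_key(f))
    lab <- cache[[key]]
    if (is.null(lab)) {
      lab <- classify_bf(f)$label
      cache[[key]] <- lab
    }
    lab
  }, character(1))
}

#' Per-k summary of a BF collection
#'
#' Counts, for every input count present in the data: total functions,
#' odd/even bias, NCFs, chain-0, chain-1, generalized chain (each function
#' counted once, including the \code{k <= 2} overlap) and non-chain NCFs.
#'
#' @param records a \code{\link{bf_records}} data frame.
#' @return data frame with one row per \code{k}.
#' @export
summarize_dataset <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records collection is empty")
  labels <- .record_labels(records)
  bias_odd <- vapply(records$fn, function(f) f$bias %% 2L == 1L, logical(1))
  ks <- sort(unique(records$k))
  rows <- lapply(ks, function(kk) {
    sel <- records$k == kk
    lab <- labels[sel]
    is_chf0 <- lab %in% c("CHF0", "CHF_BOTH")
    is_chf1 <- lab %in% c("CHF1", "CHF_BOTH")
    is_chfu <- lab %in% c("CHF0", "CHF1", "CHF_BOTH")
    is_ncf <- is_chfu | lab == "NCF_NON_CHFU"
    data.frame(k = kk, total = sum(sel),
               odd_bias = sum(bias_odd[sel]),
               even_bias = sum(!bias_odd[sel]),
               ncf = sum(is_ncf),
               chf0 = sum(is_chf0), chf1 = sum(is_chf1),
               chfu = sum(is_chfu),
               non_chfu_ncf = sum(lab == "NCF_NON_CHFU"))
  })
  do.call(rbind, rows)
}

#' Relative enrichment ratio
#'
#' @param f_s1,f_1 dataset fractions of the sub-type and its englobing type.
#' @param f_s0,f_0 the corresponding theoretical fractions.
#' @return list with \code{e_r} (NA with \code{defined = FALSE} on zero
#'   denominators) and \code{defined}.
#' @export
relative_enrichment <- function(f_s1, f_1, f_s0, f_0) {
  if (any(c(f_1, f_s0, f_0) == 0) || is.na(f_s1))
    return(list(e_r = NA_real_, defined = FALSE))
  list(e_r = (f_s1 / f_1) / (f_s0 / f_0), defined = TRUE)
}

#' Upper-tail binomial p-value for a sub-type count
#'
#' Inclusive upper tail: the probability, under uniform draws from the
#' englobing type, of observing at least \code{m} sub-type members among
#' \code{M_T} (computed in log space by \code{pbinom}).
#'
#' @param M_T number of englobing-type functions observed.
#' @param m number of sub-type functions observed.
#' @param f_R theoretical ratio \code{|T_s| / |T|}.
#' @return p-value in [0, 1].
#' @examples
#' enrichment_pvalue(10, 10, 0.5)  # 2^-10
#' @export
enrichment_pvalue <- function(M_T, m, f_R) {
  stopifnot(M_T >= 0, m >= 0, m <= M_T, f_R >= 0, f_R <= 1)
  if (m == 0) return(1)
  stats::pbinom(m - 1, size = M_T, prob = f_R, lower.tail = FALSE)
}

#' Relative-enrichment report over (type, sub-type) pairs
#'
#' One row per (k, T, T_s).  Supported types: englobing \code{"NCF"} with
#' sub-types \code{"CHF0"}, \code{"CHF1"}, \code{"CHFU"},
#' \code{"NON_CHFU_NCF"}.  For \code{k <= 2} every NCF is a generalized
#' chain function, so chain-vs-NCF rows are flagged \code{defined = FALSE}
#' (no meaningful enrichment or significance exists there).
#'
#' @param records a \code{\link{bf_records}} data frame.
#' @param pairs data frame with columns \code{type}, \code{subtype}
#'   (defaults to NCF vs the three chain classes).
#' @param k_max drop strata above this input count (default 10, the regime
#'   where reference datasets carry enough functions per k).
#' @return data frame with per-row counts, fractions, \code{e_r},
#'   \code{p_value} and \code{defined}.
#' @export
enrichment_report <- function(records,
                              pairs = data.frame(
                                type = "NCF",
                                subtype = c("CHF0", "CHF1", "CHFU")),
                              k_max = 10L) {
  records <- records[records$k <= k_max, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records at or below k_max")
  labels <- .record_labels(records)
  ks <- sort(unique(records$k))
  out <- list()
  for (kk in ks) {
    sel <- records$k == kk
    lab <- labels[sel]
    n_all <- sum(sel)
    is_ncf <- lab %in% c("CHF0", "CHF1", "CHF_BOTH", "NCF_NON_CHFU")
    M_T <- sum(is_ncf)
    for (p in seq_len(nrow(pairs))) {
      stopifnot(pairs$type[p] == "NCF")
      st <- pairs$subtype[p]
      m <- switch(st,
                  CHF0 = sum(lab %in% c("CHF0", "CHF_BOTH")),
                  CHF1 = sum(lab %in% c("CHF1", "CHF_BOTH")),
                  CHFU = sum(lab %in% c("CHF0", "CHF1", "CHF_BOTH")),
                  NON_CHFU_NCF = sum(lab == "NCF_NON_CHFU"),
                  stop("unknown subtype: ", st))
      if (M_T == 0L) next   # empty stratum: nothing to test
      f_R <- switch(st,
                    CHF0 = chain_ncf_ratio(kk, "CHF0"),
                    CHF1 = chain_ncf_ratio(kk, "CHF1"),
                    CHFU = chain_ncf_ratio(kk, "CHFU"),
                    NON_CHFU_NCF = 1 - chain_ncf_ratio(kk, "CHFU"))
      defined <- kk > 2L   # chain classes saturate the NCFs at k <= 2
      e_r <- if (defined && f_R > 0 && M_T > 0)
        (m / M_T) / f_R else NA_real_
      p_val <- if (defined && f_R > 0)
        enrichment_pvalue(M_T, m, f_R) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        k = kk, type = "NCF", subtype = st,
        n_total = n_all, M_T = M_T, m = m,
        f_s1 = if (n_all > 0) m / n_all else NA_real_,
        f_1 = if (n_all > 0) M_T / n_all else NA_real_,
        f_R = f_R, e_r = e_r, p_value = p_val, defined = defined)
    }
  }
  do.call(rbind, out)
}
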