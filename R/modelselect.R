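# Constrained ensemble generation and relative-stability model
# selection.  Starting from a signed GRN and named biological fixed
# points, each node's admissible update rules are the members of a
# function class (chain-0 / chain-1 / generalized chain / NCF) that
# (1) reproduce every fixed point row-wise, (2) are positive-unate in
# activators and negative-unate in inhibitors (for NCFs the literal
# sign equals the unate direction, so the sign rule can be enforced on
# the constructive form), and (3) belong to the class.  The ensemble
# is the cartesian product over nodes; selection then requires the
# MFPT stability hierarchy, a basin-sum floor, and optionally the
# absence of spurious attractors.

#' Construct a signed interaction network
#'
#' @param edges data frame with columns \code{source}, \code{target} and
#'   \code{sign} (+1 activation, -1 inhibition).  The regulator order of a
#'   target is the order its edges appear in.
#' @param nodes optional node names (defaults to all names appearing in
#'   \code{edges}, sources first).
#' @return object of class \code{signed_network} with \code{nodes},
#'   \code{edges} and per-target \code{regulators} / \code{signs}.
#' @export
signed_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c(-1, 1)))
    stop("edge signs must be +1 or -1; offending edge(s): ",
         paste(which(!edges$sign %in% c(-1, 1)), collapse = ", "))
  if (anyDuplicated(edges[, c("source", "target")]))
    stop("duplicate (source, target) edge")
  if (is.null(nodes))
    nodes <- unique(c(edges$source, edges$target))
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("edge references a node not in `nodes`")
  regs <- lapply(nodes, function(nd) edges$source[edges$target == nd])
  sgns <- lapply(nodes, function(nd) as.integer(edges$sign[edges$target == nd]))
  names(regs) <- names(sgns) <- nodes
  structure(list(nodes = nodes, edges = edges,
                 regulators = regs, signs = sgns),
            class = "signed_network")
}

#' Fixed-point input/output constraints per node
#'
#' For each declared fixed point X* and node i, the truth-table row formed by
#' X* restricted to i's regulators must map to X*_i.  Conflicting rows mark
#' the node infeasible.
#'
#' @param network a \code{\link{signed_network}}.
#' @param fps 0/1 matrix of fixed points: one row per named cell state,
#'   columns named by node.
#' @return named list per node: \code{rows} (0-based truth-table rows),
#'   \code{out} (required bits), \code{infeasible} flag.
#' @export
fixed_point_constraints <- function(network, fps) {
  fps <- as.matrix(fps)
  if (!setequal(colnames(fps), network$nodes))
    stop("fixed-point columns must cover exactly the network nodes")
  fps <- fps[, network$nodes, drop = FALSE]
  out <- list()
  for (nd in network$nodes) {
    regs <- network$regulators[[nd]]
    k <- length(regs)
    rows <- integer(0); req <- integer(0)
    for (s in seq_len(nrow(fps))) {
      r <- if (k == 0L) 0L else bits_to_state(fps[s, regs])
      rows <- c(rows, r)
      req <- c(req, fps[s, nd])
    }
    dup <- !duplicated(rows)
    infeasible <- any(tapply(req, rows, function(v) length(unique(v)) > 1L))
    out[[nd]] <- list(node = nd, k = k, rows = rows[dup], out = req[dup],
                      infeasible = isTRUE(infeasible))
  }
  out
}

#' Node constraint bundle
#'
#' @param network a \code{\link{signed_network}}.
#' @param fps fixed-point matrix (see \code{\link{fixed_point_constraints}}).
#' @param class function class imposed at every node.
#' @param fallback optional class used at nodes where the primary class
#'   admits no function.
#' @return named list of constraints consumable by
#'   \code{\link{admissible_functions}}.
#' @export
node_constraints <- function(network, fps,
                             class = c("CHFU", "CHF0", "CHF1", "NCF"),
                             fallback = NULL) {
  class <- match.arg(class)
  io <- fixed_point_constraints(network, fps)
  out <- list()
  for (nd in network$nodes) {
    out[[nd]] <- list(node = nd, k = io[[nd]]$k,
                      signs = network$signs[[nd]],
                      rows = io[[nd]]$rows, out = io[[nd]]$out,
                      infeasible = io[[nd]]$infeasible,
                      class = class, fallback = fallback)
  }
  out
}

# constructive generation of one class under fixed literal signs;
# returns deduplicated list of boolfn
.generate_class_signed <- function(k, class, signs) {
  out <- list()
  seen <- new.env(parent = emptyenv())
  add <- function(f) {
    key <- bf_key(f)
    if (is.null(seen[[key]])) { seen[[key]] <- TRUE; out[[length(out) + 1L]] <<- f }
  }
  if (k == 1L) {
    f <- if (signs[1L] > 0L) boolfn(c(0L, 1L)) else boolfn(c(1L, 0L))
    return(list(f))
  }
  for (P in seq(1L, 2^k - 1L, by = 2L)) {
    ls <- layers_from_bias(k, P)
    bits <- (P %/% 2^((k - 1):0)) %% 2L
    ops <- bits[seq_len(k - 1L)]
    pos_op <- c(ops, ops[k - 1L])
    bounds <- cumsum(ls$layer_sizes)
    starts <- c(1L, utils::head(bounds, -1L) + 1L)
    nlay <- ls$layer_number
    forced <- if (class == "CHF1") ifelse(pos_op == 0L, -1L, 1L)
              else ifelse(pos_op == 0L, 1L, -1L)   # CHF0 rule; NCF ignores
    for (lay in .layer_assignments(k, ls$layer_sizes)) {
      sigma <- unlist(lay)
      if (class == "NCF") {
        add(build_ncf("NCF", k, P, layers = lay, signs = signs[sigma]))
      } else {
        ok <- TRUE
        if (nlay > 1L) {
          for (j in seq_len(nlay - 1L)) {
            pos <- starts[j]:bounds[j]
            if (any(signs[sigma[pos]] != forced[pos])) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        lastpos <- starts[nlay]:bounds[nlay]
        mism <- lastpos[signs[sigma[lastpos]] != forced[lastpos]]
        if (length(mism) == 0L) {
          add(build_ncf(class, k, P, layers = lay))
        } else if (length(mism) == 1L) {
          add(build_ncf(class, k, P, layers = lay,
                        deviant = sigma[mism]))
        }
      }
    }
  }
  out
}

#' Admissible functions at a node
#'
#' Exactly the class members whose literal (equivalently unate) sign per
#' regulator matches the edge sign and whose truth table satisfies all
#' fixed-point I/O rows.  Generated constructively (odd biases, layer
#' structures, sign-compatible layer assignments, one optional last-layer
#' deviant for the chain classes) and deduplicated.  An infeasible
#' constraint yields an empty list; if a fallback class is configured it is
#' tried when the primary class admits nothing.
#'
#' @param constraint one element of \code{\link{node_constraints}}.
#' @return list of \code{\link{boolfn}}; attribute \code{"class_used"} names
#'   the class that produced it.
#' @export
admissible_functions <- function(constraint) {
  k <- constraint$k
  if (k == 0L) {
    # constant node: output fixed by the I/O rows (or both constants if free)
    cand <- list(boolfn(0L), boolfn(1L))
    keep <- Filter(function(f) all(f$outputs[constraint$rows + 1L] ==
                                     constraint$out), cand)
    attr(keep, "class_used") <- "CONST"
    return(keep)
  }
  if (k > 10L)
    stop("constructive class generation capped at k = 10")
  if (isTRUE(constraint$infeasible)) return(list())
  try_class <- function(cls) {
    pool <- if (cls == "CHFU") {
      both <- c(.generate_class_signed(k, "CHF0", constraint$signs),
                .generate_class_signed(k, "CHF1", constraint$signs))
      both[!duplicated(vapply(both, bf_key, character(1)))]
    } else .generate_class_signed(k, cls, constraint$signs)
    Filter(function(f) all(f$outputs[constraint$rows + 1L] == constraint$out),
           pool)
  }
  res <- try_class(constraint$class)
  used <- constraint$class
  if (length(res) == 0L && !is.null(constraint$fallback)) {
    res <- try_class(constraint$fallback)
    used <- constraint$fallback
  }
  keys <- vapply(res, bf_key, character(1))
  res <- res[order(keys)]
  attr(res, "class_used") <- used
  res
}

#' Cartesian ensemble over per-node admissible lists
#'
#' @param per_node named list (node -> list of \code{\link{boolfn}}).
#' @param network the \code{\link{signed_network}} the lists were built for.
#' @return object of class \code{bn_ensemble} with exact big-integer
#'   \code{size} (double rendering in \code{size_num}).
#' @export
build_ensemble <- function(per_node, network) {
  counts <- vapply(per_node, length, integer(1))
  size <- big(1)
  for (ct in counts) size <- big_mul_small(size, ct)
  structure(list(network = network, per_node = per_node,
                 counts = counts, size = size,
                 size_num = big_to_double(size)),
            class = "bn_ensemble")
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat("Model ensemble over", length(x$counts), "nodes; per-node counts:",
      paste(x$counts, collapse = " x "), "=", big_to_string(x$size), "\n")
  invisible(x)
}

#' Materialize one ensemble member
#'
#' Models are indexed 1..size in mixed-radix order (last node fastest).
#'
#' @param ensemble a \code{\link{build_ensemble}} result.
#' @param index model index (1-based, must be within \code{size_num} and
#'   representable as a double).
#' @return a \code{\link{boolean_model}}.
#' @export
ensemble_model <- function(ensemble, index) {
  stopifnot(index >= 1, index <= ensemble$size_num)
  counts <- ensemble$counts
  idx <- integer(length(counts))
  r <- index - 1
  for (i in rev(seq_along(counts))) {
    idx[i] <- r %% counts[i]
    r <- r %/% counts[i]
  }
  fns <- mapply(function(lst, j) lst[[j + 1L]], ensemble$per_node, idx,
                SIMPLIFY = FALSE)
  boolean_model(ensemble$network$nodes, ensemble$network$regulators, fns)
}

#' Selection criteria
#'
#' @param hierarchy data frame with columns \code{less} and \code{more}: the
#'   named cell state in \code{more} must be the more stable of each pair
#'   (\code{RS(more, less) > 0}).
#' @param basin_reference_sum floor for the summed basin sizes of the
#'   biological fixed points (usually the original model's own sum); NULL
#'   disables the criterion.
#' @param require_no_spurious reject models with attractors outside the
#'   declared fixed points.
#' @param dynamics \code{\link{stochastic_dynamics}} settings for sampled
#'   MFPTs (exact solves are used automatically for \code{N <= 12}).
#' @export
selection_criteria <- function(hierarchy,
                               basin_reference_sum = NULL,
                               require_no_spurious = TRUE,
                               dynamics = stochastic_dynamics()) {
  stopifnot(is.data.frame(hierarchy),
            all(c("less", "more") %in% names(hierarchy)))
  structure(list(hierarchy = hierarchy,
                 basin_reference_sum = basin_reference_sum,
                 require_no_spurious = require_no_spurious,
                 dynamics = dynamics),
            class = "selection_criteria")
}

# evaluate one model against fps/criteria; returns audit row pieces
.evaluate_model <- function(model, fp_states, criteria, seed_base = NULL) {
  att <- attractors(model)
  att_states <- lapply(att, `[[`, "states")
  fp_vec <- unlist(fp_states)
  is_bio <- vapply(att_states, function(st)
    length(st) == 1L && st %in% fp_vec, logical(1))
  spurious <- any(!is_bio)
  basin_sum <- sum(vapply(att[is_bio], `[[`, numeric(1), "basin_size"))
  basin_ok <- is.null(criteria$basin_reference_sum) ||
    basin_sum >= criteria$basin_reference_sum
  spurious_ok <- !criteria$require_no_spurious || !spurious
  hier <- criteria$hierarchy
  verdicts <- character(nrow(hier))
  n_viol <- 0L
  if (basin_ok && spurious_ok) {
    use_exact <- model$N <= 12L
    for (h in seq_len(nrow(hier))) {
      u <- fp_states[[hier$more[h]]]
      v <- fp_states[[hier$less[h]]]
      dyn <- criteria$dynamics
      if (!use_exact && !is.null(seed_base))
        dyn$seed <- (seed_base + h) %% .Machine$integer.max
      m_uv <- mfpt(model, u, v, dyn, mode = if (use_exact) "exact" else "sampled")
      m_vu <- mfpt(model, v, u, dyn, mode = if (use_exact) "exact" else "sampled")
      rs <- relative_stability(m_uv$mfpt, m_vu$mfpt, m_uv$se, m_vu$se)
      verdicts[h] <- rs$verdict
      if (rs$verdict != "u>v") n_viol <- n_viol + 1L
    }
  } else {
    verdicts[] <- NA_character_
    n_viol <- NA_integer_
  }
  selected <- basin_ok && spurious_ok &&
    !anyNA(verdicts) && all(verdicts == "u>v")
  list(n_attractors = length(att), spurious = spurious,
       basin_sum = basin_sum, verdicts = verdicts,
       n_violated = n_viol, selected = selected)
}

#' Select models satisfying stability hierarchies and basin criteria
#'
#' Exhaustively evaluates every ensemble member: attractor/basin screening
#' first (cheapest), then MFPT hierarchies (exact linear solve for
#' \code{N <= 12}, sampled otherwise with a per-(model, pair) seed stream).
#' A sampled RS within 3 SE of zero counts as undecided and fails the
#' hierarchy constraint.
#'
#' @param ensemble a \code{\link{build_ensemble}} result.
#' @param fps fixed-point matrix with named rows (cell states).
#' @param criteria a \code{\link{selection_criteria}}.
#' @param seed master seed for sampled-mode MFPT streams.
#' @return list with \code{audit} (one data-frame row per model: attractor
#'   count, spurious flag, basin sum, per-hierarchy verdicts, violation
#'   count, selected flag) and \code{selected} (model indices).
#' @export
select_models <- function(ensemble, fps, criteria, seed = 1L) {
  if (ensemble$size_num == 0)
    return(list(audit = data.frame(), selected = integer(0)))
  if (ensemble$size_num > 1e6)
    stop("ensemble too large for exhaustive desk-scale evaluation (",
         big_to_string(ensemble$size), " models)")
  fps <- as.matrix(fps)
  net <- ensemble$network
  fp_states <- stats::setNames(
    lapply(seq_len(nrow(fps)),
           function(s) bits_to_state(fps[s, net$nodes])),
    rownames(fps))
  missing_states <- setdiff(unlist(criteria$hierarchy), names(fp_states))
  if (length(missing_states) > 0L)
    stop("hierarchy names undeclared cell state(s): ",
         paste(missing_states, collapse = ", "))
  n <- ensemble$size_num
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    model <- ensemble_model(ensemble, i)
    ev <- .evaluate_model(model, fp_states, criteria,
                          seed_base = seed * 10007 + i)
    rows[[i]] <- data.frame(
      model = i, n_attractors = ev$n_attractors, spurious = ev$spurious,
      basin_sum = ev$basin_sum,
      verdicts = paste(ev$verdicts, collapse = ";"),
      n_violated = ev$n_violated, selected = ev$selected)
  }
  audit <- do.call(rbind, rows)
  list(audit = audit, selected = audit$model[audit$selected])
}
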