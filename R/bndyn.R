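# Synchronous Boolean-network dynamics, attractors/basins, the noisy
# transition model and MFPT-based relative stability.
#
# Network states are integers in [0, 2^N) whose bits, read
# most-significant-first, follow node declaration order (so node 1 is
# the high bit).  The noisy dynamics flip each bit independently with
# probability eta per step; when no bit flips, the deterministic
# synchronous image is applied.  The one-step law is the column of
# T* = (1-eta)^N T + P, with P the pure-noise perturbation kernel
# eta^d (1-eta)^(N-d) over Hamming distances d >= 1.

#' Construct a Boolean network model
#'
#' @param nodes character vector of node names (declaration order fixes the
#'   state bit order, node 1 most significant).
#' @param regulators named list: for each node, the ordered character vector
#'   of its regulators (the order matches the input slots of its function).
#'   Constant nodes have zero regulators.
#' @param functions named list of \code{\link{boolfn}} objects, one per node,
#'   with arity equal to the regulator count.
#' @return an object of class \code{boolean_model}.
#' @export
boolean_model <- function(nodes, regulators, functions) {
  stopifnot(is.character(nodes), length(nodes) >= 1L, !anyDuplicated(nodes))
  stopifnot(setequal(names(regulators), nodes), setequal(names(functions), nodes))
  regulators <- regulators[nodes]
  functions <- functions[nodes]
  for (nd in nodes) {
    regs <- regulators[[nd]]
    if (length(regs) > 0L && !all(regs %in% nodes))
      stop("node '", nd, "' has unresolved regulator(s): ",
           paste(setdiff(regs, nodes), collapse = ", "))
    f <- functions[[nd]]
    .check_bf(f)
    if (f$k != length(regs))
      stop("node '", nd, "': function arity ", f$k, " != ",
           length(regs), " regulators")
  }
  structure(list(nodes = nodes, regulators = regulators,
                 functions = functions, N = length(nodes)),
            class = "boolean_model")
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("Boolean model with %d nodes\n", x$N))
  for (nd in x$nodes)
    cat(sprintf("  %s <- f(%s)\n", nd,
                paste(x$regulators[[nd]], collapse = ", ")))
  invisible(x)
}

state_to_bits <- function(state, N) (state %/% 2^((N - 1):0)) %% 2L

bits_to_state <- function(bits) sum(bits * 2^((length(bits) - 1):0))

#' Full synchronous transition table
#'
#' @param model a \code{\link{boolean_model}} with \code{N <= 24}.
#' @return integer vector \code{tt} of length \code{2^N}: the successor of
#'   state \code{s} (0-based) is \code{tt[s + 1]}.
#' @export
transition_table <- function(model) {
  N <- model$N
  if (N > 24L) stop("full state-space enumeration capped at N = 24")
  states <- 0:(2^N - 1)
  nxt <- numeric(2^N)
  for (i in seq_len(N)) {
    nd <- model$nodes[i]
    regs <- match(model$regulators[[nd]], model$nodes)
    f <- model$functions[[nd]]
    if (f$k == 0L) {
      outi <- rep(f$outputs[1L], 2^N)
    } else {
      row <- numeric(2^N)
      for (j in seq_along(regs))
        row <- row + ((states %/% 2^(N - regs[j])) %% 2) * 2^(f$k - j)
      outi <- f$outputs[row + 1]
    }
    nxt <- nxt + outi * 2^(N - i)
  }
  as.numeric(nxt)
}

#' One synchronous update step
#'
#' @param model a \code{\link{boolean_model}}.
#' @param state integer state in \code{[0, 2^N)}.
#' @return the successor state.
#' @export
synchronous_step <- function(model, state) {
  N <- model$N
  stopifnot(state >= 0, state < 2^N)
  bits <- state_to_bits(state, N)
  new <- integer(N)
  for (i in seq_len(N)) {
    nd <- model$nodes[i]
    regs <- match(model$regulators[[nd]], model$nodes)
    f <- model$functions[[nd]]
    new[i] <- if (f$k == 0L) f$outputs[1L]
              else f$outputs[bits_to_state(bits[regs]) + 1L]
  }
  bits_to_state(new)
}

#' Attractors and basin sizes under synchronous update
#'
#' Enumerates the full state-transition graph.  Every state maps to exactly
#' one attractor; basin sizes (including the attractor states) sum to
#' \code{2^N}.
#'
#' @param model a \code{\link{boolean_model}} with \code{N <= 24}.
#' @return list of attractors, each a list with \code{states} (0-based, in
#'   cycle order), \code{type} (\code{"fixed"} or \code{"cyclic"}) and
#'   \code{basin_size}.
#' @export
attractors <- function(model) {
  tt <- transition_table(model)
  n <- length(tt)
  attr_id <- integer(n)                 # 0 = unvisited
  atts <- list()
  for (s0 in seq_len(n)) {
    if (attr_id[s0] != 0L) next
    path <- integer(0)
    onpath <- new.env(parent = emptyenv())
    s <- s0
    while (attr_id[s] == 0L && is.null(onpath[[as.character(s)]])) {
      onpath[[as.character(s)]] <- length(path) + 1L
      path <- c(path, s)
      s <- tt[s] + 1L
    }
    if (attr_id[s] != 0L) {
      id <- attr_id[s]
    } else {
      # new cycle found: states from first occurrence of s on the path
      start <- onpath[[as.character(s)]]
      cyc <- path[start:length(path)]
      id <- length(atts) + 1L
      atts[[id]] <- list(states = cyc - 1L,
                         type = if (length(cyc) == 1L) "fixed" else "cyclic")
    }
    attr_id[path] <- id
  }
  basins <- tabulate(attr_id, nbins = length(atts))
  for (i in seq_along(atts)) atts[[i]]$basin_size <- basins[i]
  structure(atts, class = "bn_attractors", attr_id = attr_id)
}

#' Fixed points of a model
#'
#' @param model a \code{\link{boolean_model}}.
#' @return numeric vector of fixed-point states (0-based).
#' @export
fixed_points <- function(model) {
  tt <- transition_table(model)
  which(tt == seq_along(tt) - 1L) - 1L
}

#' Stochastic dynamics settings
#'
#' @param eta per-node, per-step flip probability (default 0.05, as used for
#'   the MFPT estimates; hierarchies are insensitive to small deviations of
#'   the noise level around 0.01-0.05).
#' @param n_traj trajectories averaged per MFPT estimate (default 3000).
#' @param max_steps cap per trajectory; trajectories exceeding it are counted
#'   as failures and reported, never silently dropped.
#' @param seed optional integer seed.
#' @return list of settings, class \code{stochastic_dynamics}.
#' @export
stochastic_dynamics <- function(eta = 0.05, n_traj = 3000L,
                                max_steps = 1e6, seed = NULL) {
  stopifnot(eta >= 0, eta < 1, n_traj >= 1L, max_steps >= 1)
  structure(list(eta = eta, n_traj = as.integer(n_traj),
                 max_steps = max_steps, seed = seed),
            class = "stochastic_dynamics")
}

#' One step of the noisy dynamics
#'
#' Each bit flips independently with probability \code{eta}; if at least one
#' flipped, the perturbed state is returned, otherwise the deterministic
#' synchronous image.  With \code{eta = 0} this reduces to
#' \code{\link{synchronous_step}}.
#'
#' @param model a \code{\link{boolean_model}}.
#' @param state current state.
#' @param dynamics a \code{\link{stochastic_dynamics}} object.
#' @param tt optional precomputed \code{\link{transition_table}}.
#' @return the next state.
#' @export
noisy_step <- function(model, state, dynamics = stochastic_dynamics(),
                       tt = NULL) {
  N <- model$N
  flips <- stats::runif(N) < dynamics$eta
  if (any(flips)) {
    mask <- sum(2^((N - 1):0)[flips])
    return(bitwXor(as.integer(state), as.integer(mask)))
  }
  if (!is.null(tt)) tt[state + 1] else synchronous_step(model, state)
}

# dense noisy transition matrix T*, column-stochastic: T*[l, m] = P(m -> l)
# (0-based states l, m map to rows/cols l+1, m+1)
noisy_transition_matrix <- function(model, eta) {
  N <- model$N
  if (N > 12L) stop("dense transition matrix capped at N = 12")
  n <- 2^N
  tt <- transition_table(model)
  states <- 0:(n - 1)
  xo <- bitwXor(matrix(states, n, n), matrix(states, n, n, byrow = TRUE))
  d <- matrix(0L, n, n)
  for (b in 0:(N - 1)) d <- d + (xo %/% 2^b) %% 2L
  P <- eta^d * (1 - eta)^(N - d)
  diag(P) <- 0
  Tm <- matrix(0, n, n)
  Tm[cbind(tt + 1, states + 1)] <- 1
  (1 - eta)^N * Tm + P
}

#' Mean first passage time between two states
#'
#' Mean number of noisy-dynamics steps to first reach the target \code{u}
#' starting from \code{v}.  \code{mode = "exact"} solves the absorbing-chain
#' linear system on the full \code{2^N} chain (requires \code{N <= 12});
#' \code{mode = "sampled"} averages first-passage times over
#' \code{dynamics$n_traj} simulated trajectories and reports a standard
#' error plus the count of trajectories truncated at \code{max_steps}.
#'
#' @param model a \code{\link{boolean_model}}.
#' @param u target state (0-based integer).
#' @param v source state.
#' @param dynamics a \code{\link{stochastic_dynamics}}.
#' @param mode \code{"sampled"} or \code{"exact"}.
#' @return list with \code{mfpt}, \code{se} (NA in exact mode),
#'   \code{n_fail} and \code{mode}.  \code{u == v} returns 0 by convention.
#' @examples
#' # single self-activating gene: leaving a fixed point needs one bit flip,
#' # a geometric waiting time with mean 1/eta = 20 at eta = 0.05
#' m <- boolean_model("A", list(A = "A"), list(A = boolfn(c(0, 1))))
#' mfpt(m, u = 1, v = 0, mode = "exact")$mfpt
#' @export
mfpt <- function(model, u, v, dynamics = stochastic_dynamics(),
                 mode = c("sampled", "exact")) {
  mode <- match.arg(mode)
  N <- model$N
  stopifnot(u >= 0, u < 2^N, v >= 0, v < 2^N)
  if (u == v) return(list(mfpt = 0, se = 0, n_fail = 0L, mode = mode))
  if (mode == "exact") {
    if (N > 12L) stop("exact MFPT requires N <= 12; use sampled mode")
    if (dynamics$eta <= 0)
      stop("exact MFPT requires eta > 0 (the noisy chain must be irreducible)")
    Tstar <- noisy_transition_matrix(model, dynamics$eta)
    B <- t(Tstar)                       # B[m, l] = P(m -> l)
    keep <- setdiff(seq_len(2^N), u + 1)
    t_vec <- solve(diag(length(keep)) - B[keep, keep, drop = FALSE],
                   rep(1, length(keep)))
    idx <- match(v + 1, keep)
    return(list(mfpt = t_vec[idx], se = NA_real_, n_fail = 0L,
                mode = "exact"))
  }
  if (!is.null(dynamics$seed)) set.seed(dynamics$seed)
  tt <- transition_table(model)
  eta <- dynamics$eta
  if (eta == 0 && is.null(.reaches(tt, v, u)))
    return(list(mfpt = Inf, se = NA_real_, n_fail = dynamics$n_traj,
                mode = "sampled",
                note = "target unreachable under deterministic dynamics"))
  n_traj <- dynamics$n_traj
  cur <- rep(as.integer(v), n_traj)
  steps_done <- numeric(0)
  steps <- 0
  pow2 <- as.integer(2^((N - 1):0))
  while (length(cur) > 0L && steps < dynamics$max_steps) {
    steps <- steps + 1
    nf <- length(cur)
    flips <- matrix(stats::runif(nf * N) < eta, nf, N)
    nflips <- rowSums(flips)
    masks <- as.integer(flips %*% pow2)
    nxt <- ifelse(nflips > 0L, bitwXor(cur, masks), tt[cur + 1])
    hit <- nxt == u
    steps_done <- c(steps_done, rep(steps, sum(hit)))
    cur <- as.integer(nxt[!hit])
  }
  n_fail <- length(cur)
  n_ok <- length(steps_done)
  est <- if (n_ok > 0L) mean(steps_done) else NA_real_
  se <- if (n_ok > 1L) stats::sd(steps_done) / sqrt(n_ok) else NA_real_
  list(mfpt = est, se = se, n_fail = n_fail, mode = "sampled")
}

# deterministic reachability: steps from v to u under tt, NULL if never
.reaches <- function(tt, v, u) {
  seen <- logical(length(tt))
  s <- v; nsteps <- 0
  repeat {
    if (s == u) return(nsteps)
    if (seen[s + 1]) return(NULL)
    seen[s + 1] <- TRUE
    s <- tt[s + 1]
    nsteps <- nsteps + 1
  }
}

#' Relative stability of two cell states
#'
#' \code{RS(u, v) = 1/M_uv - 1/M_vu}; positive when \code{u} is the more
#' stable state (it is reached faster than it is left).  Antisymmetric by
#' construction.  When standard errors are supplied (sampled MFPTs), an RS
#' within \code{tol_se} standard errors of zero is reported as undecided.
#'
#' @param M_uv,M_vu positive mean first passage times (to \code{u} from
#'   \code{v}, and to \code{v} from \code{u}).
#' @param se_uv,se_vu optional standard errors of the two estimates.
#' @param tol_se tie tolerance in standard-error units (default 3).
#' @return list with \code{rs} and \code{verdict} in
#'   \code{c("u>v", "v>u", "undecided")}.
#' @export
relative_stability <- function(M_uv, M_vu, se_uv = NA, se_vu = NA,
                               tol_se = 3) {
  if (!is.finite(M_uv) || !is.finite(M_vu) || M_uv <= 0 || M_vu <= 0)
    stop("MFPTs must be positive and finite")
  rs <- 1 / M_uv - 1 / M_vu
  tol <- 0
  if (!is.na(se_uv) && !is.na(se_vu))
    tol <- tol_se * sqrt((se_uv / M_uv^2)^2 + (se_vu / M_vu^2)^2)
  verdict <- if (abs(rs) <= tol) "undecided"
             else if (rs > 0) "u>v" else "v>u"
  list(rs = rs, verdict = verdict)
}
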