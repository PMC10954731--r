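# Synthetic data: class-conditioned Boolean-function sampling, random
# signed GRN fixtures with planted fixed points, and planted-mixture
# BF datasets for enrichment testing.  All generators are pure
# functions of their arguments plus the R RNG state (use set.seed or
# the seed arguments for reproducibility).  Class sampling is
# enumeration-backed: uniform over the materialized, deduplicated
# class, which is exact but inherits the enumeration k-caps.

.enum_cache <- new.env(parent = emptyenv())

.class_pool <- function(k, class) {
  key <- paste0(class, ".", k)
  pool <- .enum_cache[[key]]
  if (is.null(pool)) {
    pool <- enumerate_class(k, class)
    .enum_cache[[key]] <- pool
  }
  pool
}

#' Sample functions uniformly from a class
#'
#' @param k number of inputs (within the \code{\link{enumerate_class}} caps;
#'   class \code{"RANDOM"} means uniform over all \code{2^(2^k)} functions
#'   and is capped at \code{k = 20}).
#' @param class \code{"NCF"}, \code{"CHF0"}, \code{"CHF1"}, \code{"CHFU"} or
#'   \code{"RANDOM"}.
#' @param n number of draws.
#' @param seed optional seed.
#' @return list of \code{\link{boolfn}} (a single \code{boolfn} when
#'   \code{n = 1}).
#' @export
sample_function <- function(k, class = c("NCF", "CHF0", "CHF1", "CHFU",
                                         "RANDOM"),
                            n = 1L, seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  if (class == "RANDOM") {
    draws <- lapply(seq_len(n), function(i)
      boolfn(sample(c(0L, 1L), 2^k, replace = TRUE), k))
  } else {
    pool <- .class_pool(k, class)
    draws <- pool[sample.int(length(pool), n, replace = TRUE)]
  }
  if (n == 1L) draws[[1L]] else draws
}

#' Random signed GRN with class-constrained rules and planted fixed points
#'
#' Each node receives 1..\code{max_in_degree} distinct regulators and a
#' function sampled uniformly from \code{class}; edge signs are set to the
#' function's unate directions, so the fixture is sign-conforming by
#' construction.  Fixed points are computed exactly by attractor
#' enumeration; when \code{min_fixed_points} cannot be met the generation is
#' retried up to \code{max_tries} times before failing.
#'
#' @param N number of nodes (\code{<= 12}).
#' @param max_in_degree maximum regulators per node (\code{<= 6}).
#' @param class function class for every node.
#' @param min_fixed_points retry until at least this many fixed points.
#' @param seed optional seed.
#' @param max_tries retry budget.
#' @return list with \code{network} (a \code{\link{signed_network}}),
#'   \code{model} (a \code{\link{boolean_model}}) and \code{fps} (0/1
#'   matrix of fixed points, rows named \code{FP1, FP2, ...}).
#' @export
random_model <- function(N, max_in_degree = 3L,
                         class = c("CHFU", "CHF0", "CHF1", "NCF"),
                         min_fixed_points = 0L, seed = NULL,
                         max_tries = 200L) {
  class <- match.arg(class)
  stopifnot(N >= 2L, N <= 12L, max_in_degree >= 1L, max_in_degree <= 6L)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("g", seq_len(N))
  for (try in seq_len(max_tries)) {
    regulators <- list(); functions <- list()
    edges <- list()
    for (i in seq_len(N)) {
      k <- sample.int(max_in_degree, 1L)
      regs <- nodes[sample.int(N, k)]
      f <- sample_function(k, class)
      dirs <- unate_directions(f)
      regulators[[nodes[i]]] <- regs
      functions[[nodes[i]]] <- f
      edges[[i]] <- data.frame(source = regs, target = nodes[i],
                               sign = ifelse(dirs == "positive", 1L, -1L))
    }
    model <- boolean_model(nodes, regulators, functions)
    fp <- fixed_points(model)
    if (length(fp) >= min_fixed_points) {
      fps <- t(vapply(fp, function(s) as.integer(state_to_bits(s, N)),
                      integer(N)))
      if (length(fp) == 0L) fps <- matrix(0L, 0L, N)
      colnames(fps) <- nodes
      rownames(fps) <- if (length(fp) > 0L) paste0("FP", seq_along(fp))
      network <- signed_network(do.call(rbind, edges), nodes = nodes)
      return(list(network = network, model = model, fps = fps))
    }
  }
  stop("could not generate a model with >= ", min_fixed_points,
       " fixed points in ", max_tries, " tries")
}

#' Planted-mixture BF dataset
#'
#' Draws \code{n} functions with class proportions \code{mixture} (over
#' \code{CHF0}, \code{CHF1}, \code{NCF}, \code{NCF_NON_CHFU} is not sampled
#' directly; \code{RANDOM} means uniform over all functions) and per-k
#' weights \code{k_weights}.  The planted class of each record is kept in
#' the \code{truth} column as hidden ground truth.
#'
#' @param n dataset size.
#' @param mixture named numeric vector of class proportions (must sum to 1),
#'   e.g. \code{c(CHF1 = 0.8, NCF = 0.2)}.
#' @param k_weights named numeric vector of weights over input counts, e.g.
#'   \code{c(`4` = 0.5, `5` = 0.5)}.
#' @param seed optional seed.
#' @return a \code{\link{bf_records}} data frame with an extra \code{truth}
#'   column.
#' @export
synthetic_bf_dataset <- function(n, mixture, k_weights, seed = NULL) {
  stopifnot(n >= 1L, abs(sum(mixture) - 1) < 1e-9,
            all(mixture >= 0), all(k_weights >= 0), sum(k_weights) > 0)
  if (!is.null(seed)) set.seed(seed)
  classes <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  ks <- as.integer(sample(names(k_weights), n, replace = TRUE,
                          prob = k_weights))
  fns <- vector("list", n)
  for (i in seq_len(n))
    fns[[i]] <- sample_function(ks[i], classes[i])
  rec <- bf_records(model_id = sprintf("synth%04d", seq_len(n)),
                    node = sprintf("gene%04d", seq_len(n)),
                    fn = fns)
  rec$truth <- classes
  rec
}
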