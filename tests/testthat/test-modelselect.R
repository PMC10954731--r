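# Constrained ensembles and stability-based selection.

toy_network <- function() {
  signed_network(data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = c(1, 1)))
}

test_that("fixed points induce row constraints per node", {
  net <- toy_network()
  fps <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("ON", "OFF"), c("A", "B")))
  io <- fixed_point_constraints(net, fps)
  expect_equal(io$A$rows, c(1L, 0L))
  expect_equal(io$A$out, c(1, 0))
  expect_false(io$A$infeasible)
  # conflicting requirements flag the node infeasible
  fps2 <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  io2 <- fixed_point_constraints(net, fps2)
  expect_true(io2$A$infeasible)
  # touched rows only; the rest stay free
  expect_equal(length(io$A$rows), 2)
})

test_that("admissible functions respect class, sign and fixed points", {
  net <- toy_network()
  fps <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("ON", "OFF"), c("A", "B")))
  nc <- node_constraints(net, fps, class = "CHFU")
  ad <- admissible_functions(nc$A)
  expect_equal(length(ad), 1)           # k = 1 activator with {1->1, 0->0}: x
  expect_identical(ad[[1]]$outputs, c(0L, 1L))
  # an I/O pair violating the only sign-conforming candidate empties the list
  nc$A$rows <- 1L; nc$A$out <- 0L
  expect_equal(length(admissible_functions(nc$A)), 0)
  # fallback class engages when the primary admits nothing
  nc$A$fallback <- "NCF"
  expect_equal(length(admissible_functions(nc$A)), 0)  # NCF no better at k=1
})

test_that("constructive generation equals brute-force class filtering", {
  set.seed(71)
  for (rep in 1:12) {
    k <- sample(2:4, 1)
    cls <- sample(c("CHF0", "CHF1", "CHFU", "NCF"), 1)
    signs <- sample(c(-1L, 1L), k, replace = TRUE)
    nrows <- sample(0:2, 1)
    rows <- sample(0:(2^k - 1), nrows)
    outs <- sample(0:1, nrows, replace = TRUE)
    constraint <- list(node = "n", k = k, signs = signs,
                       rows = rows, out = outs, infeasible = FALSE,
                       class = cls, fallback = NULL)
    got <- admissible_functions(constraint)
    # oracle: filter the enumerated class by unate signs and I/O rows
    pool <- enumerate_class(k, if (cls == "NCF") "NCF" else cls)
    want_dir <- ifelse(signs > 0, "positive", "negative")
    keep <- Filter(function(f) {
      identical(unate_directions(f), want_dir) &&
        all(f$outputs[rows + 1] == outs)
    }, pool)
    expect_setequal(vapply(got, function(f) paste(f$outputs, collapse = ""),
                           character(1)),
                    vapply(keep, function(f) paste(f$outputs, collapse = ""),
                           character(1)))
  }
})

test_that("ensemble size is the exact product with a faithful iterator", {
  net <- toy_network()
  dummy <- lapply(1:5, function(i) boolfn(c(0L, 1L)))
  per_node <- list(A = dummy[1:5], B = dummy[1:3])
  ens <- build_ensemble(per_node, net)
  expect_equal(ens$size_num, 15)
  # Table-style per-node counts (1,1,1,1,1,5,1,1,12) -> 60 models
  counts <- c(1, 1, 1, 1, 1, 5, 1, 1, 12)
  size <- ncfchain:::big(1)
  for (ct in counts) size <- ncfchain:::big_mul_small(size, ct)
  expect_equal(ncfchain:::big_to_double(size), 60)
  # zero anywhere empties the ensemble
  ens0 <- build_ensemble(list(A = dummy[1:2], B = list()), net)
  expect_equal(ens0$size_num, 0)
  # mixed-radix iteration hits each member exactly once
  seen <- vapply(1:15, function(i) {
    m <- ensemble_model(ens, i)
    paste(vapply(m$nodes, function(nd)
      paste(m$functions[[nd]]$outputs, collapse = ""), character(1)),
      collapse = "/")
  }, character(1))
  expect_equal(length(seen), 15)
})

test_that("selection excludes hierarchy reversals and basin shrinkage", {
  # two self-activating genes, no interaction between them is needed:
  # A' = A, B' = B has four fixed points; constrain to two cell states
  net <- signed_network(data.frame(source = c("A", "B"),
                                   target = c("A", "B"), sign = c(1, 1)))
  fns <- list(A = boolfn(c(0L, 1L)), B = boolfn(c(0L, 1L)))
  model <- boolean_model(c("A", "B"), list(A = "A", B = "B"), fns)
  fps <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("ON", "OFF"), c("A", "B")))
  nc <- node_constraints(net, fps, class = "CHFU")
  ad <- lapply(nc, admissible_functions)
  ens <- build_ensemble(ad, net)
  expect_gte(ens$size_num, 1)
  dyn <- stochastic_dynamics(eta = 0.05)
  # which state is more stable in the true model?
  m_uv <- mfpt(model, 3, 0, dyn, mode = "exact")$mfpt
  m_vu <- mfpt(model, 0, 3, dyn, mode = "exact")$mfpt
  rs <- relative_stability(m_uv, m_vu)
  expect_equal(rs$verdict, "undecided")  # symmetric by construction
  # a reversed (unsatisfiable) hierarchy excludes every model
  crit_rev <- selection_criteria(data.frame(less = "ON", more = "OFF"),
                                 require_no_spurious = FALSE, dynamics = dyn)
  res <- select_models(ens, fps, crit_rev)
  expect_equal(length(res$selected), 0)
  # basin floor above 2^N excludes everything as well
  crit_basin <- selection_criteria(data.frame(less = character(0),
                                              more = character(0)),
                                   basin_reference_sum = 5,
                                   require_no_spurious = FALSE,
                                   dynamics = dyn)
  expect_equal(length(select_models(ens, fps, crit_basin)$selected), 0)
  # with an attainable basin floor the audit retains every model
  crit_ok <- selection_criteria(data.frame(less = character(0),
                                           more = character(0)),
                                basin_reference_sum = 4,
                                require_no_spurious = FALSE, dynamics = dyn)
  res_ok <- select_models(ens, fps, crit_ok)
  expect_equal(nrow(res_ok$audit), ens$size_num)
  expect_true(all(res_ok$audit$basin_sum <= 4))
  sel_models <- res_ok$selected
  # the spurious-attractor screen only keeps models whose every attractor
  # is a declared cell state
  crit_sp <- selection_criteria(data.frame(less = character(0),
                                           more = character(0)),
                                require_no_spurious = TRUE, dynamics = dyn)
  res_sp <- select_models(ens, fps, crit_sp)
  for (i in res_sp$selected) {
    att <- attractors(ensemble_model(ens, i))
    sts <- unlist(lapply(att, `[[`, "states"))
    expect_true(all(sts %in% c(0, 3)))
  }
})

test_that("hierarchy constraints must name declared cell states", {
  net <- toy_network()
  fps <- matrix(c(1, 1), 1, 2, dimnames = list("ON", c("A", "B")))
  nc <- node_constraints(net, fps, class = "CHFU")
  ens <- build_ensemble(lapply(nc, admissible_functions), net)
  crit <- selection_criteria(data.frame(less = "ON", more = "GHOST"))
  expect_error(select_models(ens, fps, crit), "undeclared")
})

test_that("a planted model passes its own selection criteria", {
  set.seed(73)
  for (rep in 1:5) {
    fx <- random_model(4, 3, "CHFU", min_fixed_points = 2)
    nc <- node_constraints(fx$network, fx$fps, class = "CHFU")
    ad <- lapply(nc, admissible_functions)
    # generating functions are admissible at every node
    for (nd in fx$network$nodes) {
      key <- paste(fx$model$functions[[nd]]$outputs, collapse = "")
      keys <- vapply(ad[[nd]], function(f) paste(f$outputs, collapse = ""),
                     character(1))
      expect_true(key %in% keys, info = nd)
    }
  }
})
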