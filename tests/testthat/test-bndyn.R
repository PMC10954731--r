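# Synchronous dynamics, attractors, the noisy kernel and MFPTs.

test_that("synchronous update follows the regulator functions", {
  m <- boolean_model(c("A", "B"), list(A = "B", B = "A"),
                     list(A = boolfn(c(0L, 1L)), B = boolfn(c(0L, 1L))))
  expect_equal(synchronous_step(m, 1), 2)  # 01 -> 10
  expect_equal(synchronous_step(m, 2), 1)
  tg <- toggle_model()
  expect_equal(synchronous_step(tg, 0), 3)  # 00 -> 11
  # identity model leaves every state unchanged
  idm <- boolean_model(c("A", "B"),
                       list(A = "A", B = "B"),
                       list(A = boolfn(c(0L, 1L)), B = boolfn(c(0L, 1L))))
  for (s in 0:3) expect_equal(synchronous_step(idm, s), s)
  expect_identical(transition_table(idm), as.numeric(0:3))
  # arity mismatch surfaces at construction
  expect_error(boolean_model("A", list(A = "A"),
                             list(A = boolfn(c(0L, 0L, 0L, 1L)))),
               "arity")
})

test_that("attractors partition the state space", {
  att <- attractors(toggle_model())
  types <- vapply(att, `[[`, character(1), "type")
  sizes <- vapply(att, `[[`, numeric(1), "basin_size")
  expect_equal(sum(types == "fixed"), 2)
  expect_equal(sum(types == "cyclic"), 1)
  expect_equal(sort(sizes), c(1, 1, 2))
  expect_equal(sum(sizes), 4)
  cyc <- att[[which(types == "cyclic")]]
  expect_setequal(cyc$states, c(0, 3))
  expect_setequal(fixed_points(toggle_model()), c(1, 2))
  set.seed(41)
  for (rep in 1:5) {
    fx <- random_model(5, 3, "CHFU")
    att <- attractors(fx$model)
    expect_equal(sum(vapply(att, `[[`, numeric(1), "basin_size")), 32)
    sts <- unlist(lapply(att, `[[`, "states"))
    expect_equal(anyDuplicated(sts), 0)
    # planted fixed points are attractors of the model
    tt <- transition_table(fx$model)
    for (s in fixed_points(fx$model)) expect_equal(tt[s + 1], s)
  }
})

test_that("the noisy transition matrix is column-stochastic and matches
           the simulated one-step law", {
  m <- random_model(3, 2, "CHFU", seed = 43)$model
  eta <- 0.05
  Ts <- ncfchain:::noisy_transition_matrix(m, eta)
  expect_equal(colSums(Ts), rep(1, 8), tolerance = 1e-12)
  # eta = 0 reduces to the deterministic step
  dyn0 <- stochastic_dynamics(eta = 0)
  set.seed(1)
  expect_equal(noisy_step(m, 5, dyn0), synchronous_step(m, 5))
  # simulated one-step frequencies against the matrix column
  # (chi-square goodness of fit)
  set.seed(47)
  n <- 40000L
  N <- m$N
  tt <- transition_table(m)
  from <- 6L
  flips <- matrix(stats::runif(n * N) < eta, n, N)
  masks <- as.integer(flips %*% as.integer(2^((N - 1):0)))
  nxt <- ifelse(rowSums(flips) > 0, bitwXor(from, masks), tt[from + 1])
  obs <- tabulate(nxt + 1, nbins = 2^N)
  p <- Ts[, from + 1]
  keep <- p > 0
  chisq <- sum((obs[keep] - n * p[keep])^2 / (n * p[keep]))
  expect_lt(chisq, qchisq(1 - 1e-4, df = sum(keep) - 1))
})

test_that("exact MFPT solves the known geometric case", {
  m1 <- identity_gene()
  r <- mfpt(m1, u = 1, v = 0, stochastic_dynamics(eta = 0.05),
            mode = "exact")
  expect_equal(r$mfpt, 20, tolerance = 1e-9)
  expect_equal(mfpt(m1, 0, 0)$mfpt, 0)
  expect_error(mfpt(m1, 1, 0, stochastic_dynamics(eta = 0), mode = "exact"),
               "eta > 0")
})

test_that("sampled MFPT is consistent with the absorbing-chain solve", {
  m1 <- identity_gene()
  dyn <- stochastic_dynamics(eta = 0.05, n_traj = 3000, seed = 53)
  s <- mfpt(m1, 1, 0, dyn, mode = "sampled")
  expect_equal(s$n_fail, 0)
  expect_lt(abs(s$mfpt - 20), 3 * s$se)
  set.seed(59)
  for (rep in 1:3) {
    fx <- random_model(4, 3, "CHFU", min_fixed_points = 2)
    sts <- apply(fx$fps, 1, function(b) sum(b * 2^((fx$model$N - 1):0)))
    ex <- mfpt(fx$model, sts[1], sts[2], dyn, mode = "exact")$mfpt
    sm <- mfpt(fx$model, sts[1], sts[2],
               stochastic_dynamics(eta = 0.05, n_traj = 1500,
                                   max_steps = 1e5),
               mode = "sampled")
    expect_equal(sm$n_fail, 0)
    expect_lt(abs(sm$mfpt - ex), 3 * sm$se)
  }
})

test_that("sampled MFPT converges with the trajectory budget", {
  m1 <- identity_gene()
  errs <- vapply(c(300, 3000, 30000), function(nt) {
    r <- mfpt(m1, 1, 0, stochastic_dynamics(eta = 0.05, n_traj = nt,
                                            seed = 61), mode = "sampled")
    abs(r$mfpt - 20)
  }, numeric(1))
  expect_lt(errs[3], 0.5)     # ~ 3 SE at n = 30000
  expect_lt(errs[2], 1.5)
})

test_that("relative stability is antisymmetric with sane verdicts", {
  r <- relative_stability(10, 20)
  expect_equal(r$rs, 0.05)
  expect_equal(r$verdict, "u>v")
  expect_equal(relative_stability(15, 15)$rs, 0)
  expect_equal(relative_stability(15, 15)$verdict, "undecided")
  expect_equal(relative_stability(20, 10)$rs,
               -relative_stability(10, 20)$rs)
  # sampled ties within 3 SE are undecided
  expect_equal(relative_stability(100, 101, se_uv = 5, se_vu = 5)$verdict,
               "undecided")
  expect_error(relative_stability(-1, 5), "positive")
})

test_that("hierarchy verdicts are insensitive to the noise level", {
  fx <- random_model(4, 3, "CHFU", min_fixed_points = 2, seed = 67)
  sts <- apply(fx$fps, 1, function(b) sum(b * 2^((fx$model$N - 1):0)))
  verdicts <- vapply(c(0.01, 0.02, 0.05), function(eta) {
    m_uv <- mfpt(fx$model, sts[1], sts[2], stochastic_dynamics(eta = eta),
                 mode = "exact")$mfpt
    m_vu <- mfpt(fx$model, sts[2], sts[1], stochastic_dynamics(eta = eta),
                 mode = "exact")$mfpt
    relative_stability(m_uv, m_vu)$verdict
  }, character(1))
  expect_equal(length(unique(verdicts)), 1)
})
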