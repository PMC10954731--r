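# Canalyzing structure recovery and the chain classes.

test_that("canalyzing pairs come from constant restrictions", {
  cp <- canalyzing_pairs(bf_from_expression("x1 & x2", c("x1", "x2")))
  expect_equal(nrow(cp), 2)
  expect_true(all(cp$value == 0) && all(cp$output == 0))
  expect_equal(nrow(canalyzing_pairs(boolfn(c(0L, 1L, 1L, 0L)))), 0)
  cp <- canalyzing_pairs(bf_from_expression("x1 & (x2 | x3)",
                                            paste0("x", 1:3)))
  expect_equal(nrow(cp), 1)
  expect_equal(unlist(cp), c(input = 1, value = 0, output = 0))
  # constants have no canalyzing inputs by convention
  expect_equal(nrow(canalyzing_pairs(boolfn(rep(1L, 4)))), 0)
})

test_that("ncf_decompose recovers layers and rejects non-NCFs", {
  f <- bf_from_expression("x1 & x2 & (!x3 | x4)", paste0("x", 1:4))
  d <- ncf_decompose(f)
  expect_identical(d$structure$layer_sizes, c(2L, 2L))

  expect_null(ncf_decompose(boolfn(c(0L, 1L, 1L, 0L))))     # XOR
  expect_null(ncf_decompose(boolfn("0011")))                # dummy input
  expect_null(ncf_decompose(boolfn(rep(0L, 4))))            # constant

  d <- ncf_decompose(bf_from_expression("x1 & (x2 | x3)", paste0("x", 1:3)))
  expect_identical(d$sigma, 1:3)
  expect_identical(d$a, c(0L, 1L, 1L))
  expect_identical(d$b, c(0L, 1L, 1L))
  expect_identical(d$structure$layer_sizes, c(1L, 2L))

  # rebuilding the truth table from the recovered form is exact
  set.seed(23)
  for (f in sample(enumerate_class(4, "NCF"), 50)) {
    d <- ncf_decompose(f)
    layers <- split(d$sigma, rep(seq_along(d$structure$layer_sizes),
                                 d$structure$layer_sizes))
    g <- build_ncf("NCF", f$k, f$bias, layers = layers,
                   signs = d$signs)
    expect_identical(g$outputs, f$outputs)
  }
})

test_that("classification matches the worked examples", {
  f1 <- bf_from_expression("x1 & x2 & x3 & (!x4 | !x5 | !x6)",
                           paste0("x", 1:6))
  expect_equal(classify_bf(f1)$label, "CHF0")
  expect_equal(classify_bf(bf_from_expression("!x1 & (x2 | x3)",
                                              paste0("x", 1:3)))$label,
               "CHF1")
  expect_equal(classify_bf(bf_from_expression("x1 & (x2 | x3)",
                                              paste0("x", 1:3)))$label,
               "NCF_NON_CHFU")
  expect_equal(classify_bf(bf_from_expression("x1 & !x2",
                                              c("x1", "x2")))$label,
               "CHF_BOTH")
  expect_equal(classify_bf(boolfn(c(0L, 1L, 1L, 0L)))$label, "NOT_NCF")
  # both 1-input functions canalyze in both values
  expect_equal(classify_bf(boolfn(c(0L, 1L)))$label, "CHF_BOTH")
  expect_equal(classify_bf(boolfn(c(1L, 0L)))$label, "CHF_BOTH")
})

test_that("greedy peeling equals exhaustive search over peel orders", {
  for (k in 1:3) {
    for (v in 0:(2^(2^k) - 1)) {
      f <- boolfn(outputs_of_int(v, k))
      expect_identical(classify_bf(f)$label, ncfchain:::.classify_search(f),
                       info = paste("k =", k, "v =", v))
    }
  }
  set.seed(31)
  for (k in 4:5) {
    for (rep in 1:200) {
      f <- random_boolfn(k)
      expect_identical(classify_bf(f)$label, ncfchain:::.classify_search(f))
    }
    # also functions certain to be NCFs
    for (f in sample(enumerate_class(k, "NCF"), 100))
      expect_identical(classify_bf(f)$label, ncfchain:::.classify_search(f))
  }
})

test_that("layer structure follows the binary form of the bias", {
  ls <- layers_from_bias(4, 5)
  expect_identical(ls$operators, c("AND", "OR", "AND"))
  expect_identical(ls$layer_sizes, c(1L, 1L, 2L))
  expect_identical(layers_from_bias(6, 7)$layer_sizes, c(3L, 3L))
  for (k in c(2, 5, 9)) {
    ls <- layers_from_bias(k, 1)
    expect_identical(ls$layer_sizes, as.integer(k))
    expect_equal(ls$m_last, k)
  }
  expect_error(layers_from_bias(4, 6), "odd")
  expect_error(layers_from_bias(4, 17), "2\\^k - 1")
})

test_that("built chain functions classify back to their class", {
  f2 <- build_ncf("CHF0", 6, 7, deviant = 6)
  expect_identical(f2$outputs,
                   bf_from_expression("x1 & x2 & x3 & (!x4 | !x5 | x6)",
                                      paste0("x", 1:6))$outputs)
  expect_identical(build_ncf("CHF0", 2, 1)$outputs, c(0L, 0L, 0L, 1L))
  for (k in 1:5) {
    for (P in seq(1, 2^k - 1, by = 2)) {
      for (cls in c("CHF0", "CHF1")) {
        f <- build_ncf(cls, k, P)
        expect_equal(f$bias, P)
        lab <- classify_bf(f)$label
        expect_true(lab == cls || (k <= 2 && lab == "CHF_BOTH"),
                    info = paste(cls, k, P, "->", lab))
      }
    }
  }
  expect_error(build_ncf("CHF0", 4, 5, deviant = 1), "last layer")
  expect_error(build_ncf("NCF", 3, 3), "sign vector")
})

test_that("the printer emits the regrouped nested form", {
  f1 <- bf_from_expression("x1 & x2 & x3 & (!x4 | !x5 | !x6)",
                           paste0("x", 1:6))
  txt <- ncf_expression(classify_bf(f1)$form)
  expect_identical(bf_from_expression(txt, paste0("x", 1:6))$outputs,
                   f1$outputs)
  # round-trip through the printer for arbitrary NCFs
  set.seed(5)
  for (f in sample(enumerate_class(5, "NCF"), 40)) {
    txt <- ncf_expression(classify_bf(f)$form)
    expect_identical(bf_from_expression(txt, paste0("x", 1:5))$outputs,
                     f$outputs)
  }
})

test_that("every enumerated NCF has odd bias and bias-consistent layers", {
  for (k in 2:5) {
    for (f in enumerate_class(k, "NCF")) {
      expect_equal(f$bias %% 2, 1)
      d <- ncf_decompose(f)
      expect_identical(d$structure$layer_sizes,
                       layers_from_bias(k, f$bias)$layer_sizes)
    }
  }
})
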