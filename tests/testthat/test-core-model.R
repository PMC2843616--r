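test_that("p(D) follows from the probability decomposition p(S) = p(D) p(S|D)", {
  # pilot screen: 111/215 soluble fragments, 111/175 within soluble domains
  expect_equal(round(p_D_from_conditionals(111 / 215, 111 / 175), 2), 0.81)
  # reconciliation values
  expect_equal(round(p_D_from_conditionals(0.52, 0.693), 2), 0.75)
  # perfect boundary prediction passes p(S) through unchanged
  expect_equal(p_D_from_conditionals(0.37, 1), 0.37)

  expect_error(p_D_from_conditionals(0.5, 0), "undefined")
  expect_error(p_D_from_conditionals(0.7, 0.6), "p\\(D\\) > 1")
})

test_that("multiple-copy P_N matches direct evaluation of 1 - (1-q)^N", {
  expect_equal(P_N_multiple(q = 0.63, N = 1), 0.63)
  expect_equal(round(P_N_multiple(q = 0.63, N = 9), 5), 0.99987)
  expect_equal(round(P_N_multiple(q = 0.693, N = 10), 7), 0.9999926)
  # ratio and (f, F) routes agree; non-integer averages are accepted
  expect_equal(P_N_multiple(f = 6.3, F = 10, N = 4), P_N_multiple(q = 0.63, N = 4))

  expect_error(P_N_multiple(f = 6, F = 5, N = 1), "exceed")
  expect_error(P_N_multiple(f = 0, F = 5, N = 1), "positive")
  expect_error(P_N_multiple(q = 0.5, N = 0))
})

test_that("single-copy P_N equals exhaustive subset enumeration for every F <= 12", {
  for (F in 2:12) {
    for (f in 1:F) {
      N <- 1:F
      expect_equal(P_N_single(f, F, N),
                   vapply(N, function(n) enum_P_N(f, F, n), numeric(1)),
                   tolerance = 1e-12,
                   info = sprintf("f=%d F=%d", f, F))
    }
  }
})

test_that("single-copy P_N handles edge and large-window cases stably", {
  expect_equal(P_N_single(2, 5, 2), 0.7)
  # exhaustive draw must find the lone soluble design
  expect_identical(P_N_single(1, 37, 37), 1)
  # once the insoluble designs cannot fill the draw, success is certain
  expect_identical(P_N_single(3, 10, 8), 1)
  # iterated-ratio evaluation survives large windows without overflow
  expect_true(is.finite(P_N_single(5000, 10000, 10)))
  expect_equal(P_N_single(1, 10000, 1), 1e-4)

  expect_error(P_N_single(2, 5, 6), "more distinct")
  expect_error(P_N_single(6, 5, 2), "exceed")
  expect_error(P_N_single(2.5, 5, 2), "integer")
})

test_that("P_N obeys complement, monotonicity and dominance across the grid", {
  for (F in c(2, 3, 5, 9, 16, 30)) {
    for (f in 1:F) {
      N <- 1:F
      ps <- P_N_single(f, F, N)
      pm <- P_N_multiple(f = f, F = F, N = N)
      # complement law to machine precision
      expect_true(all(abs(ps + (1 - ps) - 1) <= .Machine$double.eps))
      expect_true(all(abs(pm + (1 - pm) - 1) <= .Machine$double.eps))
      # non-decreasing in N
      expect_true(all(diff(ps) >= -1e-15))
      expect_true(all(diff(pm) >= -1e-15))
      # without-replacement sampling can only help
      expect_true(all(ps >= pm - 1e-12))
    }
    # increasing in f at fixed (F, N); decreasing in F at fixed (f, N)
    N_mid <- max(1L, F %/% 2L)
    expect_true(all(diff(vapply(1:F, function(f) P_N_single(f, F, N_mid), 1)) >= -1e-15))
    expect_true(all(diff(vapply(1:F, function(f) P_N_multiple(f = f, F = F, N = N_mid), 1)) >= -1e-15))
  }
  fixed_f <- 3
  ps_overF <- vapply(4:30, function(F) P_N_single(fixed_f, F, 2), numeric(1))
  pm_overF <- vapply(4:30, function(F) P_N_multiple(f = fixed_f, F = F, N = 2), numeric(1))
  expect_true(all(diff(ps_overF) <= 1e-15))
  expect_true(all(diff(pm_overF) <= 1e-15))
})

test_that("hypergeometric and binomial sampling agree when N is a small part of F", {
  # pilot-scale window
  expect_lt(abs(P_N_single(567, 900, 9) - P_N_multiple(f = 567, F = 900, N = 9)), 5e-4)
  # the few-percent claim over a spread of soluble fractions, N <= 0.02 F
  F <- 900
  for (f in c(9, 90, 300, 567, 810)) {
    for (N in c(1, 5, 10, 18)) {
      expect_lt(abs(P_N_single(f, F, N) - P_N_multiple(f = f, F = F, N = N)), 0.02)
    }
  }
})

test_that("expected_domains combines p(D) and P_N into yields", {
  par_pilot <- model_parameters(p_D = 0.81, p_S_given_D = 0.63)
  yv <- expected_domains(par_pilot, design_point(M = 1, N = 9))
  expect_equal(round(yv$E_domain, 2), 0.81)

  # reconciliation design reproduces the observed 18-of-24
  par_rec <- model_parameters(p_D = 0.75, p_S_given_D = 0.693)
  yv2 <- expected_domains(par_rec, design_point(M = 24, N = 10))
  expect_equal(round(yv2$E_domain, 1), 18.0)

  # certainty
  yv3 <- expected_domains(model_parameters(p_D = 1, p_S_given_D = 1),
                          design_point(M = 7, N = 3))
  expect_equal(yv3$E_domain, 7)

  # structural invariants of the yield value
  for (yv_i in list(yv, yv2, yv3)) {
    expect_lte(abs(yv_i$P_N + yv_i$P_N_complement - 1), .Machine$double.eps)
    expect_lte(yv_i$E_domain, yv_i$M)
    expect_equal(yv_i$e_domain, yv_i$P_N / (yv_i$N + yv_i$r))
  }

  # at N = 1 the model closes the loop: E/M = p(D) p(S|D) = p(S)
  par_full <- model_parameters(p_S = 111 / 215, p_S_given_D = 111 / 175)
  yv4 <- expected_domains(par_full, design_point(M = 1, N = 1))
  expect_equal(yv4$E_domain, 111 / 215)

  expect_error(expected_domains(model_parameters(p_S_given_D = 0.6),
                                design_point(M = 1, N = 2)),
               "cannot be derived")
})

test_that("normalized yield e_domain divides P_N by the per-domain cost", {
  expect_equal(e_domain(q = 0.63, N = 1, r = 0), 0.63)
  expect_equal(signif(e_domain(q = 0.63, N = 7, r = 1000), 4), 9.921e-4)
  expect_equal(e_domain(q = 0.63, N = 2, r = 0), 0.43155)
  # with no set-up cost, spending more per domain only dilutes the yield
  expect_true(all(diff(e_domain(q = 0.63, N = 1:50, r = 0)) < 0))
  expect_error(e_domain(q = 0.63, N = 2, r = -1), "non-negative")
})

test_that("heterogeneous per-domain (f, F) sums per-domain success probabilities", {
  expect_equal(expected_domains_heterogeneous(data.frame(f = c(3, 0), F = c(10, 10)),
                                              N = 1), 0.3)
  expect_equal(expected_domains_heterogeneous(data.frame(f = rep(567, 18), F = rep(900, 18)),
                                              N = 9),
               18 * P_N_multiple(f = 567, F = 900, N = 9))
  expect_equal(expected_domains_heterogeneous(data.frame(f = c(1, 2), F = c(4, 4)),
                                              N = 2, copy_mode = "single"),
               0.5 + 5 / 6)
  expect_error(expected_domains_heterogeneous(data.frame(f = 1, F = 4), N = 5,
                                              copy_mode = "single"),
               "smallest F")
})

test_that("model_parameters validates and derives its members", {
  mp <- model_parameters(p_S = 111 / 215, p_S_given_D = 111 / 175)
  expect_equal(mp$p_D, (111 / 215) / (111 / 175))
  # derived from counts
  mp2 <- model_parameters(f = 567, F = 900)
  expect_equal(mp2$p_S_given_D, 0.63)
  # a triple pre-rounded to two decimals is accepted under the default tolerance
  expect_silent(model_parameters(p_S = 0.52, p_S_given_D = 0.63, p_D = 0.81))

  expect_error(model_parameters(p_S = 0.7, p_S_given_D = 0.6), "inconsistent")
  expect_error(model_parameters(p_S = 0.2, p_S_given_D = 0.5, p_D = 0.9), "inconsistent")
  expect_error(model_parameters(f = 5, F = 4), "f <= F")
  expect_error(model_parameters(p_S = 0.5, se = list(p_S = 0.7)), "\\[0, 0.5\\]")
  expect_error(design_point(M = 0, N = 1))
  expect_error(design_point(M = 1, N = 1, r = -2), "non-negative")
})
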