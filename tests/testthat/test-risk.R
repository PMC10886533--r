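demo_params <- function(model = "mechanistic", alpha = 0.1, R = 0.5,
                        beta_ear = 1, gamma_e = 0, gamma_a = 0) {
  list(model = model, alpha = alpha, R = R, beta_ear = beta_ear,
       gamma_e = gamma_e, gamma_a = gamma_a, alpha_beta = 3)
}

test_that("risk-equivalent dose models satisfy their closed forms", {
  for (m in c("linear", "bell", "plateau", "mechanistic"))
    expect_equal(red(0, 2, demo_params(m)), 0)
  expect_equal(red(7.5, 2, demo_params("linear")), 7.5)

  # plateau -> D to first order as alpha' * D -> 0
  expect_equal(red(1e-4, 1e-5, demo_params("plateau")), 1e-4,
               tolerance = 1e-5)

  # mechanistic equals a literal transcription of the formula
  expect_equal(red(10, 2, demo_params("mechanistic", alpha = 0.1, R = 0.5)),
               mech_oracle(10, 2, 0.1, 0.5), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:25) {
    D <- runif(1, 0, 40); d <- D / sample(15:18, 1)
    al <- runif(1, 0.01, 0.3); R <- runif(1, 0.1, 0.9)
    expect_equal(red(D, d, demo_params(alpha = al, R = R)),
                 mech_oracle(D, d, al, R), tolerance = 1e-10)
  }
  expect_error(red(-1, 2, demo_params()), ">= 0")
})

test_that("mechanistic model converges to bell and plateau at R endpoints", {
  D <- seq(0.5, 39.5, by = 0.5); d <- D / 15
  near0 <- red(D, d, demo_params("mechanistic", R = 1e-8))
  bell <- red(D, d, demo_params("bell"))
  expect_true(all(abs(near0 - bell) < 1e-6))
  near1 <- red(D, d, demo_params("mechanistic", R = 1 - 1e-8))
  plat <- red(D, d, demo_params("plateau"))
  expect_true(all(abs(near1 - plat) < 1e-6))
  # exact endpoints are dispatched, never NaN
  expect_equal(red(D, d, demo_params("mechanistic", R = 0)), bell)
  expect_equal(red(D, d, demo_params("mechanistic", R = 1)), plat)
  # continuity in dose
  fine <- red(seq(0, 40, by = 1e-3), 2, demo_params())
  expect_true(all(abs(diff(fine)) < 1e-2))
})

test_that("OED reduces to mean dose for the linear model and matches the bin loop", {
  set.seed(13)
  d <- random_dvh(30)
  expect_equal(oed(d, demo_params("linear"), 15), mean_dose(d),
               tolerance = 1e-14)
  # uniform DVH: single-bin reduction to red(D, D/n)
  u <- dvh("x", c(0, 23.95, 24.05), c(0, 100))
  expect_equal(oed(u, demo_params(), 15), red(24, 24 / 15, demo_params()),
               tolerance = 1e-12)
  for (i in 1:10) {
    d <- random_dvh(50)
    p <- demo_params(alpha = runif(1, 0.02, 0.3), R = runif(1, 0.2, 0.8))
    expect_equal(oed(d, p, 18), oed_loop_oracle(d, p, 18), tolerance = 1e-10)
  }
})

test_that("nonlinear OED is sublinear: never above the mean dose", {
  set.seed(17)
  for (i in 1:20) {
    d <- random_dvh()
    for (m in c("bell", "plateau", "mechanistic")) {
      p <- demo_params(m, alpha = runif(1, 0.02, 0.3), R = runif(1, 0.2, 0.8))
      expect_lte(oed(d, p, 15), mean_dose(d) + 1e-9)
    }
  }
})

test_that("EAR age modifier and hand-evaluated oracle agree", {
  p <- demo_params(beta_ear = 2.5, gamma_e = 0.01, gamma_a = 3)
  # at exposure age 30 and attained age 70 the modifier is exactly 1
  expect_equal(ear(4, p, 30, 70), 2.5 * 4)
  expect_equal(ear(0, p, 40, 60), 0)
  p2 <- demo_params(beta_ear = 1, gamma_e = 0.002, gamma_a = 4.23)
  expect_equal(ear(10, p2, 40, 60),
               10 * exp(0.002 * (40 - 30) + 4.23 * log(60 / 70)),
               tolerance = 1e-12)
  expect_error(ear(1, p, 50, 40), "attained age")
})

test_that("LAR accumulates yearly EAR over the projection window", {
  flat <- demo_params(beta_ear = 1, gamma_e = 0, gamma_a = 0)
  # flat EAR E over ages 45..70: 26 years
  E <- 3.7
  expect_equal(lar(E, flat, 40, 70, 5), 100 * E * 26 / 1e4, tolerance = 1e-12)
  expect_equal(lar(0, flat, 40), 0)
  p <- demo_params(beta_ear = 2, gamma_e = 0.01, gamma_a = 2.5)
  for (agex in c(32, 41, 54)) {
    expect_equal(lar(5, p, agex), lar_loop_oracle(5, p, agex),
                 tolerance = 1e-12)
  }
  # monotone non-decreasing in the projection age
  lars <- vapply(60:75, function(pa) lar(5, p, 40, pa), numeric(1))
  expect_true(all(diff(lars) >= 0))
  expect_warning(out <- lar(5, p, 68, 70, latency = 5), "empty")
  expect_equal(out, 0)
})

test_that("EAR and LAR are homogeneous in OED but not in DVH dose", {
  p <- demo_params(beta_ear = 1.3, gamma_e = 0.005, gamma_a = 1.2)
  expect_equal(ear(8, p, 40, 60), 2 * ear(4, p, 40, 60))
  expect_equal(lar(8, p, 40), 2 * lar(4, p, 40))
  # doubling every DVH dose does not double the OED for a nonlinear model
  set.seed(31)
  d <- random_dvh(30)
  d2 <- dvh(d$structure, d$edges * 2, d$bin_volume)
  o1 <- oed(d, demo_params(), 15)
  o2 <- oed(d2, demo_params(), 15)
  expect_gt(abs(o2 - 2 * o1), 1e-3)
})

test_that("total_risk sums per-organ values and rejects duplicates", {
  tb <- tibble::tibble(organ = c("liver", "stomach"), ear = c(1.1, 2.2),
                       lar = c(0.1, 0.2))
  expect_equal(total_risk(tb), c(ear = 3.3, lar = 0.3))
  expect_equal(total_risk(tb[0, ]), c(ear = 0, lar = 0))
  expect_error(total_risk(rbind(tb, tb[1, ])), "duplicate")
})

test_that("demonstration registry clones kidneys and pancreas from small bowel", {
  tb <- default_risk_params()
  expect_setequal(tb$organ, risk_organs())
  sb <- tb[tb$organ == "small_bowel", ]
  for (org in c("kidneys", "pancreas")) {
    row <- tb[tb$organ == org, ]
    expect_equal(row$alpha, sb$alpha)
    expect_equal(row$beta_ear, sb$beta_ear)
    expect_match(row$source, "cloned from small_bowel")
  }
  expect_true(all(tb$alpha_beta == 3))
})
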