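test_that("the F-field vanishes when conditions are identical within subject", {
  S <- 5; C <- 4; N <- 20
  base <- withr::with_seed(2, matrix(rnorm(S * N), S, N))
  Y <- aperm(array(rep(base, C), c(S, N, C)), c(1, 3, 2))
  Fv <- f_field(curve_dataset(Y))
  expect_equal(as.numeric(Fv), rep(0, N))
})

test_that("node-wise F matches a textbook repeated-measures ANOVA", {
  cd <- fx_curves(S = 6, C = 3, N = 11)
  Fv <- f_field(cd)
  for (node in c(1, 5, 11)) {
    tab <- cd$curves[, , node]
    df <- data.frame(y = as.vector(tab),
                     subj = factor(rep(seq_len(6), 3)),
                     cond = factor(rep(seq_len(3), each = 6)))
    av <- summary(stats::aov(y ~ subj + cond, data = df))[[1]]
    expect_equal(Fv[node], av["cond", "F value"], tolerance = 1e-10)
  }
})

test_that("per-subject offsets do not move the F-field", {
  cd <- fx_curves(S = 5, C = 3, N = 15)
  shifted <- cd$curves + array(rep(rnorm(5) * 100, 3 * 15), dim(cd$curves))
  expect_equal(as.numeric(f_field(curve_dataset(shifted))),
               as.numeric(f_field(cd)), tolerance = 1e-8)
})

test_that("effect size f follows the sums-of-squares definition", {
  # hand-computable 2x2 table, constant across nodes:
  # SS_cond = 2.25, SS_err = 0.25 -> f = 3
  Y <- array(0, c(2, 2, 3))
  Y[1, , ] <- c(0, 1)
  Y[2, , ] <- c(0, 2)
  f <- effect_size_f(curve_dataset(Y))
  expect_equal(as.numeric(f), 3)
  # identical conditions -> f = 0
  Yid <- array(rep(c(1, 2), 2 * 3), c(2, 2, 3))
  expect_equal(as.numeric(effect_size_f(curve_dataset(Yid))), 0)
  # invariant to a global constant
  expect_equal(as.numeric(effect_size_f(curve_dataset(Y + 100))), 3)
  expect_error(effect_size_f(curve_dataset(Y), window = c(200, 300)), "window")
})

test_that("permutation inference is seed-deterministic and alpha-monotone", {
  cd <- fx_curves(S = 8, C = 4, N = 51, effect = 0.6)
  a <- permutation_inference(cd, n_perm = 199, seed = 3)
  b <- permutation_inference(cd, n_perm = 199, seed = 3)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$threshold, b$threshold)
  thr <- vapply(c(0.01, 0.05, 0.2),
                function(al) permutation_inference(cd, alpha = al,
                                                   n_perm = 199,
                                                   seed = 3)$threshold,
                numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("a strong whole-curve offset yields one near-global cluster", {
  cd <- fx_curves(S = 8, C = 3, N = 101, sd = 0.3)
  Y <- cd$curves
  Y[, 3, ] <- Y[, 3, ] + 10  # one condition shifted everywhere
  res <- permutation_inference(curve_dataset(Y), n_perm = 199, seed = 5)
  expect_gte(nrow(res$clusters), 1)
  main <- which.max(res$clusters$extent)
  expect_gte(res$clusters$extent[main], 90)
  expect_lt(res$clusters$p[main], 0.05)
})

test_that("small designs are enumerated exhaustively and ignore the seed", {
  cd <- fx_curves(S = 3, C = 2, N = 21, effect = 1)  # (2!)^3 = 8 <= n_perm
  a <- permutation_inference(cd, n_perm = 100, seed = 1)
  b <- permutation_inference(cd, n_perm = 100, seed = 99)
  expect_true(a$exhaustive)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$clusters, b$clusters)
  expect_equal(a$n_perm, 7)  # 8 relabelings minus the observed one
})

test_that("degenerate and invalid inputs are caught", {
  expect_error(curve_dataset(array(0, c(1, 4, 10))), "2 subjects")
  Y <- array(rnorm(40), c(2, 2, 10)); Y[1, 1, 1] <- NA
  expect_error(curve_dataset(Y), "incomplete")
  expect_error(permutation_inference(fx_curves(S = 3, C = 2, N = 5),
                                     n_perm = 50), "n_perm")
})
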