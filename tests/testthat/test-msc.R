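test_that("identity and exact affine fits are recovered", {
  axis <- seq(500, 2000, by = 2)
  ref <- water_reference(axis)
  fit <- fit_msc(ref, ref)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)

  z <- ir_spectrum(axis, 0.5 + 2 * ref$absorbance, id = "affine")
  fit <- fit_msc(z, ref)
  expect_equal(fit$a, 0.5, tolerance = 1e-12)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
})

test_that("fit matches the normal-equations oracle and is optimal", {
  set.seed(101)
  axis <- toy_axis(50L, from = 800, by = 20)
  r <- runif(50)
  ref <- ir_spectrum(axis, r)
  for (i in 1:5) {
    z <- runif(50)
    fit <- fit_msc(ir_spectrum(axis, z), ref)
    orc <- oracle_msc(z, r)
    expect_equal(fit$a, orc$a, tolerance = 1e-10)
    expect_equal(fit$b, orc$b, tolerance = 1e-10)
    expect_equal(fit$rmse, orc$rmse, tolerance = 1e-10)
    # least-squares optimality on a perturbation grid
    da <- seq(-0.1, 0.1, length.out = 21)
    db <- seq(-0.1, 0.1, length.out = 21)
    for (x in da) for (yv in db) {
      rm2 <- sqrt(mean((z - (fit$a + x) - (fit$b + yv) * r)^2))
      expect_gte(rm2, fit$rmse - 1e-12)
    }
  }
})

test_that("residual satisfies the least-squares normal equations", {
  set.seed(7)
  axis <- toy_axis(80L, from = 600, by = 15)
  r <- runif(80); z <- runif(80)
  fit <- fit_msc(ir_spectrum(axis, z), ir_spectrum(axis, r))
  n <- length(r); scale <- max(abs(z))
  expect_lt(abs(sum(fit$residual)), 1e-8 * n * scale)
  expect_lt(abs(sum(fit$residual * r)), 1e-8 * n * scale)
  expect_equal(fit$rmse, sqrt(mean(fit$residual^2)), tolerance = 1e-15)
})

test_that("rmse_of matches closed forms and a loop oracle", {
  expect_identical(rmse_of(numeric(7) * 0), 0)
  expect_equal(rmse_of(c(3, 4)), 5 / sqrt(2), tolerance = 1e-14)
  set.seed(2)
  eps <- rnorm(100)
  acc <- 0
  for (e in eps) acc <- acc + e * e
  expect_equal(rmse_of(eps), sqrt(acc / 100), tolerance = 1e-14)
  expect_error(rmse_of(numeric(0)), class = "ir_contract_error")
})

test_that("threshold rule is inclusive on the water side", {
  expect_identical(classify_rmse(0.13, 0.13), "water")
  expect_identical(classify_rmse(0, 0.13), "water")
  expect_identical(classify_rmse(0.144, 0.13), "cartilage")
  expect_identical(classify_rmse(c(0.1, 0.2), 0.15), c("water", "cartilage"))
  expect_error(classify_rmse(0.1, 0), class = "ir_contract_error")
  expect_error(classify_rmse(NaN, 0.1), class = "ir_contract_error")
})

test_that("affine invariance and reference-scale equivariance hold", {
  set.seed(33)
  axis <- toy_axis(60L, from = 700, by = 20)
  r <- runif(60); z <- runif(60)
  ref <- ir_spectrum(axis, r)
  fit <- fit_msc(ir_spectrum(axis, z), ref)

  alpha <- 0.7; beta <- 2.3
  fit2 <- fit_msc(ir_spectrum(axis, alpha + beta * z), ref)
  expect_equal(fit2$a, alpha + beta * fit$a, tolerance = 1e-9)
  expect_equal(fit2$b, beta * fit$b, tolerance = 1e-9)
  expect_equal(fit2$rmse, beta * fit$rmse, tolerance = 1e-9)

  gamma <- -1.7
  fit3 <- fit_msc(ir_spectrum(axis, z), ir_spectrum(axis, gamma * r))
  expect_equal(fit3$b, fit$b / gamma, tolerance = 1e-9)
  expect_equal(fit3$residual, fit$residual, tolerance = 1e-12)
  expect_equal(fit3$rmse, fit$rmse, tolerance = 1e-12)
})

test_that("rmse grows strictly with analyte fraction in noise-free mixtures", {
  axis <- fp_axis()
  w <- water_reference(axis)
  cart <- cartilage_spectrum(axis)
  rmses <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(cf) {
    z <- ir_spectrum(axis, 0.02 + 1.1 * w$absorbance + cf * cart$absorbance)
    fit_msc(z, w, region = c(800, 1900))$rmse
  }, numeric(1))
  expect_true(all(diff(rmses) > 0))
  expect_equal(rmses[1], 0, tolerance = 1e-12)
})

test_that("fit contracts: constant reference, small region, axis mismatch", {
  axis <- toy_axis(10L)
  z <- ir_spectrum(axis, runif(10))
  expect_error(fit_msc(z, ir_spectrum(axis, rep(2, 10))),
               class = "ir_numeric_error")
  expect_error(fit_msc(z, ir_spectrum(axis, 1:10), region = c(1000, 1011)),
               class = "ir_region_error")
  expect_error(fit_msc(z, ir_spectrum(axis + 1, 1:10)),
               class = "ir_contract_error")
})

test_that("preclassify labels, preserves order and is equivariant", {
  axis <- seq(700, 1950, by = 2.5)
  ref <- water_reference(axis)
  n <- 4L
  copies <- ir_dataset(axis, matrix(rep(ref$absorbance, n), nrow = n,
                                    byrow = TRUE))
  res <- preclassify(copies, ref, threshold = 0.01)
  expect_identical(res$label, rep("water", n))

  sim <- simulate_spectra(n_water = 20L, n_cartilage = 20L, seed = 9L)
  wr <- water_reference(sim$dataset$axis)
  res <- preclassify(sim$dataset, wr, threshold = 1, region = c(800, 1900))
  theta <- gap_midpoint(res$rmse[sim$truth$class == "water"],
                        res$rmse[sim$truth$class == "cartilage"])
  res <- preclassify(sim$dataset, wr, threshold = theta,
                     region = c(800, 1900))
  expect_identical(res$label == "water", sim$truth$class == "water")

  # permuting rows permutes results identically
  perm <- c(31:40, 1:30)
  d2 <- ir_dataset(sim$dataset$axis, sim$dataset$matrix[perm, ],
                   ids = sim$dataset$ids[perm])
  res2 <- preclassify(d2, wr, threshold = theta, region = c(800, 1900))
  expect_equal(res2$rmse, res$rmse[perm], tolerance = 1e-14)
  expect_identical(res2$label, res$label[perm])
})

test_that("gap_midpoint sits between separated clusters and warns on overlap", {
  expect_equal(gap_midpoint(c(0.01, 0.02), c(0.1, 0.3)), 0.06)
  expect_warning(gap_midpoint(c(1, 5), c(4, 9)), "overlap")
})
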