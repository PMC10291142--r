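test_that("compute_loss reproduces hand-evaluated values", {
  g <- chain_graph(3)
  # balanced, non-negative, scale-matched -> all terms zero
  f <- matrix(c(2, 2, 2), 1)
  loss <- compute_loss(f, g, ta = 6, lambda_scale = 1)
  expect_equal(loss, list(total = 0, balance = 0, nonneg = 0, scale = 0))

  # single-module graph, flux -1: (f - |f|)^2 = (-2)^2 = 4
  g1 <- factor_graph(list(metabolite("A", role = "end"), metabolite("B", role = "end")),
                     list(reaction_module("M", inputs = "A", outputs = "B", genes = "g")))
  loss1 <- compute_loss(matrix(-1, 1, 1), g1, ta = 0, lambda_scale = 0)
  expect_equal(loss1$nonneg, 4)
  expect_equal(loss1$total, 4)

  # chain (1,2,3), TA 5, lambda 0.5: balance (1-2)^2+(2-3)^2 = 2,
  # scale 0.5*(6-5)^2 = 0.5, total 2.5
  loss2 <- compute_loss(matrix(c(1, 2, 3), 1), g, ta = 5, lambda_scale = 0.5)
  expect_equal(loss2$balance, 2)
  expect_equal(loss2$nonneg, 0)
  expect_equal(loss2$scale, 0.5)
  expect_equal(loss2$total, 2.5)

  expect_error(compute_loss(matrix(1, 1, 2), g, ta = 1), "columns")
  expect_error(compute_loss(matrix(1, 2, 3), g, ta = 1), "length")
})

test_that("loss is non-negative and zero only for feasible flux states", {
  g <- diamond_graph()
  set.seed(1)
  for (i in 1:20) {
    f <- matrix(rnorm(8), 2, 4)
    ta <- runif(2, 0, 5)
    loss <- compute_loss(f, g, ta, lambda_scale = 0.7)
    expect_gte(loss$total, 0)
  }
  F <- sample_balanced_fluxes(g, 5, seed = 2)
  expect_equal(compute_loss(F, g, rowSums(F), 1)$total, 0, tolerance = 1e-18)
})

test_that("total activity sums network genes only, or takes a constant", {
  g <- chain_graph(2)
  expr <- rbind(g1_1 = c(1, 2), g2_1 = c(2, 0), other = c(5, 5))
  colnames(expr) <- c("s1", "s2")
  ta <- total_activity(expr, g, mode = "metabolic_total")
  expect_equal(unname(ta), c(3, 2))  # 'other' excluded
  expect_equal(unname(total_activity(expr, g, mode = "constant", constant = 10)),
               c(10, 10))
  expect_error(total_activity(expr, g, mode = "constant", constant = -1),
               "non-negative")
  expect_warning(total_activity(expr * 0, g), "zero")
})

test_that("training is deterministic given the seed and respects epochs = 0", {
  g <- chain_graph(3)
  F <- sample_balanced_fluxes(g, 60, seed = 4)
  ex <- expression_from_flux(F, g, genes_per_module = 2, noise_sd = 0.1, seed = 5)
  cfg <- flux_training_config(epochs = 20L)
  fit1 <- train_flux_model(ex$graph, ex$expression, cfg)
  fit2 <- train_flux_model(ex$graph, ex$expression, cfg)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$flux, fit2$flux)

  fit0 <- train_flux_model(ex$graph, ex$expression, flux_training_config(epochs = 0L))
  expect_equal(nrow(fit0$trace), 1L)
  expect_equal(fit0$trace$epoch, 0)
  expect_true(is.finite(fit0$trace$total))
})

test_that("training reduces the imbalance term on clean chain data", {
  g <- chain_graph(3)
  F <- sample_balanced_fluxes(g, 200, seed = 7)
  ex <- expression_from_flux(F, g, genes_per_module = 3, noise_sd = 0, seed = 8)
  fit <- train_flux_model(ex$graph, ex$expression,
                          flux_training_config(epochs = 300L))
  tr <- fit$trace
  expect_lt(tr$balance[nrow(tr)] / tr$balance[1], 0.05)
  expect_true(all(is.finite(tr$total)))
  expect_true(all(diff(cummin(tr$total)) <= 0))  # running minimum non-increasing
})

test_that("prediction is consistent with training output and sample identity", {
  g <- diamond_graph()
  F <- sample_balanced_fluxes(g, 50, seed = 1)
  ex <- expression_from_flux(F, g, genes_per_module = 2, noise_sd = 0.05, seed = 2)
  fit <- train_flux_model(ex$graph, ex$expression, flux_training_config(epochs = 30L))
  pred <- predict_flux(fit$model, ex$expression)
  expect_equal(pred, fit$flux)

  dup <- ex$expression[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  p2 <- predict_flux(fit$model, dup)
  expect_equal(unname(p2["a", ]), unname(p2["b", ]))

  # absent genes are zero-filled by name, with a warning
  partial <- ex$expression[-1, , drop = FALSE]
  expect_warning(p3 <- predict_flux(fit$model, partial), "zero-filled")
  expect_equal(dim(p3), dim(pred))

  # clamped reporting is non-negative
  expect_true(min(predict_flux(fit$model, ex$expression, clamp = TRUE)) >= 0)
})

test_that("modules without observed genes are pinned to zero flux", {
  g <- chain_graph(3)
  F <- sample_balanced_fluxes(g, 40, seed = 3)
  ex <- expression_from_flux(F, g, genes_per_module = 2, noise_sd = 0.1, seed = 3)
  expr <- ex$expression[!grepl("^M2_", rownames(ex$expression)), ]
  w <- capture_warnings(
    fit <- train_flux_model(ex$graph, expr, flux_training_config(epochs = 5L)))
  expect_true(any(grepl("pinned", w)))
  expect_true(any(grepl("zero expression", w)))
  expect_true(all(fit$flux[, "M2"] == 0))
})

test_that("training rejects degenerate inputs", {
  g <- chain_graph(2)
  expr <- matrix(1, 2, 3, dimnames = list(c("nope1", "nope2"), c("a", "b", "c")))
  expect_error(train_flux_model(g, expr, flux_training_config()), "no genes")
  expect_error(train_flux_model(g, -expr, flux_training_config()), "non-negative")
})

test_that("metabolite change equals influx minus outflux and is linear", {
  # two producers (2, 3) and one consumer (4) -> change +1
  g <- factor_graph(
    list(metabolite("S1", role = "end"), metabolite("S2", role = "end"),
         metabolite("K"), metabolite("T", role = "end")),
    list(reaction_module("a", inputs = "S1", outputs = "K", genes = "ga"),
         reaction_module("b", inputs = "S2", outputs = "K", genes = "gb"),
         reaction_module("c", inputs = "K", outputs = "T", genes = "gc")))
  expect_equal(unname(metabolite_change(matrix(c(2, 3, 4), 1), g)[1, 1]), 1)

  chain <- chain_graph(3)
  expect_equal(unname(metabolite_change(matrix(c(3, 1, 1), 1), chain)[1, ]),
               c(2, 0))
  F <- sample_balanced_fluxes(chain, 10, seed = 2)
  expect_equal(max(abs(metabolite_change(F, chain))), 0)

  # linearity
  F1 <- matrix(rnorm(6), 2, 3); F2 <- matrix(rnorm(6), 2, 3)
  expect_equal(metabolite_change(2 * F1 + 3 * F2, chain),
               2 * metabolite_change(F1, chain) + 3 * metabolite_change(F2, chain))
})
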