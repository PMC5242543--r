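test_that("noise-free forward-model coefficients are recovered exactly", {
  truth <- list(g = 0.01, coefs = c(-0.3, 0.05, 0.01))
  pair <- toy_pair(40, truth$coefs, truth$g, noise_sd = 0)
  fit <- fit_mapping(pair$s, pair$f, k_max = 2, mu = 1e-8,
                     warn_spectral = FALSE)
  expect_equal(fit$global_input, truth$g, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), truth$coefs, tolerance = 1e-4)

  # fit + predict closes the loop on the data
  pred <- predict(fit, pair$s)
  expect_lt(max(abs(pred - pair$f)), 1e-6)
})

test_that("self-mapping F = S at K = 1 yields c1 ~ 1 and negligible offset", {
  s <- toy_pair(30)$s
  f_self <- connectivity_matrix(unclass(s), labels = node_labels(s),
                                kind = "functional", weighted = TRUE)
  fit <- fit_mapping(s, f_self, k_max = 1, mu = 1e-10,
                     warn_spectral = FALSE)
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 1e-6)
  expect_lt(abs(fit$coefficients[1]), 1e-6)
  expect_lt(abs(fit$global_input), 1e-6)
})

test_that("restored coefficients reproduce the normalized-scale prediction", {
  pair <- toy_pair(25, noise_sd = 0.01, seed = 9)
  basis <- build_power_basis(pair$s, 3)
  x <- assemble_design(basis)
  y <- vectorize_lower(unclass(pair$f))
  b <- solve_tikhonov(x, y, 1e-4, c(FALSE, rep(TRUE, 4)))
  pred_normalized <- unvectorize_lower(drop(x %*% b), 25)

  fit <- fit_mapping(pair$s, pair$f, k_max = 3, mu = 1e-4,
                     warn_spectral = FALSE)
  pred_restored <- predict(fit, pair$s)
  expect_lt(max(abs(unclass(pred_restored) - pred_normalized)), 1e-10)
})

test_that("in-sample RSS is nonincreasing in K at mu = 0", {
  pair <- toy_pair(30, noise_sd = 0.05, seed = 17)
  rss <- vapply(0:5, function(k) {
    fit_mapping(pair$s, pair$f, k, mu = 0, warn_spectral = FALSE)$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("coefficients are recovered within 5% at 1% relative noise", {
  # parameter-recovery property across sizes and true degrees
  cases <- list(
    list(n = 40, coefs = c(-0.3, 0.05, 0.01), seed = 1),
    list(n = 60, coefs = c(-0.3, 0.05, 0.01, 0.0005), seed = 2),
    list(n = 80, coefs = c(0.02, 0.06, -0.01, 0.002, 3e-4), seed = 3)
  )
  for (cs in cases) {
    s <- generate_modular_sc(cs$n, 4, 0.6, 0.1, seed = cs$seed)
    f0 <- forward_model(s, cs$coefs, global_input = 0.01, noise_sd = 0)
    sig_sd <- sd(vectorize_lower(unclass(f0)))
    f <- forward_model(s, cs$coefs, global_input = 0.01,
                       noise_sd = 0.01 * sig_sd, seed = cs$seed + 100)
    fit <- fit_mapping(s, f, k_max = length(cs$coefs) - 1, mu = "gcv",
                       warn_spectral = FALSE)
    rel_err <- abs(unname(fit$coefficients) - cs$coefs) / abs(cs$coefs)
    expect_lt(max(rel_err), 0.05)
    expect_lt(abs(fit$global_input - 0.01) / 0.01, 0.05)
  }
})

test_that("predict rebuilds the polynomial from raw powers", {
  s <- path_graph_cm(6)
  model <- structure(
    list(coefficients = c(c0 = 0, c1 = 1), global_input = 0, k_max = 1,
         scale_factors = c(1, 1), n_nodes = 6),
    class = "sf_mapping"
  )
  expect_equal(unclass(predict(model, s)), unclass(s), ignore_attr = TRUE)

  model$coefficients <- c(c0 = 0, c1 = 0)
  model$global_input <- 0.5
  expect_equal(unclass(predict(model, s)), matrix(0.5, 6, 6),
               ignore_attr = TRUE)
})

test_that("fit validates label and size agreement", {
  s <- toy_pair(10)$s
  f_small <- generate_correlation_matrix(8, 2, 0.5, seed = 2)
  expect_error(fit_mapping(s, f_small, 1), class = "polyconn_validation_error")
  f_relabel <- connectivity_matrix(unclass(toy_pair(10)$f),
                                   labels = sprintf("x%02d", 1:10),
                                   kind = "functional")
  expect_error(fit_mapping(s, f_relabel, 1),
               class = "polyconn_validation_error")
})

test_that("bootstrap intervals are deterministic, calibrated, and guarded", {
  pair <- toy_pair(30, noise_sd = 0.005, seed = 5)
  ci1 <- bootstrap_ci(pair$s, pair$f, 2, mu = 1e-6, n_boot = 150, seed = 99)
  ci2 <- bootstrap_ci(pair$s, pair$f, 2, mu = 1e-6, n_boot = 150, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$conf.low <= ci1$estimate + 1e-12))
  expect_true(all(ci1$estimate <= ci1$conf.high + 1e-12))

  # interval widths shrink toward zero as the noise vanishes
  near0 <- toy_pair(30, noise_sd = 1e-6, seed = 5)
  ci0 <- bootstrap_ci(near0$s, near0$f, 2, mu = 1e-8, n_boot = 150, seed = 1)
  expect_lt(max(ci0$conf.high - ci0$conf.low), 1e-3)
  wider <- toy_pair(30, noise_sd = 0.05, seed = 5)
  ciw <- bootstrap_ci(wider$s, wider$f, 2, mu = 1e-8, n_boot = 150, seed = 1)
  expect_gt(mean(ciw$conf.high - ciw$conf.low),
            mean(ci0$conf.high - ci0$conf.low))

  expect_error(bootstrap_ci(pair$s, pair$f, 2, mu = 1e-6, n_boot = 50,
                            seed = 1),
               class = "polyconn_parameter_error")
})

test_that("tidy/glance expose the fit as tibbles and JSON round-trips", {
  pair <- toy_pair(20)
  fit <- fit_mapping(pair$s, pair$f, 2, mu = 1e-6, n_boot = 120, seed = 3,
                     warn_spectral = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("G", "c0", "c1", "c2"))
  expect_true(all(c("conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$k_max, 2)

  path <- withr::local_tempfile(fileext = ".json")
  write_mapping(fit, path, provenance = list(seed = 3))
  back <- read_mapping(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$global_input, fit$global_input)
  expect_equal(back$mu, fit$mu)
  expect_equal(unclass(predict(back, pair$s)),
               unclass(predict(fit, pair$s)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
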