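test_that("expected signals invert exactly through the dependence formulas", {
  grid <- expand.grid(g = c(0, 10, 33.3, 75, 100), m = c(-25, 0, 40, 100))
  for (i in seq_len(nrow(grid))) {
    pop <- population_spec("p", g = grid$g[i], m = grid$m[i])
    s <- vapply(condition_labels, function(cl) expected_signal(pop, cl),
                numeric(1))
    expect_equal(unname(s["2DG+Oligo"]), pop$B)  # f = 0 leaves background
    p <- dependence_profile(s["DMSO"], s["2DG"], s["Oligo"], s["2DG+Oligo"])
    expect_equal(p$glucose_dependence, grid$g[i], tolerance = 1e-12)
    expect_equal(p$mitochondrial_dependence, grid$m[i], tolerance = 1e-12)
  }
  # g = 0: glucose inhibition leaves the control signal unchanged
  pop0 <- population_spec("p", g = 0, m = 50)
  expect_equal(expected_signal(pop0, "2DG"), expected_signal(pop0, "DMSO"))
})

test_that("kinetics saturate monotonically and homoharringtonine flattens them", {
  pop <- population_spec("p", g = 50, m = 50)
  times <- c(0, 30, 60, 120, 240, 360)
  k <- simulate_kinetics(pop, times)
  expect_equal(k$signal[1], pop$B)  # t = 0 is pure background
  expect_true(all(diff(k$signal) >= 0))
  expect_lt(max(k$signal), pop$B + pop$k * pop$T0 * 120 + 1e-9)  # saturation cap
  hh <- simulate_kinetics(pop, times, homoharringtonine = TRUE)
  expect_equal(hh$signal, rep(pop$B, length(times)))
  # property: monotone nondecreasing for random parameter draws
  set.seed(4)
  for (i in 1:25) {
    p2 <- population_spec("q", g = runif(1, 0, 100), m = runif(1, -50, 100),
                          T0 = runif(1, 0, 20), B = runif(1, 0, 500),
                          k = runif(1, 0.1, 10))
    expect_true(all(diff(simulate_kinetics(p2, times,
                                           tau = runif(1, 10, 600))$signal) >= -1e-12))
  }
})

test_that("a fixed seed reproduces simulated tables exactly", {
  spec <- simulation_spec(population_spec("p", 40, 60, n_events = 500),
                          seed = 123, n_replicates = 2L)
  s1 <- simulate_experiment(spec)
  s2 <- simulate_experiment(spec)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(simulation_spec(
    population_spec("p", 40, 60, n_events = 500), seed = 124))
  expect_false(identical(s1$tables[[1]]$values, s3$tables[[1]]$values))
})

test_that("the noise-free limit reproduces ground truth through the full pipeline", {
  sim <- simulate_experiment(simulation_spec(
    population_spec("p", g = 35, m = 65, n_events = 200, sigma_log = 0),
    barcode = list(plan = barcode_plan(), hi = 1e4, lo = 1e2, sigma_log10 = 0),
    seed = 5))
  fit <- fit_simulation(sim)
  expect_equal(unname(coef(fit)["p", "glucose_dependence"]), 35,
               tolerance = 1e-9)
  expect_equal(unname(coef(fit)["p", "mitochondrial_dependence"]), 65,
               tolerance = 1e-9)
  expect_equal(unname(fit$accounting["unassigned"]), 0L)
})

test_that("unpooled mode emits per-condition tables that skip demultiplexing", {
  sim <- simulate_experiment(simulation_spec(
    population_spec("p", g = 50, m = 25, n_events = 300),
    pooled = FALSE, seed = 8))
  expect_length(sim$tables, 4L)
  expect_setequal(vapply(sim$tables, function(tb) tb$meta$condition,
                         character(1)), condition_labels)
  expect_false("BC_A" %in% sim$tables[[1]]$channel_names)
  fit <- cencat(sim$tables, sim$cmap, sim$gates)
  expect_equal(unname(coef(fit)["p", "glucose_dependence"]), 50, tolerance = 3)
})

test_that("recovery error shrinks roughly as the square root of events", {
  pts <- list(c(25, 75), c(50, 50), c(75, 25))
  rmse <- vapply(c(500, 5000, 50000), function(n) {
    errs <- unlist(lapply(seq_along(pts), function(i) {
      sim <- simulate_experiment(simulation_spec(
        population_spec("p", g = pts[[i]][1], m = pts[[i]][2], n_events = n),
        seed = 1000L + 10L * i + as.integer(log10(n))))
      cf <- coef(fit_simulation(sim))
      c(cf["p", "glucose_dependence"] - pts[[i]][1],
        cf["p", "mitochondrial_dependence"] - pts[[i]][2])
    }))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_gt(rmse[1] / rmse[3], 3)  # ~ sqrt(100) = 10 expected
})

test_that("preset scenarios encode their advertised phenotypes", {
  sc <- preset_scenarios(seed = 2, n_events = 2000)
  expect_setequal(names(sc), c("classical_macrophage", "alternative_macrophage",
                               "naive_T_quiescent", "T_MITA", "tissue_panel"))
  cls <- coef(fit_simulation(simulate_experiment(sc$classical_macrophage)))
  alt <- coef(fit_simulation(simulate_experiment(sc$alternative_macrophage)))
  expect_gt(cls["macrophage", "glycolytic_capacity"],
            alt["macrophage", "glycolytic_capacity"])
  expect_lt(cls["macrophage", "mitochondrial_dependence"],
            alt["macrophage", "mitochondrial_dependence"])

  mita <- fit_simulation(simulate_experiment(sc$T_MITA))
  expect_lt(coef(mita)["T_cell", "mitochondrial_dependence"], 0)
  expect_match(mita$profiles$flags, "MITA")

  quiet <- fit_simulation(simulate_experiment(sc$naive_T_quiescent))
  expect_match(quiet$profiles$flags, "LOW_RESOLUTION")

  panel <- sc$tissue_panel
  expect_length(panel, 12L)
  expect_setequal(unique(vapply(panel, function(s) s$meta$tissue, character(1))),
                  c("spleen", "liver", "lung", "kidney"))
})
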