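test_that("geometric MFI matches closed forms and counts drops", {
  expect_equal(geometric_mfi(rep(7.3, 30))$gmfi, 7.3)
  expect_equal(geometric_mfi(c(rep(1, 15), rep(100, 15)))$gmfi, 10)
  r <- geometric_mfi(c(rep(50, 40), 0, -3), error_events = 10L)
  expect_equal(r$n_dropped, 2L)
  expect_equal(r$n_events, 40L)
  expect_true(r$low_n)
  expect_error(geometric_mfi(rep(1, 10), context = "mono/DMSO"), "mono/DMSO")
})

test_that("geometric MFI of lognormal draws converges to exp(mu)", {
  set.seed(99)
  x <- rlnorm(50000, meanlog = log(500), sdlog = 0.25)
  expect_equal(geometric_mfi(x)$gmfi, 500, tolerance = 0.02)
  # arithmetic alternative is the plain mean
  expect_equal(geometric_mfi(c(10, 20, 30, 40) * 1.0, error_events = 2L,
                             statistic = "arithmetic")$gmfi, 25)
})

test_that("dependence_profile reproduces the worked ratio examples", {
  p <- dependence_profile(1000, 400, 700, 200)
  expect_equal(p$glucose_dependence, 75)
  expect_equal(p$mitochondrial_dependence, 37.5)
  expect_equal(p$glycolytic_capacity, 62.5)
  expect_equal(p$faoaao_capacity, 25)
  expect_equal(p$delta_mfi, 800)
  expect_length(p$flags, 0L)

  z <- dependence_profile(1000, 1000, 1000, 200)
  expect_equal(z$glucose_dependence, 0)
  expect_equal(z$glycolytic_capacity, 100)

  m <- dependence_profile(1000, 300, 1200, 200)
  expect_equal(m$mitochondrial_dependence, -25)
  expect_true("MITA" %in% m$flags)
  expect_true("OUT_OF_RANGE" %in% m$flags)

  expect_error(dependence_profile(1000, 400, 700, 1000), "undefined profile")
  expect_error(dependence_profile(1000, 400, 700, 1100), "undefined profile")
})

test_that("profiles agree with an independent formula oracle on random quadruples", {
  q <- random_quadruples(500, seed = 7)
  for (i in seq_len(nrow(q))) {
    p <- dependence_profile(q$dmso[i], q$x2dg[i], q$oligo[i], q$both[i])
    o <- oracle_profile(q$dmso[i], q$x2dg[i], q$oligo[i], q$both[i])
    expect_equal(p$glucose_dependence, unname(o["glucose"]), tolerance = 1e-12)
    expect_equal(p$mitochondrial_dependence, unname(o["mito"]), tolerance = 1e-12)
    # capacities are exact complements by construction; the sums are 100
    # to floating-point rounding
    expect_identical(p$faoaao_capacity, 100 - p$glucose_dependence)
    expect_identical(p$glycolytic_capacity, 100 - p$mitochondrial_dependence)
    expect_equal(p$glucose_dependence + p$faoaao_capacity, 100,
                 tolerance = 1e-13)
  }
})

test_that("LOW_RESOLUTION flag and clamping behave as reporting-layer QC", {
  p <- dependence_profile(105, 101, 103, 100, resolution_floor = 10)
  expect_true("LOW_RESOLUTION" %in% p$flags)
  m <- dependence_profile(1000, 1100, 700, 200)  # glucose < 0
  expect_true("NEGATIVE_GLUCOSE_DEP" %in% m$flags)
  cl <- clamp_profile(m)
  expect_equal(cl$glucose_dependence, 0)
  expect_equal(m$glucose_dependence, -12.5)  # raw value untouched
  expect_identical(cl$flags, m$flags)
})

test_that("fold change is the within-donor control-condition ratio", {
  expect_equal(fold_change(500, 500)$fold_change, 1)
  expect_equal(fold_change(2000, 500)$fold_change, 4)
  expect_error(fold_change(0, 10), "positive")
})

test_that("a stimulation multiplier on translation is recovered as fold change", {
  s <- 4
  base <- population_spec("T", g = 60, m = 40, n_events = 5000, B = 0)
  stim <- population_spec("T", g = 60, m = 40, n_events = 5000, B = 0,
                          stim_multiplier = s)
  g_medium <- geometric_mfi(simulate_experiment(simulation_spec(
    base, seed = 21))$tables[[1]]$values[1:5000, "ncAA"])$gmfi
  g_stim <- geometric_mfi(simulate_experiment(simulation_spec(
    stim, seed = 22))$tables[[1]]$values[1:5000, "ncAA"])$gmfi
  expect_equal(fold_change(g_stim, g_medium)$fold_change, s, tolerance = 0.05)
})

test_that("replicate aggregation policies agree where they must and differ predictably", {
  mk <- function(gmfis) {
    data.frame(population = "p",
               condition = rep(condition_labels, each = 2),
               replicate_id = rep(c("1", "2"), 4),
               gmfi = gmfis)
  }
  # identical replicates: both policies give the same profile
  mfi_same <- mk(rep(c(1000, 400, 700, 200), each = 2))
  p1 <- aggregate_replicates(mfi_same, "mean_of_gmfi_before_formula")$p
  p2 <- aggregate_replicates(mfi_same, "profile_per_replicate_then_mean")$p
  expect_equal(p1$glucose_dependence, p2$glucose_dependence)
  expect_equal(p1$glucose_dependence, 75)

  # duplicate gMFIs (900,1100),(380,420),(680,720),(190,210): means give
  # the canonical (1000,400,700,200) profile
  mfi_dup <- mk(c(900, 1100, 380, 420, 680, 720, 190, 210))
  pd <- aggregate_replicates(mfi_dup, "mean_of_gmfi_before_formula")$p
  expect_equal(pd$glucose_dependence, 75)
  expect_equal(pd$mitochondrial_dependence, 37.5)

  # heteroscedastic replicates: the two paths differ by exactly the
  # difference between the two explicit computations
  mfi_het <- mk(c(800, 1600, 300, 500, 600, 900, 100, 400))
  pa <- aggregate_replicates(mfi_het, "mean_of_gmfi_before_formula")$p
  pb <- aggregate_replicates(mfi_het, "profile_per_replicate_then_mean")$p
  path_a <- oracle_profile(1200, 400, 750, 250)
  path_b <- (oracle_profile(800, 300, 600, 100) +
               oracle_profile(1600, 500, 900, 400)) / 2
  expect_equal(pa$glucose_dependence, unname(path_a["glucose"]))
  expect_equal(pb$glucose_dependence, unname(path_b["glucose"]))
  expect_equal(pa$mitochondrial_dependence - pb$mitochondrial_dependence,
               unname(path_a["mito"] - path_b["mito"]))

  # a missing condition names itself
  expect_error(aggregate_replicates(mfi_same[mfi_same$condition != "Oligo", ]),
               "Oligo")
})

test_that("seahorse glycolytic capacity is the ECAR difference", {
  expect_equal(seahorse_glycolytic_capacity(10, 25)$capacity, 15)
  expect_equal(seahorse_glycolytic_capacity(25, 25)$capacity, 0)
  r <- seahorse_glycolytic_capacity(25, 10)
  expect_equal(r$capacity, -15)
  expect_equal(r$flags, "NEGATIVE_CAPACITY")
})
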