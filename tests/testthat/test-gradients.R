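test_that("density from weighing is mass over volume", {
  expect_equal(density_from_weighing(1.0, 1.0), 1.0)
  expect_equal(density_from_weighing(0.8914, 0.5), 1.7828)
  expect_equal(density_from_weighing(0.1779, 0.1), 1.779)
  expect_error(density_from_weighing(0, 1), class = "sipef_invalid_argument")
  expect_error(density_from_weighing(1, -2), class = "sipef_invalid_argument")
})

test_that("build_profile sorts, validates and rejects duplicates", {
  rec <- data.frame(gradient_id = "g1", fraction_index = c(3, 1, 7, 5, 2, 6, 4),
                    density = c(1.81, 1.84, 1.76, 1.79, 1.83, 1.77, 1.80),
                    measured_copies = 1:7)
  p <- build_profile(rec, "12C")
  expect_true(all(diff(p$fractions$density) < 0))
  # fraction_index is collection order only; density governs the sort
  expect_equal(p$fractions$fraction_index, c(1, 2, 3, 4, 5, 6, 7))
  dup <- rbind(rec, rec[3, ])
  expect_error(build_profile(dup, "12C"), class = "sipef_duplicate_record")
  expect_error(build_profile(rec[1, ], "12C"), class = "sipef_insufficient_data")
})

test_that("greedy pool selection reproduces the hand-worked example", {
  # masses heaviest -> lightest; min_mass 120:
  # heavy run 5+20+60+200 = 285 first reaches 120 at fraction 4;
  # light run 15+300 = 315 first reaches it at fraction 6
  p12 <- profile_from_masses(c(5, 20, 60, 200, 400, 300, 15))
  p13 <- profile_from_masses(c(400, 200, 60, 20, 5, 15, 300), gradient_id = "g2",
                             isotope = "13C")
  pools <- select_pools(p12, p13, min_mass = 120, heavy_cutoff = NULL)
  expect_equal(pools[["12C-heavy"]]$members$fraction_index, 1:4)
  expect_equal(pools[["12C-light"]]$members$fraction_index, c(7, 6))
  expect_equal(pools[["12C-heavy"]]$pooled_mass, 285)
  expect_equal(pools[["12C-light"]]$pooled_mass, 315)
  # every pool meets the mass constraint and pools of one isotope are disjoint
  for (p in pools) expect_gte(p$pooled_mass, 120)
  expect_length(intersect(pools[["13C-heavy"]]$members$fraction_index,
                          pools[["13C-light"]]$members$fraction_index), 0)
})

test_that("a sharp heavy 13C band above the cutoff pools a single fraction", {
  p12 <- profile_from_masses(c(5, 20, 60, 200, 400, 300, 15))
  p13 <- profile_from_masses(c(900, 30, 10, 5, 5, 20, 500), gradient_id = "g2",
                             isotope = "13C")
  pools <- select_pools(p12, p13, min_mass = 120, heavy_cutoff = 1.815)
  expect_equal(pools[["13C-heavy"]]$members$fraction_index, 1)
  # realized window is that fraction's width (0.015 g/ml here)
  expect_equal(diff(pools[["13C-heavy"]]$density_window), 0.105 / 7,
               tolerance = 1e-12)
})

test_that("infeasible mass constraints raise the documented error", {
  thin <- profile_from_masses(rep(10, 7))
  expect_error(select_pools(thin, thin, min_mass = 120, heavy_cutoff = NULL),
               class = "sipef_pool_infeasible")
  # feasible in total but not disjointly: both runs need > half the gradient
  p <- profile_from_masses(c(40, 40, 40, 40, 40, 40, 40))
  expect_error(select_pools(p, p, min_mass = 160, heavy_cutoff = NULL),
               class = "sipef_pool_infeasible")
  # 13C-heavy infeasible above the cutoff is named in the error
  p13 <- profile_from_masses(c(1, 1, 1, 200, 200, 200, 200), gradient_id = "g2",
                             isotope = "13C")
  err <- tryCatch(select_pools(p, p13, min_mass = 120, heavy_cutoff = 1.815),
                  error = identity)
  expect_s3_class(err, "sipef_pool_infeasible")
  expect_match(conditionMessage(err), "13C-heavy")
})

test_that("duplicate gradients are merged by density and selection is deterministic", {
  a <- profile_from_masses(c(5, 20, 60, 100, 200, 150, 10))
  b <- profile_from_masses(c(6, 18, 55, 110, 190, 160, 12), gradient_id = "gB")
  pools <- select_pools(list(a, b), list(a, b), min_mass = 120, heavy_cutoff = NULL)
  pools2 <- select_pools(list(a, b), list(a, b), min_mass = 120, heavy_cutoff = NULL)
  expect_identical(pools, pools2)
  # members from both gradients within the shared window
  expect_setequal(unique(pools[["12C-heavy"]]$members$gradient_id), c("g1", "gB"))
})

test_that("fixed windows select fractions by density, ignoring min_mass", {
  p12 <- profile_from_masses(c(5, 20, 60, 200, 400, 300, 15))
  p13 <- profile_from_masses(c(400, 200, 60, 20, 5, 15, 300), gradient_id = "g2",
                             isotope = "13C")
  cfg <- sim_config()
  w <- list(
    `12C-heavy` = fraction_window(cfg, 1:4), `12C-light` = fraction_window(cfg, 6:7),
    `13C-heavy` = fraction_window(cfg, 1:4), `13C-light` = fraction_window(cfg, 6:7)
  )
  pools <- select_pools(p12, p13, windows = w)
  expect_equal(pools[["12C-heavy"]]$members$fraction_index, 1:4)
  expect_equal(pools[["13C-light"]]$members$fraction_index, c(6, 7))
})

test_that("simulated labeled vs control gradients pool at distinct densities", {
  cfg <- run_config(seed = 21)
  exp <- simulate_experiment(cfg)
  pools <- exp$pools
  mw_density <- function(p) with(p$members, sum(density * mass) / sum(mass))
  expect_gt(mw_density(pools[["13C-heavy"]]), mw_density(pools[["12C-heavy"]]))
  expect_gt(pools[["13C-heavy"]]$density_window[1],
            pools[["12C-heavy"]]$density_window[1])
})
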