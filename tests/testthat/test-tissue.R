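test_that("probe presets have the documented site counts and unique layouts", {
  expect_equal(nrow(build_probe("tetrode")$sites), 4)
  expect_equal(nrow(build_probe("polytrode_8x4")$sites), 32)
  one <- build_probe("custom", coords = matrix(0, 1, 3))
  expect_equal(nrow(one$sites), 1)
  expect_equal(unname(one$sites[1, ]), c(0, 0, 0))
  expect_error(build_probe("custom"), class = "spikebench_configuration_error")
  expect_error(build_probe("custom", coords = matrix(0, 2, 3)),
               class = "spikebench_validation_error")
})

test_that("probe JSON round trip preserves geometry", {
  p <- build_probe("polytrode_8x4")
  path <- withr::local_tempfile(fileext = ".json")
  write_probe(p, path)
  q <- read_probe(path)
  expect_equal(q$sites, p$sites)
  expect_equal(q$site_diameter, p$site_diameter)
})

test_that("positioned probes land inside the volume or fail loudly", {
  vol <- tissue_cube(volume_mm3 = 1.5)
  p <- position_probe(build_probe("polytrode_8x4"), vol)
  expect_true(all(p$sites >= 0 & p$sites <= vol$dimensions[1]))
  small <- tissue_volume(c(50, 50, 50),
                         list(layer_spec("l", 50, 0, awake_rate_model())))
  expect_error(position_probe(build_probe("polytrode_8x4"), small),
               class = "spikebench_validation_error")
})

test_that("per-layer unit counts equal round(density x sub-volume)", {
  # 1.5 mm^3 at 300,000/mm^3 -> 450,000 units
  pop <- place_neurons(tissue_cube(), seed = 1)
  expect_equal(nrow(pop), 450000)
  # stratum pyramidale slab: 1 x 1 mm footprint, 55 um, 272,400/mm^3
  sp <- tissue_volume(c(1000, 1000, 55),
                      list(layer_spec("sp", 55, 272400, awake_rate_model())))
  np <- nrow(place_neurons(sp, seed = 1))
  expect_equal(np, round(272400 * 0.055))
  expect_equal(np, 14982)
  # zero density -> empty population
  empty <- place_neurons(tissue_cube(volume_mm3 = 0.1, density = 0), seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("positions fall inside their layer slabs and placement is seeded", {
  layers <- list(
    layer_spec("a", 100, 5e4, awake_rate_model()),
    layer_spec("b", 200, 2e4, awake_rate_model()))
  vol <- tissue_volume(c(500, 500, 300), layers)
  pop <- place_neurons(vol, seed = 11)
  expect_true(all(pop$z[pop$layer_id == 1] >= 0 &
                    pop$z[pop$layer_id == 1] < 100))
  expect_true(all(pop$z[pop$layer_id == 2] >= 100 &
                    pop$z[pop$layer_id == 2] < 300))
  expect_true(all(pop$x >= 0 & pop$x <= 500 & pop$y >= 0 & pop$y <= 500))
  pop2 <- place_neurons(vol, seed = 11)
  expect_identical(pop, pop2)
  expect_false(identical(pop, place_neurons(vol, seed = 12)))
})

test_that("active counts follow round(active_fraction x n)", {
  vol <- tissue_cube(volume_mm3 = 0.01, density = 1e5, active_fraction = 0.1)
  pop <- place_neurons(vol, seed = 3)
  expect_equal(sum(pop$active), 100)
})

test_that("cell-type assignment is exact proportional rounding", {
  vol <- tissue_cube(volume_mm3 = 0.0001, density = 1e5)  # 10 units
  pop <- assign_types(place_neurons(vol, seed = 1), 0.8, seed = 2)
  expect_equal(sum(pop$cell_type == "pyramidal"), 8)
  vol1k <- tissue_cube(volume_mm3 = 0.01, density = 1e5)  # 1000 units
  pop1k <- assign_types(place_neurons(vol1k, seed = 1), 0.8, seed = 2)
  expect_equal(sum(pop1k$cell_type == "pyramidal"), 800)
  all_pyr <- assign_types(pop, 1, seed = 2)
  expect_true(all(all_pyr$cell_type == "pyramidal"))
  expect_error(assign_types(pop, 1.2), class = "spikebench_validation_error")
})

test_that("interneuron rates are the pyramidal law scaled by the factor", {
  vol <- tissue_cube(volume_mm3 = 0.01, density = 1e5,
                     rate_model = firing_rate_model("uniform_bounds",
                                                    min_rate = 0.5,
                                                    max_rate = 5))
  pop <- assign_types(place_neurons(vol, seed = 1), 0.8, seed = 2)
  pop <- assign_rates(pop, interneuron_factor = 5, seed = 3)
  int_r <- pop$rate[pop$cell_type == "interneuron"]
  pyr_r <- pop$rate[pop$cell_type == "pyramidal"]
  expect_true(all(pyr_r >= 0.5 & pyr_r <= 5))
  expect_true(all(int_r >= 2.5 & int_r <= 25))
  # factor 1: same law for both types
  p1 <- assign_rates(pop, interneuron_factor = 1, seed = 4)
  expect_true(all(p1$rate >= 0.5 & p1$rate <= 5))
  expect_error(assign_rates(pop, interneuron_factor = -1),
               class = "spikebench_validation_error")
})

test_that("drawn uniform rates are consistent with the configured law", {
  m <- firing_rate_model("uniform_bounds", min_rate = 0.5, max_rate = 12)
  vol <- tissue_cube(volume_mm3 = 0.1, density = 1e5, rate_model = m)
  pop <- assign_types(place_neurons(vol, seed = 5), 1, seed = 5)
  pop <- assign_rates(pop, seed = 5)
  draws <- pop$rate[seq_len(10000)]
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 0.5, 12))
  expect_gt(ks$p.value, 0.01)
})

test_that("other rate families draw positive rates with the right shape", {
  gp <- firing_rate_model("generalized_pareto", location = 0.1, scale = 1,
                          shape = 0.2)
  r <- with_seed_draws(gp, 5000)
  expect_true(all(r > 0))
  expect_gt(mean(r), 1)  # heavy-tailed above the exponential location
  lg <- firing_rate_model("logistic", location = 0.4, scale = 0.04)
  rl <- with_seed_draws(lg, 5000)
  expect_true(all(rl >= 0.01))
  expect_equal(median(rl), 0.4, tolerance = 0.05)
  ct <- firing_rate_model("custom_table", rates = c(1, 2, 4))
  rc <- with_seed_draws(ct, 100)
  expect_true(all(rc %in% c(1, 2, 4)))
})
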