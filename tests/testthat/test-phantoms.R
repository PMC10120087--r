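test_that("flat phantoms are constant and seed maps carry the margin", {
  ph <- make_phantom(phantom_spec("flat", fov = c(16, 20), margin = 10,
                                  flat_tau = 1, flat_amp = 1, seed = 1))
  expect_equal(dim(ph$a), c(16, 30))
  expect_true(all(ph$a == 1) && all(ph$tau == 1))
})

test_that("bead phantoms have exactly the population lifetimes on lit pixels", {
  spec <- phantom_spec("beads", fov = c(48, 48), margin = 12,
                       bead_params = list(
                         list(radius = 4, lifetime = 2.1, count = 4),
                         list(radius = 8, lifetime = 4.0, count = 2)),
                       seed = 5)
  ph <- make_phantom(spec)
  expect_setequal(unique(ph$tau[ph$a > 0]), c(2.1, 4.0))
  expect_true(all(ph$a >= 0))
  ph2 <- make_phantom(spec)
  expect_identical(ph, ph2)                    # determinism
})

test_that("infeasible bead packing fails after bounded retries", {
  spec <- phantom_spec("beads", fov = c(16, 16), margin = 0,
                       bead_params = list(list(radius = 6, lifetime = 2,
                                               count = 30)),
                       seed = 2)
  expect_error(make_phantom(spec), "infeasible bead packing")
})

test_that("texture phantoms stay inside the configured lifetime range", {
  for (kind in c("cell_like", "random_texture")) {
    ph <- make_phantom(phantom_spec(kind, fov = c(32, 40), margin = 8,
                                    lifetime_range = c(0.3, 6), seed = 3))
    expect_true(all(ph$tau >= 0.3 & ph$tau <= 6))
    expect_true(all(ph$a >= 0))
  }
})

test_that("dataset generation writes consistent triplets with the stated split", {
  dir <- withr::local_tempdir()
  cfg <- narrow_config()
  det <- detector_config()
  spec <- phantom_spec("mixed", fov = c(16, 24), margin = 6, seed = 21,
                       bead_params = list(list(radius = 2, lifetime = 2.1,
                                               count = 3)))
  man <- generate_dataset(8, spec, cfg, det, dir, seed = 21)
  expect_equal(table(vapply(man$items, `[[`, "", "split"))[c("train", "val", "test")],
               c(train = 6, val = 1, test = 1), ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (it in man$items) {
    q <- read_image(file.path(dir, it$cmos))
    s <- read_image(file.path(dir, it$iccd))
    lab <- read_image(file.path(dir, it$tau))
    expect_equal(dim(lab), c(16, 24))
    expect_equal(dim(q), dim(s))
    expect_true(all(lab >= 0.1 & lab <= 8))
  }
})

test_that("generated images equal a fresh forward render of their recorded seeds", {
  dir <- withr::local_tempdir()
  cfg <- narrow_config()
  det <- detector_config()
  spec <- phantom_spec("beads", fov = c(16, 24), margin = 6, seed = 31,
                       bead_params = list(list(radius = 3, lifetime = 2.1,
                                               count = 3)))
  man <- generate_dataset(3, spec, cfg, det, dir, seed = 31)
  it <- man$items[[2]]
  spec_i <- spec; spec_i$seed <- it$phantom_seed
  ph <- make_phantom(spec_i)
  s_clean <- simulate_iccd(ph$tau, ph$a, cfg, fov_width = 24)
  s_noisy <- sample_noisy_iccd(s_clean, det, seed = it$noise_seed)
  expect_equal(read_image(file.path(dir, it$iccd)), unclass(s_noisy),
               tolerance = 1e-6, ignore_attr = TRUE)  # float32 rounding
  expect_equal(read_image(file.path(dir, it$cmos)),
               unclass(simulate_cmos(ph$tau, ph$a, cfg, fov_width = 24)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a dataset regenerated from its manifest is bit-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- narrow_config()
  spec <- phantom_spec("mixed", fov = c(16, 24), margin = 6, seed = 77,
                       bead_params = list(list(radius = 2, lifetime = 2.1,
                                               count = 3)))
  generate_dataset(4, spec, cfg, detector_config(), d1, seed = 77)
  regenerate_dataset(file.path(d1, "manifest.json"), d2)
  for (f in list.files(d1, pattern = "[.]tif$")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("phantom margin below the shear extent is rejected", {
  cfg <- system_config(y = 10L)
  spec <- phantom_spec("flat", fov = c(16, 60), margin = 10, seed = 1)
  expect_error(generate_dataset(1, spec, cfg, detector_config(),
                                withr::local_tempdir()),
               "margin")
})
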