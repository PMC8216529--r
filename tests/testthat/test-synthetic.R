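test_that("cohort counting and dimensions follow the protocol", {
  p <- cohort_params(n_per_group = 2, duration_s = 2, n_trials = 3, seed = 1)
  co <- simulate_cohort(p)
  expect_length(co$recordings, 2 * 2 * 2 * 3)   # subjects x tasks x trials
  expect_equal(nrow(co$subjects), 4)
  expect_setequal(unique(co$subjects$group), c("CNP", "control"))

  r <- co$recordings[[1]]
  expect_equal(dim(r$samples), c(2 * 1000, 6))
  expect_identical(colnames(r$samples), emg_channels())
  expect_true(all(is.finite(r$samples)))

  man <- cohort_manifest(co)
  expect_equal(nrow(man), length(co$recordings))
})

test_that("generation is deterministic and independent of order", {
  p <- cohort_params(n_per_group = 1, duration_s = 1, n_trials = 1, seed = 42)
  a <- generate_recording(p, "sub001", "CNP", "curvilinear", 1)
  # interleave other generation to perturb the global RNG stream
  set.seed(999); rnorm(10)
  generate_recording(p, "sub002", "control", "rectilinear", 1)
  b <- generate_recording(p, "sub001", "CNP", "curvilinear", 1)
  expect_identical(a$samples, b$samples)
  # different trial/task/subject gives a different stream
  expect_false(identical(
    a$samples, generate_recording(p, "sub001", "CNP", "curvilinear", 2)$samples))
})

test_that("cohort files regenerate bit-identically from the same seed", {
  p <- cohort_params(n_per_group = 1, duration_s = 1, n_trials = 1, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(p, d1)
  generate_cohort(p, d2)
  for (f in c("manifest.csv", "recordings/sub001_rectilinear_t1.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(generate_cohort(p, d1), "overwrite")
  co <- read_cohort(d1)
  expect_equal(length(co$recordings), 4)  # 2 subjects x 2 tasks x 1 trial
  expect_equal(co$recordings[[1]]$samples,
               simulate_cohort(p)$recordings[[1]]$samples,
               tolerance = 1e-12)
})

test_that("expected_msc is the product of shared-power fractions", {
  mk <- function(g1, g2) {
    drives <- list(list(name = "delta", band = c(1, 4),
                        channels = c("SCM_L", "SC_L"),
                        gamma = list(
                          list(group = "all", task = "all",
                               channels = "SCM_L", value = g1),
                          list(group = "all", task = "all",
                               channels = "SC_L", value = g2))))
    cohort_params(n_per_group = 1, duration_s = 1, band_drives = drives)
  }
  expect_equal(expected_msc(mk(1, 1), c("SCM_L", "SC_L"), "delta"), 1)
  expect_equal(expected_msc(mk(0.5, 0.5), c("SCM_L", "SC_L"), "delta"), 0.25)
  expect_equal(expected_msc(mk(0.9, 0), c("SCM_L", "SC_L"), "delta"), 0)
  # channel outside the drive's pair set has no shared power
  expect_equal(expected_msc(mk(1, 1), c("SCM_L", "UT_R"), "delta"), 0)
  # band not configured as a drive
  expect_equal(expected_msc(mk(1, 1), c("SCM_L", "SC_L"), "beta"), 0)
  # numeric band spec matches too
  expect_equal(expected_msc(mk(0.5, 0.5), c("SCM_L", "SC_L"), c(1, 4)), 0.25)
})

test_that("invalid generator parameters are rejected", {
  bad_band <- list(list(name = "x", band = c(5, 4), channels = emg_channels(),
                        gamma = list(list(group = "all", task = "all",
                                          channels = "all", value = 0.5))))
  expect_error(cohort_params(band_drives = bad_band), "lo >= hi")
  bad_hi <- list(list(name = "x", band = c(5, 600), channels = emg_channels(),
                      gamma = list(list(group = "all", task = "all",
                                        channels = "all", value = 0.5))))
  expect_error(cohort_params(band_drives = bad_hi), "fs/2")
  bad_gamma <- list(list(name = "x", band = c(1, 4), channels = emg_channels(),
                         gamma = list(list(group = "all", task = "all",
                                           channels = "all", value = 1.5))))
  expect_error(cohort_params(band_drives = bad_gamma), "\\[0, 1\\]")
  expect_error(cohort_params(duration_s = 1.0005), "integer sample count")
})

test_that("doubling amplitude_scale scales amplitude features by the right law", {
  scale_rules <- function(v) list(list(group = "all", task = "all",
                                       channels = "all", value = v))
  base <- cohort_params(n_per_group = 1, duration_s = 2, n_trials = 1,
                        noise_floor = 0, seed = 3,
                        amplitude_scale = scale_rules(1))
  doubled <- cohort_params(n_per_group = 1, duration_s = 2, n_trials = 1,
                           noise_floor = 0, seed = 3,
                           amplitude_scale = scale_rules(2))
  a <- generate_recording(base, "sub001", "control", "rectilinear")$samples[, 1]
  b <- generate_recording(doubled, "sub001", "control", "rectilinear")$samples[, 1]
  fa <- time_features(a); fb <- time_features(b)
  expect_equal(fb[c("MAV", "RMS")], 2 * fa[c("MAV", "RMS")], tolerance = 1e-12)
  expect_equal(fb[c("VAR", "SSI")], 4 * fa[c("VAR", "SSI")], tolerance = 1e-12)
})

test_that("a fully shared drive with flat envelope gives near-unit band MSC", {
  drives <- list(list(name = "delta", band = c(1, 4),
                      channels = c("SCM_L", "SC_L"),
                      gamma = list(list(group = "all", task = "all",
                                        channels = "all", value = 1))))
  p <- cohort_params(n_per_group = 1, duration_s = 30, n_trials = 1,
                     noise_floor = 0, envelope = "flat",
                     band_drives = drives, seed = 9)
  r <- generate_recording(p, "sub001", "control", "rectilinear")
  s <- msc(r$samples[, "SCM_L"], r$samples[, "SC_L"], p$fs)
  expect_gt(band_msc(s, "delta"), 0.95)
})
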