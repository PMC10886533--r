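test_that("constructor enforces DVH invariants", {
  d <- dvh("organ", c(0, 10, 20, 30), c(10, 20, 30))
  expect_equal(d$total_volume, 60)
  expect_error(dvh("x", c(1, 2, 3), c(1, 1)), "first")
  expect_error(dvh("x", c(0, 2, 2), c(1, 1)), "increasing")
  expect_error(dvh("x", c(0, 1, 2), c(1, -1)), "negative")
  expect_error(dvh("x", c(0, 1), c(1, 1)), "one more")
})

test_that("cumulative and differential forms round-trip exactly", {
  d <- dvh("organ", c(0, 10, 20, 30), c(10, 20, 30))
  cum <- to_cumulative(d)
  expect_equal(cum$dose, c(0, 10, 20))
  expect_equal(cum$volume_cc, c(60, 50, 30))
  back <- dvh_from_cumulative("organ", cum$dose, cum$volume_cc)
  expect_equal(back$edges, d$edges)
  expect_equal(back$bin_volume, d$bin_volume)

  # with an explicit trailing zero
  d2 <- dvh_from_cumulative("organ", c(0, 10, 20, 30), c(60, 50, 30, 0))
  expect_equal(d2$bin_volume, c(10, 20, 30))

  # single-bin DVH: all volume at or above 0
  d3 <- dvh("organ", c(0, 5), 42)
  expect_equal(to_cumulative(d3)$volume_cc, 42)

  # property: exact round trip on random DVHs
  set.seed(11)
  for (i in 1:25) {
    d <- random_dvh()
    cum <- to_cumulative(d)
    expect_true(all(diff(cum$volume_cc) <= 1e-12))
    expect_equal(cum$volume_cc[1], d$total_volume)
    back <- dvh_from_cumulative(d$structure, cum$dose, cum$volume_cc)
    # the inferred final edge differs only when the last bin width differs
    expect_equal(back$bin_volume, d$bin_volume, tolerance = 1e-12)
    expect_equal(back$edges[-length(back$edges)],
                 d$edges[-length(d$edges)], tolerance = 1e-12)
  }
})

test_that("non-monotone cumulative volumes are rejected", {
  expect_error(dvh_from_cumulative("x", c(0, 10, 20), c(60, 65, 30)),
               "non-increasing")
})

test_that("mean dose matches the weighted-sum oracle and symmetry cases", {
  expect_equal(mean_dose(dvh("x", c(0, 20), 100)), 10)  # uniform: midpoint
  expect_equal(mean_dose(dvh("x", c(0, 1, 19, 20), c(50, 0, 50))), 10)
  set.seed(7)
  for (i in 1:20) {
    d <- random_dvh(5)
    v <- d$bin_volume / d$total_volume
    mids <- (d$edges[-6] + d$edges[-1]) / 2
    expect_equal(mean_dose(d), sum(v * mids), tolerance = 1e-12)
  }
  expect_error(mean_dose(dvh("x", c(0, 1), 0)), "zero total volume")
})

test_that("mean dose is stable under volume-conserving bin splitting", {
  d <- dvh("x", c(0, 4, 8, 12), c(30, 20, 10))
  split_edges <- c(0, 2, 4, 6, 8, 10, 12)
  d2 <- dvh("x", split_edges, c(15, 15, 10, 10, 5, 5))
  expect_lt(abs(mean_dose(d2) - mean_dose(d)), 2)  # < half the bin width
})

test_that("volume_at_dose interpolates the cumulative curve", {
  d <- dvh("x", c(0, 10, 20, 30), c(10, 20, 30))
  expect_equal(volume_at_dose(d, 0), 60)
  expect_equal(volume_at_dose(d, 10), 50)  # exact edge
  expect_equal(volume_at_dose(d, 15), 40)  # midway between 50 and 30
  expect_equal(volume_at_dose(d, 35), 0)   # above max dose
  expect_equal(volume_at_dose(d, 15, unit = "percent"), 100 * 40 / 60)
  # non-increasing in threshold
  thr <- seq(0, 35, by = 0.5)
  expect_true(all(diff(volume_at_dose(d, thr)) <= 1e-12))
})

test_that("dose_at_volume inverts volume_at_dose", {
  d <- dvh("x", c(0, 10, 20, 30), c(10, 20, 30))
  expect_equal(dose_at_volume(d, 60), 0)
  expect_equal(dose_at_volume(d, 50), 10)
  for (t in c(3.7, 12.2, 24.9)) {  # strictly inside bins
    expect_equal(dose_at_volume(d, volume_at_dose(d, t)), t,
                 tolerance = 1e-10)
  }
  expect_error(dose_at_volume(d, 0), "outside")
  expect_error(dose_at_volume(d, 61), "outside")
})

test_that("DVH CSV files read, write and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,dose_gy,volume_cc,kind",
               "organ,0,10,differential",
               "organ,10,20,differential",
               "organ,20,30,differential"), path)
  d <- read_dvh_csv(path)$organ
  expect_equal(d$total_volume, 60)
  expect_equal(d$edges, c(0, 10, 20, 30))

  writeLines(c("structure,dose_gy,volume_cc,kind",
               "organ,0,60,cumulative",
               "organ,10,50,cumulative",
               "organ,20,30,cumulative",
               "organ,30,0,cumulative"), path)
  d <- read_dvh_csv(path)$organ
  expect_equal(d$bin_volume, c(10, 20, 30))

  writeLines(c("structure,dose_gy,volume_cc,kind",
               "organ,0,60,cumulative",
               "organ,10,65,cumulative",
               "organ,20,30,cumulative"), path)
  expect_error(read_dvh_csv(path), "non-increasing")

  writeLines(c("structure,dose_gy,volume_cc,kind",
               "organ,0,60,cumulative",
               "organ,10,oops,cumulative"), path)
  expect_error(read_dvh_csv(path), "line")

  # write -> read round trip on a random multi-structure set
  set.seed(3)
  ds <- list(a = random_dvh(), b = random_dvh())
  ds$a$structure <- "a"; ds$b$structure <- "b"
  write_dvh_csv(ds, path)
  back <- read_dvh_csv(path)
  expect_equal(back$a$bin_volume, ds$a$bin_volume, tolerance = 1e-12)
  # the final right edge is inferred from the last spacing on read; all
  # stored edges and volumes round-trip exactly
  expect_equal(back$b$edges[-length(back$b$edges)],
               ds$b$edges[-length(ds$b$edges)], tolerance = 1e-12)
  expect_equal(back$b$bin_volume, ds$b$bin_volume, tolerance = 1e-12)
})

test_that("plan and patient records validate structure consistency", {
  d <- function(s) dvh(s, c(0, 10, 20), c(5, 5))
  pl <- function(m, structs) plan_record("P1", m, 30, 15,
                                         sapply(structs, d, simplify = FALSE))
  expect_error(plan_record("P1", "3D", 30, 15, list(liver = d("liver"))),
               "body")
  p1 <- pl("3D", c("body", "liver"))
  p2 <- pl("PBS", c("body", "liver"))
  expect_s3_class(patient_record("P1", 40, "IIA",
                                 list(`3D` = p1, PBS = p2)), "rt_patient")
  p3 <- pl("VMAT", c("body", "stomach"))
  expect_error(patient_record("P1", 40, "IIA", list(`3D` = p1, VMAT = p3)),
               "structure sets differ")
  # structure names match case-insensitively after whitespace normalization
  p4 <- plan_record("P1", "VMAT", 30, 15,
                    list(` Body ` = d("body"), LIVER = d("liver")))
  expect_named(p4$dvhs, c("body", "liver"))
})
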