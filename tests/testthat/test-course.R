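# Peak extraction, per-scan normalization and course assembly.

make_scan <- function(series, dcv, mz, int) scan_peak_table(series, dcv, mz, int)

test_that("extract_intensity takes the maximum height inside the window", {
  a <- species_assignment(fx_ions[["F-F-F"]], window_mz = 0.5)
  hit <- make_scan("s1", 0, 1848.75, 500)
  expect_equal(extract_intensity(hit, a), 500)
  expect_equal(extract_intensity(make_scan("s1", 0, 1700, 500), a), 0)
  two <- make_scan("s1", 0, c(1848.6, 1848.9), c(300, 400))
  expect_equal(extract_intensity(two, a), 400)
})

test_that("overlapping windows resolve to the nearest centre with a warning", {
  reg <- fx_proteoforms
  near1 <- species_assignment(fx_ions[["F-F-F"]], window_mz = 120)
  near2 <- species_assignment(fx_ions[["F-F-bF"]], window_mz = 120)
  scan <- make_scan("s1", 0, c(1848.75, 1951.80), c(10, 20))
  expect_warning(out <- cidtherm:::.extract_scan(scan, list(near1, near2)),
                 "overlapping")
  expect_equal(unname(out), c(10, 20))  # each peak claimed by its own species
})

test_that("normalization sums to 100, is idempotent and rejects zero scans", {
  x <- c(trimer = 50, dimer = 30, monomer = 20)
  expect_equal(normalize_scan(x), x)
  expect_equal(unname(normalize_scan(c(a = 2, b = 1, c = 1))), c(50, 25, 25))
  expect_equal(sum(normalize_scan(stats::runif(7))), 100, tolerance = 1e-12)
  expect_equal(normalize_scan(normalize_scan(c(a = 3, b = 9))),
               normalize_scan(c(a = 3, b = 9)))
  expect_error(normalize_scan(c(a = 0, b = 0), dcv = 12), "dcv = 12")
})

test_that("build_course merges replicate grids and keeps n = 1 points", {
  # two series on the standard dense (17) and sparse (8) grids
  course <- fx_hetero_course("F-F-F")
  grids <- standard_dcv_grids()
  expect_equal(course$dcv_grid, grids$series1)
  m <- course_means(course)
  expect_equal(m$n[m$dcv %in% grids$series2], rep(2L, 8))
  expect_equal(m$n[!m$dcv %in% grids$series2], rep(1L, 9))
  expect_true(all(is.na(m$sd[m$n == 1])))
  # per-voltage means over all species total 100%
  tot <- stats::aggregate(mean ~ dcv, data = course$summary, FUN = sum)
  expect_equal(tot$mean, rep(100, nrow(tot)), tolerance = 1e-9)
})

test_that("scan order does not affect the course and duplicates error", {
  course <- fx_hetero_course("F-F-bF")
  scans <- emit_peak_tables(course, fx_ions)
  syms <- unique(course$data$species)
  assigns <- lapply(syms, function(s) species_assignment(fx_ions[[s]]))
  c1 <- build_course(scans, assigns, educt = "F-F-bF")
  c2 <- build_course(rev(scans), assigns, educt = "F-F-bF")
  expect_equal(c1$summary, c2$summary)
  expect_error(build_course(c(scans, scans[1]), assigns, educt = "F-F-bF"),
               "duplicate")
  expect_error(build_course(scans[1:3], assigns, educt = "F-F-bF"),
               "4 distinct")
  expect_error(build_course(scans, assigns, educt = "nope"),
               "not among the assignments")
})

test_that("generator -> peak tables -> build_course round-trips exactly", {
  course <- fx_hetero_course("F-bF-bF")
  scans <- emit_peak_tables(course, fx_ions)
  syms <- unique(course$data$species)
  assigns <- lapply(syms, function(s) species_assignment(fx_ions[[s]]))
  rebuilt <- build_course(scans, assigns, educt = "F-bF-bF")
  a <- course$summary[order(course$summary$species, course$summary$dcv), ]
  b <- rebuilt$summary[order(rebuilt$summary$species, rebuilt$summary$dcv), ]
  expect_equal(a$mean, b$mean, tolerance = 1e-9)
  expect_equal(a$n, b$n)
})

test_that("satellite assignments fold into their parent species", {
  ion <- fx_ions[["F-F-F"]]
  sat <- species_assignment(ion, mz_measured = ion$mz_calc + 4.4,
                            satellite_of = "F-F-F")
  main <- species_assignment(ion)
  mono <- species_assignment(fx_ions[["F"]])
  scans <- lapply(c(0, 5, 10, 15), function(v)
    make_scan("s1", v, c(ion$mz_calc, ion$mz_calc + 4.4,
                         fx_ions[["F"]]$mz_calc), c(60, 20, 20)))
  course <- build_course(scans, list(main, sat, mono), educt = "F-F-F")
  m <- course_means(course, "F-F-F")
  expect_equal(m$mean, rep(80, 4))  # 60 + 20 summed before normalization
})

test_that("long-format tables read back into scans", {
  df <- data.frame(series_id = rep(c("a", "b"), each = 2),
                   dcv = c(0, 0, 4, 4),
                   mz = c(1848.75, 1540.80, 1848.75, 1540.80),
                   intensity = c(90, 10, 50, 50))
  scans <- read_peak_tables(df)
  expect_length(scans, 2)
  expect_true(all(vapply(scans, inherits, logical(1), "scan_peak_table")))
  expect_error(read_peak_tables(df[, -1]), "needs columns")
})
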