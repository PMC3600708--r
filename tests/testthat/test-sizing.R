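# Brute-force oracle for a 3-point reciprocal fit: grid + golden-section
# search over m0, linear least squares for (L0, c) at each m0.  Fully
# independent of the closed-form solver in the package.
brute_reciprocal3 <- function(scans, sizes, query) {
  rss <- function(m0) {
    x <- 1 / (scans - m0)
    f <- lm(sizes ~ x)
    sum(residuals(f)^2)
  }
  ## pole sits below the scans; search its distance on a log grid
  d_of <- function(theta) min(scans) - exp(theta)
  grid <- seq(log(1e-2), log(1e8), length.out = 4000)
  vals <- vapply(grid, function(th) rss(d_of(th)), numeric(1))
  j <- which.min(vals)
  opt <- optimize(function(th) rss(d_of(th)),
                  c(grid[max(1, j - 2)], grid[min(length(grid), j + 2)]),
                  tol = 1e-13)
  m0 <- d_of(opt$minimum)
  x <- 1 / (scans - m0)
  f <- lm(sizes ~ x)
  unname(coef(f)[1] + coef(f)[2] / (query - m0))
}

test_that("Local Southern is exact on reciprocal-law ladders, including
           the decreasing-mobility orientation", {
  ## scan = 500 + 2e5/(L + 50): sizes decrease as scans increase
  sizes <- rev(gs500_ladder()$sizes)
  scans <- 500 + 2e5 / (sizes + 50)
  fit <- fit_from_pairs(scans, sizes)
  q <- 500 + 2e5 / (122 + 50)
  expect_equal(local_southern_size(q, fit), 122, tolerance = 1e-9)
  ## increasing orientation with several queries
  mob <- mobility_model()
  sizes2 <- gs500_ladder()$sizes
  fit2 <- fit_from_pairs(mobility_scan(mob, sizes2), sizes2)
  for (L in c(77.3, 122, 180.5, 249.99, 301.4, 444.4)) {
    expect_equal(local_southern_size(mobility_scan(mob, L), fit2), L,
                 tolerance = 1e-6)
  }
})

test_that("Local Southern equals the mean of two brute-force 3-point
           reciprocal solves", {
  set.seed(11)
  mob <- mobility_model()
  sizes <- gs500_ladder()$sizes
  ## jitter sizes off the exact law so the two 3-point fits disagree
  scans <- mobility_scan(mob, sizes) + rnorm(length(sizes), 0, 3)
  fit <- fit_from_pairs(scans, sizes)
  for (L in c(110, 205, 330)) {
    q <- mobility_scan(mob, L)
    i <- findInterval(q, scans)
    b1 <- brute_reciprocal3(scans[(i - 1):(i + 1)], sizes[(i - 1):(i + 1)], q)
    b2 <- brute_reciprocal3(scans[i:(i + 2)], sizes[i:(i + 2)], q)
    expect_equal(local_southern_size(q, fit), (b1 + b2) / 2,
                 tolerance = 1e-6)
  }
})

test_that("a query at a matched standard returns that standard's size; too
           few flanking standards gives NA", {
  sizes <- gs500_ladder()$sizes
  scans <- mobility_scan(mobility_model(), sizes)
  fit <- fit_from_pairs(scans, sizes)
  expect_equal(local_southern_size(scans[5], fit), sizes[5])
  expect_equal(local_southern_size(scans[1], fit), sizes[1])
  ## between 1st and 2nd standard: only one below
  expect_true(is.na(local_southern_size(mean(scans[1:2]), fit)))
  expect_true(is.na(local_southern_size(scans[16] + 50, fit)))
})

test_that("sizing is strictly monotone in scan within the usable interval", {
  set.seed(3)
  sizes <- gs500_ladder()$sizes
  scans <- mobility_scan(mobility_model(), sizes) +
    rnorm(length(sizes), 0, 2)
  fit <- fit_from_pairs(scans, sizes)
  q <- seq(fit$interval_scan[1], fit$interval_scan[2], length.out = 400)
  s <- local_southern_size(q, fit)
  expect_true(all(diff(s) > 0))
})

test_that("Global Southern recovers reciprocal-law data exactly; cubic
           least squares is exact on cubic data where Local Southern is not", {
  mob <- mobility_model()
  sizes <- gs500_ladder()$sizes
  scans <- mobility_scan(mob, sizes)
  fit <- fit_from_pairs(scans, sizes)
  L <- c(90, 122, 260, 410)
  q <- mobility_scan(mob, L)
  expect_equal(comparator_size(q, fit, "global_southern"), L,
               tolerance = 1e-6)
  ## sizes generated from an exact cubic in scan
  cub <- function(m) 40 + 0.05 * m + 3e-6 * m^2 - 9e-11 * m^3
  scans2 <- seq(1000, 9000, length.out = 16)
  fit2 <- fit_from_pairs(scans2, cub(scans2))
  q2 <- c(2345, 4567, 6789)
  err_cubic <- abs(comparator_size(q2, fit2, "cubic_ls") - cub(q2))
  err_local <- abs(local_southern_size(q2, fit2) - cub(q2))
  expect_true(all(err_cubic < 1e-6))
  expect_true(all(err_local > err_cubic))
})

test_that("size_peaks labels method, flags out-of-interval peaks and keeps
           empty inputs empty", {
  sizes <- gs500_ladder()$sizes
  scans <- mobility_scan(mobility_model(), sizes)
  fit <- fit_from_pairs(scans, sizes)
  pk <- data.frame(channel = "ROX", apex_scan = scans,
                   height = 800, half_width_points = 5, area = 1)
  sized <- size_peaks(pk, fit)
  expect_equal(sized$size_bp, sizes)
  expect_equal(unique(sized$method), "local_southern")
  expect_false(sized$sized[1])   # outermost standards are outside interval
  expect_false(sized$sized[16])
  expect_true(all(sized$sized[2:15]))
  empty <- size_peaks(pk[0, ], fit)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("size_bp", "method", "sized") %in% names(empty)))
})

test_that("a clean simulated ladder is matched fragment-for-fragment", {
  sim <- render_trace(data.frame(dye = character(), size = numeric(),
                                 height = numeric(), kind = character()),
                      run = quiet_run(), seed = 21)
  pk <- detect_peaks(sim$trace, group = 1)
  rox <- pk[pk$channel == "ROX", ]
  expect_equal(nrow(rox), 16)
  fit <- match_ladder(rox, gs500_ladder())
  expect_equal(fit$sizes, gs500_ladder()$sizes)
  expect_false(fit$partial)
  truth <- sim$truth[order(sim$truth$apex_scan), ]
  expect_equal(fit$scans, truth$apex_scan, tolerance = 0.05)
})

test_that("a surviving broad artifact on the ladder channel is excluded by
           the spacing score", {
  extra <- data.frame(dye = "ROX", size = 122.7, height = 1500,
                      kind = "artifact")
  sim <- render_trace(extra, run = quiet_run(), seed = 22)
  pk <- detect_peaks(sim$trace, group = 1)
  rox <- pk[pk$channel == "ROX", ]
  expect_equal(nrow(rox), 17)
  fit <- match_ladder(rox, gs500_ladder())
  truth <- sim$truth[sim$truth$kind == "ladder", ]
  truth <- truth[order(truth$apex_scan), ]
  expect_equal(fit$scans, truth$apex_scan, tolerance = 0.05)
})

test_that("a lost ladder fragment is an error when strict, a flagged
           partial fit otherwise", {
  short <- ladder_spec(gs500_ladder()$sizes[-9])  # drop the 250 fragment
  sim <- render_trace(data.frame(dye = character(), size = numeric(),
                                 height = numeric(), kind = character()),
                      ladder = short, run = quiet_run(), seed = 23)
  rox <- detect_peaks(sim$trace, group = 1)
  rox <- rox[rox$channel == "ROX", ]
  expect_equal(nrow(rox), 15)
  expect_error(match_ladder(rox, gs500_ladder(), strict = TRUE),
               "ladder failure")
  fit <- match_ladder(rox, gs500_ladder(), strict = FALSE)
  expect_true(fit$partial)
  expect_false(250 %in% fit$sizes)
  expect_equal(length(fit$sizes), 15)
})

test_that("ladder matching refuses garbage candidate sets", {
  set.seed(9)
  junk <- data.frame(apex_scan = sort(runif(16, 100, 9000)), height = 800)
  expect_error(match_ladder(junk, gs500_ladder()), "ladder failure")
  expect_error(match_ladder(junk[0, ], gs500_ladder()), "ladder failure")
})
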