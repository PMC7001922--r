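`%||%` <- function(a, b) if (is.null(a)) b else a

make_fits <- function(D, N = NULL, ep0 = NULL, r2 = NULL, airway = NULL) {
  n <- length(D)
  tibble::tibble(
    segment_id = sprintf("s%03d", seq_len(n)),
    N = N %||% rep(3L, n),
    a_mmHg = ep0 %||% rep(20, n),
    k = 1 - D / 100,
    D_pct = D,
    r_squared = r2 %||% rep(0.98, n),
    ep0_annotated_mmHg = ep0 %||% rep(20, n),
    converged = TRUE,
    airway_type = airway %||% rep("endotracheal", n)
  )
}

test_that("stratified summary uses type-7 quantiles and conserves counts", {
  fits <- make_fits(c(8, 10, 12))
  s <- summarize_fits(fits)
  row <- s[s$stratum == "3", ]
  expect_equal(row$D_median, 10)
  expect_equal(row$D_q1, 9)
  expect_equal(row$D_q3, 11)
  expect_identical(row$n_segments, 3L)

  # single fit: degenerate IQR equals the value
  one <- summarize_fits(make_fits(7.5))
  expect_equal(one$D_q1[one$stratum == "total"], 7.5)
  expect_equal(one$D_q3[one$stratum == "total"], 7.5)

  # strata partition the cohort: counts sum to the total
  fits2 <- make_fits(runif(40, 5, 15),
                     N = sample(c(2:5, 6:9), 40, replace = TRUE))
  s2 <- summarize_fits(fits2)
  expect_identical(sum(s2$n_segments[s2$stratum != "total"]),
                   s2$n_segments[s2$stratum == "total"])
  expect_true(all(s2$D_q1 <= s2$D_median & s2$D_median <= s2$D_q3))

  # invariant to input ordering
  s3 <- summarize_fits(fits2[sample(nrow(fits2)), ])
  expect_equal(as.data.frame(s3), as.data.frame(s2))

  expect_error(summarize_fits(fits2[0, ]), "at least one")
})

test_that("cohort simulation at true k = 0.9 recovers the headline medians", {
  set.seed(303)
  fits <- purrr::map_dfr(1:200, function(i) {
    ep <- sim_ep_series(runif(1, 10, 40), 0.9, sample(2:11, 1))
    f <- fit_decay(ep)
    tibble::tibble(segment_id = as.character(i), N = f$N, a_mmHg = f$a,
                   k = f$k, D_pct = f$D, r_squared = f$r_squared,
                   ep0_annotated_mmHg = ep[1], converged = f$converged)
  })
  s <- summarize_fits(fits)
  total <- s[s$stratum == "total", ]
  expect_gte(total$D_median, 9)
  expect_lte(total$D_median, 11)
  expect_gte(total$r2_median, 0.95)
})

test_that("regression of D on initial epCO2 behaves at both extremes", {
  set.seed(42)
  # independent by construction: near-zero explained variance
  ep0 <- runif(200, 10, 40)
  D <- rnorm(200, 10, 2)
  r <- regress_decay_on_ep0(make_fits(D, ep0 = ep0))
  expect_lt(r$r_squared, 0.05)

  # perfect linear relation (lm warns about the exact fit; expected here)
  r2 <- suppressWarnings(regress_decay_on_ep0(make_fits(2 * ep0, ep0 = ep0)))
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  expect_equal(r2$slope, 2, tolerance = 1e-9)

  # constant D: zero slope
  r3 <- suppressWarnings(
    regress_decay_on_ep0(make_fits(rep(10, 50), ep0 = runif(50, 10, 40)))
  )
  expect_equal(r3$slope, 0, tolerance = 1e-9)

  expect_error(regress_decay_on_ep0(make_fits(c(1, 2)))," at least 3")
  expect_error(regress_decay_on_ep0(make_fits(1:5, ep0 = rep(20, 5))),
               "degenerate")
})

test_that("airway ANOVA controls type-I error and handles degeneracy", {
  set.seed(55)
  reject <- 0L
  for (i in 1:100) {
    D <- rnorm(100, 10, 2)  # same distribution in both groups
    fits <- make_fits(D, airway = rep(c("endotracheal", "supraglottic"),
                                      each = 50))
    a <- compare_airway_groups(fits)
    if (a$p_value < 0.05) reject <- reject + 1L
  }
  expect_lte(reject, 10L)

  # perfect separation with zero within-group variance
  sep <- compare_airway_groups(
    make_fits(c(1, 1, 1, 2, 2, 2),
              airway = rep(c("endotracheal", "supraglottic"), each = 3))
  )
  expect_identical(sep$f_statistic, Inf)
  expect_identical(sep$p_value, 0)

  # identical groups: no between-group variance at all
  same <- compare_airway_groups(
    make_fits(rep(c(4, 5, 6), 2),
              airway = rep(c("endotracheal", "supraglottic"), each = 3))
  )
  expect_equal(same$f_statistic, 0)

  expect_error(compare_airway_groups(make_fits(1:4)), "groups")
})

test_that("identical group values with nonzero within variance give F = 0", {
  fits <- make_fits(c(4, 5, 6, 4, 5, 6),
                    airway = rep(c("endotracheal", "supraglottic"), each = 3))
  a <- compare_airway_groups(fits)
  expect_equal(a$f_statistic, 0, tolerance = 1e-12)
  expect_equal(a$p_value, 1, tolerance = 1e-12)
})

test_that("fit distribution plot builds", {
  p <- plot_fit_distributions(make_fits(runif(20, 5, 15)))
  expect_s3_class(p, "ggplot")
})
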