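# independent oracle: exact interval bounds by bisection on the binomial CDF
oracle_exact_ci <- function(s, n, level = 0.95) {
  alpha <- (1 - level) / 2
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  low <- if (s == 0) 0 else
    bisect(function(p) stats::pbinom(s - 1, n, p, lower.tail = FALSE) > alpha,
           0, 1)
  high <- if (s == n) 1 else
    bisect(function(p) stats::pbinom(s, n, p) < alpha, 0, 1)
  c(low, high)
}

# independent oracle: full enumeration over 2x2 tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("exact binomial interval matches the bisection oracle", {
  # the 22/30 interval, frozen from the oracle: (0.5411, 0.8772)
  ci <- binomial_ci_exact(22, 30)
  expect_equal(unname(ci), c(0.541, 0.877), tolerance = 0.005)
  expect_equal(unname(ci), oracle_exact_ci(22, 30), tolerance = 1e-8)

  expect_equal(binomial_ci_exact(0, 10)[["low"]], 0)
  expect_equal(binomial_ci_exact(10, 10)[["high"]], 1)

  for (case in list(c(1, 8), c(5, 12), c(17, 22), c(29, 30), c(50, 120))) {
    expect_equal(unname(binomial_ci_exact(case[1], case[2])),
                 oracle_exact_ci(case[1], case[2]), tolerance = 1e-8)
  }
  expect_error(binomial_ci_exact(5, 4), class = "focalroi_error_metrics")
  expect_error(binomial_ci_exact(-1, 4), class = "focalroi_error_metrics")

  # Wilson alternative stays inside [0, 1] and brackets the estimate
  w <- binomial_ci_wilson(22, 30)
  expect_true(w[["low"]] < 22 / 30 && 22 / 30 < w[["high"]])
})

test_that("exact interval covers the true proportion in >= 95% of draws", {
  set.seed(123)
  draws <- stats::rbinom(2000, 30, 0.7)
  bounds <- vapply(0:30, function(s) binomial_ci_exact(s, 30), numeric(2))
  covered <- bounds[1, draws + 1] <= 0.7 & 0.7 <= bounds[2, draws + 1]
  expect_gte(mean(covered), 0.95)
})

test_that("Fisher exact test matches margin-fixed enumeration", {
  expect_lt(fisher_exact_2x2(17, 5, 0, 8), 0.001)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  set.seed(99)
  for (i in 1:20) {
    cells <- stats::rpois(4, 4)
    if (sum(cells) == 0) cells[1] <- 1
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, min(1, oracle_fisher(cells[1], cells[2], cells[3],
                                         cells[4])), tolerance = 1e-7)
    # invariance under row and column swaps
    expect_equal(p, fisher_exact_2x2(cells[3], cells[4], cells[1], cells[2]),
                 tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(cells[2], cells[1], cells[4], cells[3]),
                 tolerance = 1e-12)
  }
})

test_that("driver metrics summarize presence, stability and recurrence", {
  maps <- sprintf("m%d", 1:8)
  sites <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(recording_id = maps[i], x = 1, y = 0, z = 0,
                   occurrences = 1L, runs = list(3L))
  })
  m <- driver_metrics(sites, c(0, 0, 0), maps)
  expect_equal(m$consistency, 0.75)

  sites2 <- tibble::tibble(recording_id = c("m1", "m1", "m2", "m2"),
                           x = 0, y = 0, z = 0, occurrences = 1L,
                           runs = list(3L, 3L, 4L, 3L))
  m2 <- driver_metrics(sites2, c(0, 0, 0), c("m1", "m2"))
  expect_equal(m2$temporal_stability, 3.25)
  expect_equal(m2$recurrence_rate, 2)

  # uncovered maps leave the consistency denominator only
  m3 <- driver_metrics(sites, c(0, 0, 0), maps, uncovered = c("m7", "m8"))
  expect_equal(m3$consistency, 1)

  # sites beyond the correlation threshold do not count
  far <- dplyr::mutate(sites, x = 20)
  expect_equal(driver_metrics(far, c(0, 0, 0), maps)$consistency, 0)
  expect_error(driver_metrics(sites, c(0, 0, 0), character()),
               class = "focalroi_error_metrics")
})

test_that("cycle length is the mean of the first n intervals", {
  expect_equal(cycle_length(seq(0, by = 150, length.out = 31)), 150)
  alt <- cumsum(c(0, rep(c(140, 160), 15)))
  expect_equal(cycle_length(alt), 150)
  expect_error(cycle_length(1:10), class = "focalroi_error_metrics")
})

test_that("cycle length recovered from a simulated fibrillation channel", {
  sim <- simulate_recording("af_no_driver", seed = 8)
  filt <- filter_unipolar(sim$recording)
  cl <- cycle_length(filt$traces[, "C4"], sampling_rate = 1000)
  expect_equal(cl, 145, tolerance = 5 / 145)
})

test_that("ablation response and low-voltage classification", {
  expect_equal(ablation_response(145, 180), "cl_slowing")
  expect_equal(ablation_response(145, 170), "none")
  expect_equal(ablation_response(145, 175), "cl_slowing")  # boundary: 30 ms
  expect_equal(ablation_response(145, 120, terminated = TRUE), "termination")

  expect_true(lvz_classify(0.49))
  expect_false(lvz_classify(0.5))
  expect_false(lvz_classify(1.2))
  expect_error(lvz_classify(-0.1), class = "focalroi_error_metrics")
})

test_that("evaluate_detection applies the strict 1 cm rule to counts", {
  refs <- tibble::tibble(x = c(0, 100), y = 0, z = 0)
  ctl <- tibble::tibble(x = c(0, 100), y = 100, z = 0)
  roi <- tibble::tibble(x = c(3, 100), y = c(4, 9), z = 0)
  e <- evaluate_detection(roi, refs, ctl)
  expect_equal(c(e$tp, e$fn, e$fp, e$tn), c(2, 0, 0, 2))

  # a detection at exactly 10 mm does not correlate
  roi10 <- tibble::tibble(x = 10, y = 0, z = 0)
  e10 <- evaluate_detection(roi10, refs[1, ], ctl)
  expect_equal(c(e10$tp, e10$fn, e10$fp), c(0, 1, 1))

  # control sites must be well away from references
  expect_error(evaluate_detection(roi, refs,
                                  tibble::tibble(x = 15, y = 0, z = 0)),
               class = "focalroi_error_metrics")

  # empty reference list: sensitivity undefined, the rest computed
  e0 <- evaluate_detection(roi[0, ], refs[0, ], ctl)
  td <- tidy(e0)
  expect_true(td$undefined[td$measure == "sensitivity"])
  expect_equal(td$estimate[td$measure == "specificity"], 1)
})

test_that("evaluation counts balance for random configurations", {
  set.seed(77)
  for (i in 1:15) {
    n_ref <- sample(1:6, 1); n_roi <- sample(0:6, 1); n_ctl <- sample(1:6, 1)
    refs <- tibble::tibble(x = runif(n_ref, 0, 200), y = runif(n_ref, 0, 200),
                           z = 0)
    ctl <- tibble::tibble(x = runif(n_ctl, 400, 600), y = runif(n_ctl, 0, 200),
                          z = 0)
    roi <- tibble::tibble(x = runif(n_roi, 0, 600), y = runif(n_roi, 0, 200),
                          z = 0)
    e <- evaluate_detection(roi, refs, ctl)
    expect_equal(e$tp + e$fn, n_ref)
    expect_gte(e$fp, 0); expect_gte(e$tn, 0)
    g <- glance(e)
    expect_equal(g$tp, e$tp)
  }
})

test_that("sequential-row evaluation reproduces the printed presentation", {
  # 30 references, 22 detected, controls clean: 73 (54-88)
  refs <- tibble::tibble(x = seq(0, by = 50, length.out = 30), y = 0, z = 0)
  roi <- refs[1:22, ]
  ctl <- tibble::tibble(x = seq(0, by = 50, length.out = 30), y = 500, z = 0)
  e <- evaluate_detection(roi, refs, ctl)
  s <- dplyr::filter(tidy(e), measure == "sensitivity")
  expect_equal(format_rate_pct(s$estimate, s$conf.low, s$conf.high),
               "73 (54-88)")
})

test_that("configured cohort differences are recovered by the metrics", {
  # termination-type drivers (recurrence 12.2, stability 3.6) vs
  # slowing-type drivers (8.4, 2.7), 20 each, at truth level
  set.seed(2024)
  stats_for <- function(rec, stab, n) {
    purrr::map_dfr(seq_len(n), function(i) {
      runs <- draw_driver_runs(rec, stab)
      tibble::tibble(recurrence = length(runs),
                     stability = if (length(runs)) mean(runs) else NA_real_)
    })
  }
  term <- stats_for(12.2, 3.6, 20)
  slow <- stats_for(8.4, 2.7, 20)
  expect_lt(stats::wilcox.test(term$recurrence, slow$recurrence,
                               alternative = "greater",
                               exact = FALSE)$p.value, 0.01)
  expect_lt(stats::wilcox.test(term$stability, slow$stability,
                               alternative = "greater",
                               exact = FALSE)$p.value, 0.01)
})
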