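make_dwell_track <- function(t_d, t_f, arena = square_arena(),
                             lms = list(D = c(10, 10), F = c(-10, -10)),
                             dt = 0.1) {
  n_d <- round(t_d / dt); n_f <- round(t_f / dt); n_o <- 50
  nose <- rbind(matrix(rep(lms$D, n_d), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 0), n_o), ncol = 2, byrow = TRUE),
                matrix(rep(lms$F, n_f), ncol = 2, byrow = TRUE))
  n <- nrow(nose)
  behavior_track(seq(0, by = dt, length.out = n),
                 matrix(0, n, 2), nose, arena = arena, landmarks = lms)
}

test_that("discrimination index follows the dwell-time ratio", {
  tr <- make_dwell_track(6, 4)
  es <- object_exploration(tr)
  expect_equal(es$discrimination_index, 0.6, tolerance = 1e-9)
  expect_equal(es$total_exploration_s, 10, tolerance = 0.11)

  # symmetry: DI(D,F) + DI(F,D) = 1
  es_rev <- object_exploration(tr, displaced = "F", familiar = "D")
  expect_equal(es$discrimination_index + es_rev$discrimination_index, 1)

  # equal dwell gives chance-level DI
  eq <- object_exploration(make_dwell_track(5, 5))
  expect_equal(eq$discrimination_index, 0.5, tolerance = 1e-9)
})

test_that("exploration falls back to body position when nose is missing", {
  lms <- list(D = c(10, 10), F = c(-10, -10))
  body <- matrix(rep(lms$D, 100), ncol = 2, byrow = TRUE)
  tr <- behavior_track(seq(0, 9.9, by = 0.1), body, arena = square_arena(),
                       landmarks = lms)
  expect_warning(es <- object_exploration(tr), "body")
  expect_gt(es$times$time_s[es$times$object == "D"], 9)
})

test_that("sub-threshold dwells are rejected as jitter", {
  lms <- list(D = c(10, 10), F = c(-10, -10))
  # a single 0.05 s touch of D: below the 0.1 s minimum epoch
  nose <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
                matrix(rep(lms$D, 1), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE))
  tr <- behavior_track(seq(0, by = 0.05, length.out = nrow(nose)),
                       matrix(0, nrow(nose), 2), nose,
                       arena = square_arena(), landmarks = lms)
  es <- object_exploration(tr)
  expect_equal(es$total_exploration_s, 0)
})

test_that("spatial errors are bounded by 19 and monotone in coverage", {
  cups <- barnes_cups()
  arena <- circle_arena(50)
  dt <- 0.1
  visit_all <- cups[rep(seq_len(20), each = 10), ]
  tr_all <- behavior_track(seq(0, by = dt,
                               length.out = nrow(visit_all)),
                           visit_all, arena = arena)
  expect_equal(barnes_errors(tr_all, cups, baited = 1), 19)

  only_baited <- matrix(rep(cups[1, ], 100), ncol = 2, byrow = TRUE)
  tr_b <- behavior_track(seq(0, by = dt, length.out = 100), only_baited,
                         arena = arena)
  expect_equal(barnes_errors(tr_b, cups, baited = 1), 0)

  # errors never exceed 19 and never decrease as the track is extended
  prev <- 0
  for (k in c(5, 10, 20)) {
    part <- cups[rep(seq_len(k), each = 10), ]
    tr_k <- behavior_track(seq(0, by = dt, length.out = nrow(part)), part,
                           arena = arena)
    e <- barnes_errors(tr_k, cups, baited = 1)
    expect_lte(e, 19)
    expect_gte(e, prev)
    prev <- e
  }
  expect_error(barnes_errors(tr_b, cups, baited = 25), "out of range")
})

test_that("quadrant occupancies partition time exactly", {
  tr <- generate_track(circle_arena(50), "uniform", 500, 10, seed = 3)
  occ <- vapply(1:4, function(q) quadrant_occupancy(tr, q), numeric(1))
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  expect_error(quadrant_occupancy(tr, 5), "quadrant")
})

test_that("alternation success rate matches the Bernoulli oracle", {
  perfect <- data.frame(sample = rep(c("L", "R"), 5),
                        choice = rep(c("R", "L"), 5))
  expect_equal(alternation_success(perfect), 1)
  stuck <- data.frame(sample = rep("L", 10), choice = rep("L", 10))
  expect_equal(alternation_success(stuck), 0)

  set.seed(5)
  n <- 1000
  rand <- data.frame(sample = sample(c("L", "R"), n, replace = TRUE),
                     choice = sample(c("L", "R"), n, replace = TRUE))
  rate <- alternation_success(rand)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n))
  expect_error(alternation_success(data.frame()), "trials")
})

test_that("partial eta squared matches substitution and the ANOVA oracle", {
  expect_equal(partial_eta_squared(3, 1)$partial_eta_sq, 0.75)
  expect_equal(partial_eta_squared(0, 2)$partial_eta_sq, 0)
  expect_error(partial_eta_squared(0, 0), "degenerate")
  expect_error(partial_eta_squared(-1, 2), "non-negative")

  # monotone in SS_effect at fixed SS_error
  vals <- vapply(1:5, function(s)
    partial_eta_squared(s, 2)$partial_eta_sq, numeric(1))
  expect_true(all(diff(vals) > 0))

  # two-condition repeated-measures data: long-hand sum-of-squares
  # decomposition vs aov(), both fed through the effect-size formula
  set.seed(9)
  n_subj <- 8
  subj_eff <- rnorm(n_subj, sd = 2)
  d <- expand.grid(subj = factor(seq_len(n_subj)),
                   cond = factor(c("a", "b")))
  d$y <- 5 + ifelse(d$cond == "b", 1.5, 0) + subj_eff[d$subj] +
    rnorm(nrow(d), sd = 0.8)
  grand <- mean(d$y)
  cond_means <- tapply(d$y, d$cond, mean)
  subj_means <- tapply(d$y, d$subj, mean)
  ss_cond <- n_subj * sum((cond_means - grand)^2)
  ss_err <- sum((d$y - subj_means[d$subj] - cond_means[d$cond] + grand)^2)

  fit <- stats::aov(y ~ cond + Error(subj), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  expect_equal(tab["cond", "Sum Sq"], ss_cond, tolerance = 1e-8)
  expect_equal(tab["Residuals", "Sum Sq"], ss_err, tolerance = 1e-8)
  expect_equal(partial_eta_squared(tab["cond", "Sum Sq"],
                                   tab["Residuals", "Sum Sq"])$partial_eta_sq,
               ss_cond / (ss_cond + ss_err), tolerance = 1e-10)
})
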