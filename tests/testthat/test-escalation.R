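grid6 <- dose_grid(c(0.2, 0.5, 0.7, 0.8, 0.9, 0.95),
                   c(0.2, 0.5, 0.7, 0.8, 0.9, 0.95))

combo_key <- function(m) paste(m[, 1], m[, 2])

test_that("admissible sets have the expected membership", {
  # interior cell: current + 4 orthogonal neighbours
  a1 <- admissible_set(dose_combo(3, 3), grid6, "omega1")
  expect_equal(nrow(a1), 5)
  expect_setequal(combo_key(a1),
                  combo_key(rbind(c(3, 3), c(2, 3), c(4, 3), c(3, 2),
                                  c(3, 4))))
  # corner is clipped to the grid
  a1c <- admissible_set(dose_combo(1, 1), grid6, "omega1")
  expect_equal(nrow(a1c), 3)
  expect_setequal(combo_key(a1c), combo_key(rbind(c(1, 1), c(2, 1),
                                                  c(1, 2))))
  # omega2 adds the full diagonal neighbourhood by default
  a2 <- admissible_set(dose_combo(3, 3), grid6, "omega2")
  expect_equal(nrow(a2), 9)
  expect_true(all(combo_key(rbind(c(4, 4), c(2, 2), c(4, 2), c(2, 4))) %in%
                    combo_key(a2)))
  # restricted to main diagonal on request
  a2m <- admissible_set(dose_combo(3, 3), grid6, "omega2",
                        diagonal = "main")
  expect_equal(nrow(a2m), 7)
  expect_false(any(combo_key(rbind(c(4, 2), c(2, 4))) %in% combo_key(a2m)))
  # omega3 unions previously experimented combos
  h <- trial_history(i = c(1, 1, 2, 3), j = c(1, 1, 2, 1),
                     y = c(0, 0, 0, 0))
  a3 <- admissible_set(dose_combo(3, 1), grid6, "omega3", h)
  expect_true(all(combo_key(rbind(c(1, 1), c(2, 2), c(3, 1))) %in%
                    combo_key(a3)))
  expect_true(all(combo_key(admissible_set(dose_combo(3, 1), grid6,
                                           "omega2", h)) %in%
                    combo_key(a3)))
})

test_that("admissible sets nest and never lose the current combo", {
  set.seed(51)
  for (r in 1:40) {
    cur <- dose_combo(sample(6, 1), sample(6, 1), grid6)
    n <- sample(0:10, 1)
    h <- if (n == 0) trial_history() else
      trial_history(sample(6, n, TRUE), sample(6, n, TRUE),
                    rbinom(n, 1, 0.3))
    k1 <- combo_key(admissible_set(cur, grid6, "omega1", h))
    k2 <- combo_key(admissible_set(cur, grid6, "omega2", h))
    k3 <- combo_key(admissible_set(cur, grid6, "omega3", h))
    expect_true(all(k1 %in% k2))
    expect_true(all(k2 %in% k3))
    expect_true(paste(cur[["i"]], cur[["j"]]) %in% k1)
    # no dose skipping in omega1 / omega2
    a2 <- admissible_set(cur, grid6, "omega2", h)
    expect_true(all(abs(a2[, 1] - cur[["i"]]) <= 1))
    expect_true(all(abs(a2[, 2] - cur[["j"]]) <= 1))
  }
})

test_that("tolerance restriction keeps the closed window", {
  surface <- matrix(0.5, 6, 6)
  surface[2, 2] <- 0.30
  surface[3, 3] <- 0.326
  surface[4, 4] <- 0.275
  cand <- rbind(c(2, 2), c(3, 3), c(4, 4), c(5, 5))
  kept <- restrict_by_tolerance(cand, surface, ttl = 0.30, epsilon = 0.025)
  expect_setequal(combo_key(kept), combo_key(rbind(c(2, 2), c(4, 4))))
  # 0.326 is outside: |0.326 - 0.30| = 0.026 > 0.025
  expect_false("3 3" %in% combo_key(kept))
  # can be empty
  expect_equal(nrow(restrict_by_tolerance(rbind(c(1, 1)), surface,
                                          0.30, 0.025)), 0)
})

test_that("D1 picks the candidate closest to the TTL", {
  surface <- matrix(0.5, 6, 6)
  surface[1, 1] <- 0.40; surface[2, 1] <- 0.32; surface[1, 2] <- 0.35
  got <- choose_next_D1(rbind(c(1, 1), c(2, 1), c(1, 2)), surface,
                        ttl = 0.30, grid = grid6)
  expect_equal(unclass(got), c(i = 2L, j = 1L))
})

test_that("exact D1 ties resolve to the lower total dose", {
  surface <- matrix(0.5, 6, 6)
  surface[2, 3] <- 0.28; surface[4, 4] <- 0.32   # equal |diff| = 0.02
  got <- choose_next_D1(rbind(c(4, 4), c(2, 3)), surface, 0.30, grid6)
  expect_equal(unclass(got), c(i = 2L, j = 3L))
  # equal total dose: smaller drug-A index wins
  surface2 <- matrix(0.5, 6, 6)
  surface2[2, 4] <- 0.28; surface2[4, 2] <- 0.32
  got2 <- choose_next_D1(rbind(c(4, 2), c(2, 4)), surface2, 0.30, grid6)
  expect_equal(unclass(got2), c(i = 2L, j = 4L))
})

test_that("D1 matches an exhaustive-search oracle on random surfaces", {
  set.seed(52)
  for (r in 1:1000) {
    surface <- matrix(runif(36), 6, 6)
    n <- sample(2:8, 1)
    cand <- unique(cbind(sample(6, n, TRUE), sample(6, n, TRUE)))
    got <- choose_next_D1(cand, surface, 0.30, grid6)
    # brute force with the documented tie rule
    d <- abs(surface[cand] - 0.30)
    tot <- grid6$levels_a[cand[, 1]] + grid6$levels_b[cand[, 2]]
    best <- order(d, tot, cand[, 1], cand[, 2])[1]
    expect_identical(unclass(got),
                     c(i = as.integer(cand[best, 1]),
                       j = as.integer(cand[best, 2])))
  }
})

test_that("D1 and D2 always return an admissible candidate", {
  m <- copula_model(grid6, test_skeleton())
  d <- posterior_draws(m, trial_history(), n_draws = 100, seed = 53)
  set.seed(54)
  for (r in 1:20) {
    cur <- dose_combo(sample(6, 1), sample(6, 1), grid6)
    h <- trial_history(sample(6, 4, TRUE), sample(6, 4, TRUE),
                       rbinom(4, 1, 0.3))
    adm <- admissible_set(cur, grid6, sample(c("omega1", "omega2",
                                               "omega3"), 1), h)
    surface <- matrix(runif(36), 6, 6)
    g1 <- choose_next_D1(adm, surface, 0.30, grid6)
    expect_true(paste(g1[["i"]], g1[["j"]]) %in% combo_key(adm))
    g2 <- choose_next_D2(adm, surface, d, m, h, 0.30, 0.025)
    expect_true(paste(g2[["i"]], g2[["j"]]) %in% combo_key(adm))
  }
})

test_that("D2 falls back to D1 when the window is empty", {
  m <- copula_model(grid6, test_skeleton())
  d <- posterior_draws(m, trial_history(), n_draws = 50, seed = 55)
  surface <- matrix(0.9, 6, 6); surface[1, 1] <- 0.6
  cand <- rbind(c(1, 1), c(2, 1), c(1, 2))
  expect_equal(choose_next_D2(cand, surface, d, m, trial_history(),
                              0.30, 0.025),
               choose_next_D1(cand, surface, 0.30, grid6))
})

test_that("a singleton window is returned without evaluating information", {
  m <- copula_model(grid6, test_skeleton())
  d <- posterior_draws(m, trial_history(), n_draws = 50, seed = 56)
  surface <- matrix(0.9, 6, 6); surface[2, 1] <- 0.30
  got <- choose_next_D2(rbind(c(1, 1), c(2, 1), c(1, 2)), surface, d, m,
                        trial_history(), 0.30, 0.025)
  expect_equal(unclass(got), c(i = 2L, j = 1L))
})

test_that("D2 maximizes the information criterion within the window", {
  m <- copula_model(grid6, test_skeleton())
  d <- posterior_draws(m, trial_history(i = c(1, 1), j = c(1, 1),
                                        y = c(0, 1)),
                       n_draws = 100, seed = 57)
  h <- trial_history(i = c(1, 1), j = c(1, 1), y = c(0, 1))
  surface <- matrix(0.9, 6, 6)
  inwin <- rbind(c(2, 2), c(5, 5), c(3, 1))
  surface[inwin] <- 0.30
  cand <- rbind(inwin, c(1, 1))
  got <- choose_next_D2(cand, surface, d, m, h, 0.30, 0.025)
  crit <- vapply(seq_len(nrow(inwin)), function(r)
    expected_log_det_info(d, m, h, inwin[r, , drop = FALSE]), numeric(1))
  best <- inwin[which.max(crit), ]
  expect_equal(unclass(got), c(i = as.integer(best[1]),
                               j = as.integer(best[2])))
})

test_that("Phase II recommendations come only from experimented combos", {
  h <- trial_history(i = c(1, 1, 2, 2, 3, 3), j = c(1, 1, 1, 1, 2, 2),
                     y = c(0, 0, 0, 1, 0, 0))
  surface <- matrix(0.30, 6, 6)   # everything in the window
  got <- rpii_set(h, surface, 0.30, 0.025)
  expect_setequal(combo_key(got),
                  combo_key(rbind(c(1, 1), c(2, 1), c(3, 2))))
  # nothing within tolerance -> empty set
  surface2 <- matrix(0.9, 6, 6)
  expect_equal(nrow(rpii_set(h, surface2, 0.30, 0.025)), 0)
  # three-combo fixture: only |mean - ttl| <= 0.025 survives
  h3 <- trial_history(i = c(1, 2, 3), j = c(1, 1, 1), y = c(0, 0, 0))
  s3 <- matrix(0.9, 6, 6)
  s3[1, 1] <- 0.28; s3[2, 1] <- 0.32; s3[3, 1] <- 0.40
  expect_setequal(combo_key(rpii_set(h3, s3, 0.30, 0.025)),
                  combo_key(rbind(c(1, 1), c(2, 1))))
  s3[2, 1] <- 0.33   # 0.03 away: outside the window
  expect_setequal(combo_key(rpii_set(h3, s3, 0.30, 0.025)),
                  combo_key(rbind(c(1, 1))))
})

test_that("trial configuration validates its fields", {
  expect_error(trial_config(ttl = 1.2), "ttl")
  expect_error(trial_config(epsilon = 0.4), "epsilon")
  expect_error(trial_config(cohort_size = 0), "cohort_size")
  expect_error(trial_config(rule = "d9"))
  expect_error(admissible_set(dose_combo(3, 3), grid6, "omega9"))
})
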