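# Correlation and paired t-test against independent oracles.

# independent two-pass evaluation of the sample-correlation summations
cor_two_pass <- function(A, R) {
  a <- A - mean(A); r <- R - mean(R)
  sum(a * r) / (sqrt(sum(a^2)) * sqrt(sum(r^2)))
}

# independent p-value via the incomplete-beta form of the t CDF
p_incomplete_beta <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

test_that("perfect and inverted correlations are exact", {
  A <- c(33, 9.7, 49.9, 22.9, 40.5)
  expect_equal(sample_correlation(A, A), 1)
  expect_equal(sample_correlation(A, -A), -1)
  expect_equal(sample_correlation(A, 2 * A + 7), 1)
})

test_that("reference-cohort rotations against ranks match the two-pass
           oracle", {
  A <- c(33, 9.7, 49.9, 22.9, 40.5)
  R <- 1:5
  expect_equal(sample_correlation(A, R), cor_two_pass(A, R),
               tolerance = 1e-12)
})

test_that("correlation transforms correctly under affine maps", {
  set.seed(3)
  A <- rnorm(10); R <- rnorm(10)
  rho <- sample_correlation(A, R)
  expect_equal(sample_correlation(3 * A + 1, R), rho, tolerance = 1e-12)
  expect_equal(sample_correlation(A, -2 * R + 5), -rho, tolerance = 1e-12)
})

test_that("constant vectors raise a zero-variance error", {
  expect_error(sample_correlation(rep(1, 5), 1:5), "zero_variance")
  expect_error(sample_correlation(1:3, 1:4), "parameter_error")
})

test_that("paired t-test reproduces textbook cases", {
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  r0 <- paired_ttest(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  r1 <- paired_ttest(rep(0, 5), 1:5)
  expect_equal(r1$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r1$p, p_incomplete_beta(r1$t, 4), tolerance = 1e-9)
  expect_identical(r1$n, 5L)
})

test_that("correlation and t-test match their oracles on random instances", {
  set.seed(99)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    A <- rnorm(n); R <- rnorm(n)
    expect_equal(sample_correlation(A, R), cor_two_pass(A, R),
                 tolerance = 1e-12)
    tt <- paired_ttest(A, R)
    expect_equal(tt$p, p_incomplete_beta(tt$t, n - 1), tolerance = 1e-9)
  }
})

# synthetic long response table with the full condition grid
fake_responses <- function(n_patients = 5, seed = 5) {
  set.seed(seed)
  grid <- tidyr::expand_grid(patient = seq_len(n_patients),
                             state = paste0("LS", 1:5),
                             shear = c("none", "cw", "ccw"),
                             material = c("isotropic", "orthotropic"))
  grid <- grid[!(grid$material == "orthotropic" & grid$shear != "none"), ]
  rot <- stats::runif(n_patients, 5, 50)
  grid$apex_rotation_deg <- rot[grid$patient]
  grid$response_angle_deg <- stats::rnorm(nrow(grid), 0.5 *
                                            grid$apex_rotation_deg, 8)
  grid
}

test_that("cohort report has the study-design shape", {
  rep <- run_cohort(fake_responses())
  expect_identical(nrow(rep$correlations), 5L)
  expect_true(all(abs(rep$correlations$rho) <= 1))
  expect_identical(nrow(rep$ttests), 4L)
  expect_true(all(rep$ttests$n == 25L))
  expect_true(rep$best_state %in% paste0("LS", 1:5))
  expect_identical(vertefem::tidy(rep), rep$correlations)
  g <- vertefem::glance(rep)
  expect_identical(g$best_state, rep$best_state)
})

test_that("duplicating every patient leaves the correlations unchanged", {
  resp <- fake_responses()
  dup <- resp
  dup$patient <- dup$patient + 100
  both <- dplyr::bind_rows(resp, dup)
  r1 <- run_cohort(resp)
  r2 <- run_cohort(both)
  expect_equal(r2$correlations$rho, r1$correlations$rho, tolerance = 1e-12)
})

test_that("missing conditions are reported as completeness gaps", {
  resp <- fake_responses()
  expect_error(run_cohort(resp[resp$material != "orthotropic", ]),
               "completeness")
  expect_error(run_cohort(resp[-1, ]), "completeness")
})
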