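test_that("registration recovers exact transforms and is identity on equal sets", {
  lm <- tetra_landmarks()
  t_id <- horn_register(lm, lm)
  expect_equal(rt_matrix(t_id), diag(4), tolerance = 1e-9)
  # known 90-degree z rotation + translation recovered exactly
  rot <- rigid_transform(c(cos(pi / 4), 0, 0, sin(pi / 4)), c(10, -5, 2),
                         "plan", "reference")
  fixed <- transform_landmarks(rot, lm)
  est <- horn_register(lm, fixed)
  expect_equal(rt_matrix(est), rt_matrix(rot), tolerance = 1e-9)
  expect_equal(compute_fre(est, lm, fixed), 0, tolerance = 1e-9)
  expect_identical(est$source_frame, "plan")
  expect_identical(est$target_frame, "reference")
})

test_that("Horn solution matches the Kabsch/SVD oracle on random noisy instances", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(3:10, 1)
    moving <- random_cloud(n)
    truth <- random_transform("plan", "reference")
    fixed <- rt_apply(truth, moving) + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    est <- horn_register(moving, fixed)
    expect_equal(transform_ssq(est, moving, fixed),
                 kabsch_ssq(moving, fixed), tolerance = 1e-9)
    expect_equal(det(rt_rotation(est)), 1, tolerance = 1e-9)
  }
})

test_that("no reflection is returned for near-planar fiducial sets", {
  set.seed(32)
  for (i in 1:100) {
    n <- 5
    moving <- cbind(matrix(runif(2 * n, -50, 50), ncol = 2),
                    rnorm(n, sd = 1e-4))
    fixed <- rt_apply(random_transform(), moving) +
      matrix(rnorm(3 * n, sd = 1), ncol = 3)
    est <- horn_register(moving, fixed)
    expect_equal(det(rt_rotation(est)), 1, tolerance = 1e-9)
    expect_equal(transform_ssq(est, moving, fixed),
                 kabsch_ssq(moving, fixed), tolerance = 1e-6)
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(horn_register(random_cloud(2), random_cloud(2)),
               class = "emnav_degenerate_error")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(horn_register(line, line + 1),
               class = "emnav_degenerate_error")
  expect_error(horn_register(random_cloud(4), random_cloud(5)),
               class = "emnav_correspondence_error")
})

test_that("FRE matches its closed form and the direct-loop oracle", {
  # two residuals of 3 and 4 mm: RMS = sqrt((9 + 16) / 2) = 3.536
  moving <- rbind(c(0, 0, 0), c(10, 0, 0))
  fixed <- moving + rbind(c(3, 0, 0), c(0, 4, 0))
  t_id <- rt_identity("plan", "reference")
  expect_equal(compute_fre(t_id, moving, fixed), sqrt((9 + 16) / 2),
               tolerance = 1e-12)
  expect_equal(round(compute_fre(t_id, moving, fixed), 3), 3.536)
  expect_equal(compute_fre(t_id, moving, fixed, type = "mean"), 3.5)
  # random case equals a brute-force per-point loop
  set.seed(33)
  mv <- random_cloud(6)
  fx <- random_cloud(6)
  tr <- random_transform("plan", "reference")
  mapped <- rt_apply(tr, mv)
  res <- vapply(1:6, function(k) sqrt(sum((mapped[k, ] - fx[k, ])^2)),
                numeric(1))
  expect_equal(compute_fre(tr, mv, fx), sqrt(mean(res^2)), tolerance = 1e-12)
})

test_that("FRE is invariant under a common rigid motion of the fixed frame", {
  set.seed(34)
  lm <- tetra_landmarks()
  fixed <- transform_landmarks(random_transform("plan", "reference"), lm)
  fixed$points <- fixed$points + matrix(rnorm(12, sd = 0.4), ncol = 3)
  est <- horn_register(lm, fixed)
  fre0 <- compute_fre(est, lm, fixed)
  for (i in 1:50) {
    common <- random_transform("reference", "reference")
    moved <- landmark_set(fixed$names, rt_apply(common, fixed$points), "reference")
    est2 <- rt_compose(common, est)
    expect_equal(compute_fre(est2, lm, moved), fre0, tolerance = 1e-9)
  }
})

test_that("TRE closed forms hold", {
  tgt <- c(30, 0, 10)
  truth <- random_transform("plan", "reference")
  expect_equal(compute_tre(truth, tgt, truth = truth), 0)
  shifted <- rigid_transform(truth$q, truth$t + c(0, 2, 0), "plan", "reference")
  expect_equal(compute_tre(shifted, tgt, truth = truth), 2, tolerance = 1e-12)
  # rotation by theta about the z axis displaces a point at radius r from the
  # axis by 2 r sin(theta / 2)
  theta <- 7 * pi / 180
  est <- rigid_transform(c(cos(theta / 2), 0, 0, sin(theta / 2)), c(0, 0, 0),
                         "plan", "reference")
  r <- sqrt(30^2 + 0^2)
  expect_equal(compute_tre(est, tgt, truth = rt_identity("plan", "reference")),
               2 * r * sin(theta / 2), tolerance = 1e-12)
  # physical mode against a measured point
  expect_equal(compute_tre(rt_identity("plan", "reference"), tgt,
                           measured = tgt + c(3, 4, 0)), 5)
  expect_error(compute_tre(est, tgt), class = "emnav_schema_error")
})

test_that("TRE converges to truth as fiducial noise shrinks and follows the prediction", {
  set.seed(35)
  fid <- tetra_landmarks()$points
  tgt <- c(60, 50, 40)
  mean_tre <- vapply(c(1.0, 0.5, 0.1, 0.01), function(sigma) {
    mean(replicate(150, {
      noisy <- fid + matrix(rnorm(12, sd = sigma), ncol = 3)
      est <- horn_register(fid, noisy)
      compute_tre(est, tgt, truth = rt_identity("plan", "reference"))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_tre) < 0))
  # empirical mean TRE^2 agrees with the first-order prediction
  sigma <- 0.4
  tre2 <- replicate(2000, {
    noisy <- fid + matrix(rnorm(12, sd = sigma), ncol = 3)
    est <- horn_register(fid, noisy)
    compute_tre(est, tgt, truth = rt_identity("plan", "reference"))^2
  })
  pred <- predict_tre_squared(fid, tgt, 3 * sigma^2)
  expect_equal(mean(tre2), pred, tolerance = 0.1)
})

test_that("center of gravity is the componentwise mean", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(center_of_gravity(cube), c(0.5, 0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(center_of_gravity(c(1, 2, 3)), c(1, 2, 3))
  set.seed(36)
  cl <- random_cloud(17)
  expect_equal(center_of_gravity(cl), apply(cl, 2, mean))
})

test_that("registration session repeats until the policy accepts", {
  lm <- tetra_landmarks()
  truth <- random_transform("plan", "reference")
  good <- transform_landmarks(truth, lm)
  noisy <- landmark_set(good$names,
                        good$points + rbind(c(4, 0, 0), c(0, -4, 0),
                                            c(0, 0, 4), c(-4, 0, 0)),
                        "reference")
  acquire <- function(attempt) if (attempt == 1) noisy else good
  res <- registration_session(lm, acquire,
                              targets = list(CON = c(0, 0, 50)),
                              accept_policy = list(fre_mm = 2.5),
                              truth = truth)
  expect_identical(res$attempt_index, 2L)
  expect_true(res$accepted)
  expect_lt(res$fre_mm, 2.5)
  expect_equal(unname(res$tre_mm[["CON"]]), 0, tolerance = 1e-9)
  # an always-accept policy stops at the first attempt regardless of FRE
  res1 <- registration_session(lm, function(a) noisy, list(),
                               accept_policy = function(r) TRUE)
  expect_identical(res1$attempt_index, 1L)
  # exhausted attempts raise a rejection error carrying the best attempt
  err <- tryCatch(
    registration_session(lm, function(a) noisy, list(),
                         accept_policy = list(fre_mm = 0.1),
                         max_attempts = 3),
    emnav_rejection_error = function(e) e)
  expect_s3_class(err$data$best, "registration_result")
})
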