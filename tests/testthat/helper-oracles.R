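# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: transforms are checked against plain 4x4
# homogeneous-matrix algebra and registration against an SVD (Kabsch)
# solution.

random_unit_quat <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) -q else q
}

random_transform <- function(source = "a", target = "b", trans_scale = 50) {
  rigid_transform(random_unit_quat(), runif(3, -trans_scale, trans_scale),
                  source, target)
}

# 4x4 homogeneous matrix built without rt_matrix/quat_to_matrix: explicit
# quaternion-to-matrix expansion written independently (column-major fill).
homog_oracle <- function(t) {
  q <- t$q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(0, 3, 3)
  R[1, 1] <- w^2 + x^2 - y^2 - z^2
  R[2, 2] <- w^2 - x^2 + y^2 - z^2
  R[3, 3] <- w^2 - x^2 - y^2 + z^2
  R[1, 2] <- 2 * (x * y - w * z); R[2, 1] <- 2 * (x * y + w * z)
  R[1, 3] <- 2 * (x * z + w * y); R[3, 1] <- 2 * (x * z - w * y)
  R[2, 3] <- 2 * (y * z - w * x); R[3, 2] <- 2 * (y * z + w * x)
  m <- rbind(cbind(R, t$t), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  m
}

# Kabsch/SVD least-squares rigid registration, with the usual det correction
# against reflections.
kabsch_oracle <- function(moving, fixed) {
  mc <- colMeans(moving); fc <- colMeans(fixed)
  H <- t(sweep(moving, 2, mc)) %*% sweep(fixed, 2, fc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = fc - as.numeric(R %*% mc))
}

kabsch_ssq <- function(moving, fixed) {
  o <- kabsch_oracle(moving, fixed)
  res <- moving %*% t(o$R) +
    matrix(o$t, nrow(moving), 3, byrow = TRUE) - fixed
  sum(res^2)
}

transform_ssq <- function(t, moving, fixed) {
  sum((rt_apply(t, moving) - fixed)^2)
}

random_cloud <- function(n, scale = 60) {
  matrix(runif(3 * n, -scale, scale), ncol = 3)
}

# four noncoplanar landmarks used in several registration tests
tetra_landmarks <- function(frame = "plan") {
  landmark_set(c("A", "B", "C", "D"),
               rbind(c(0, 0, 0), c(40, 0, 0), c(0, 35, 0), c(10, 10, 30)),
               frame)
}
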