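# Minimal unit-quaternion toolkit (internal).
#
# Convention: q = c(w, x, y, z), scalar first, representing the rotation that
# takes sensor-frame vectors to global-frame vectors: v_global = q (0,v) q*.
# All helpers operate on plain numeric vectors of length 4 / 3.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

# axis (unit 3-vector), angle in radians
quat_from_axis_angle <- function(axis, angle) {
  nrm <- sqrt(sum(axis * axis))
  if (nrm < .Machine$double.eps) return(quat_identity())
  axis <- axis / nrm
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# exponential map of a rotation vector (radians)
quat_exp <- function(rotvec) {
  theta <- sqrt(sum(rotvec * rotvec))
  if (theta < 1e-14) {
    # second-order small-angle expansion keeps unit norm to machine precision
    q <- c(1 - theta^2 / 8, rotvec / 2)
    return(quat_normalize(q))
  }
  c(cos(theta / 2), sin(theta / 2) * rotvec / theta)
}

quat_rotate <- function(q, v) {
  # Rodrigues form of q (0,v) q*
  w <- q[1]; u <- q[2:4]
  2 * sum(u * v) * u + (w * w - sum(u * u)) * v + 2 * w * crossprod3(u, v)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

quat_from_matrix <- function(R) {
  # Shepperd's method, numerically safe for proper rotations
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  quat_normalize(q)
}

# angular difference between two unit quaternions, radians
quat_angle_between <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(min(1, d))
}
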