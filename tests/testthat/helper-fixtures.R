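# Shared fixtures, built in code. Small camera/meshes keep rasterization and
# solver tests fast.

test_K <- function() camera_intrinsics(100, 100, 80, 60, 160, 120)

test_K640 <- function() default_intrinsics()

cube_fixture <- function(side = 1) cube_mesh(side)

# a generic well-conditioned pose in front of the camera
cube_pose <- function(aa = c(0.3, 0.2, 0.1), t = c(0.1, -0.05, 4)) {
  pose6d(rotation = aa, translation = t)
}

# seeded random 8-point PnP instance (non-coplanar cloud in a unit box)
random_pnp_instance <- function(seed, noise_sd = 0.5, K = test_K640()) {
  set.seed(seed)
  z <- matrix(runif(24, -1, 1), 8, 3)
  pose <- pose6d(rotation = rnorm(3) * 0.8,
                 translation = c(runif(2, -1, 1), runif(1, 6, 10)))
  x_clean <- project_points(z, pose, K)$uv
  x <- x_clean + matrix(rnorm(16, 0, noise_sd), 8, 2)
  list(z = z, pose = pose, x = x, x_clean = x_clean, K = K)
}

# finite-difference oracle for d(pose)/d(x) via warm-started re-solves
bpnp_fd_oracle <- function(x, z, K, sol, grad_pose, h = 1e-4) {
  gx <- matrix(0, nrow(x), 2)
  for (i in seq_len(nrow(x))) {
    for (cc in 1:2) {
      xp <- x; xp[i, cc] <- xp[i, cc] + h
      xm <- x; xm[i, cc] <- xm[i, cc] - h
      sp <- solve_pnp(pnp_problem(xp, z, K), init = sol$pose)
      sm <- solve_pnp(pnp_problem(xm, z, K), init = sol$pose)
      dy <- (maskpose:::pose_to_vec6(sp$pose) -
               maskpose:::pose_to_vec6(sm$pose)) / (2 * h)
      gx[i, cc] <- sum(grad_pose * dy)
    }
  }
  gx
}

tiny_net_config <- function() {
  network_config(width_mult = 0.25, input_size = c(128L, 96L))
}

tiny_camera <- function() scale_intrinsics(default_intrinsics(), 128L, 96L)
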