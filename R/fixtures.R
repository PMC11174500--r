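#' Write the canonical fixture set
#'
#' Materializes the fixtures the test suite and examples build on: the three
#' toy instrument meshes (OBJ), a default 640x480 intrinsics file, a small
#' generated mini-dataset, and the seeded random BPnP gradient-check
#' instances (JSON: 3D points, noisy projections, upstream pose gradient).
#' Deterministic: two runs with the same seed write identical trees.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_samples Mini-dataset size (default 50).
#' @param n_grad_instances Number of gradient-check instances (default 10).
#' @return Invisibly, a list of the written paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_samples = 50L,
                          n_grad_instances = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (ty in c("tube", "hook", "jaws")) {
    p <- file.path(out_dir, paste0(ty, ".obj"))
    write_obj(toy_instrument(ty), p)
    paths[[ty]] <- p
  }
  K <- default_intrinsics()
  paths$intrinsics <- write_intrinsics(K, file.path(out_dir, "intrinsics.yaml"))
  mesh <- toy_instrument("hook")
  manifest <- generate_dataset(mesh, K, default_pose_ranges(mesh),
                               n = n_samples, seed = seed,
                               out_dir = file.path(out_dir, "mini_dataset"),
                               instrument_id = "hook")
  paths$dataset <- file.path(out_dir, "mini_dataset")
  inst <- lapply(seq_len(n_grad_instances), function(i) {
    old <- local_seed(sub_seed(seed, 500L + i))
    on.exit(restore_seed(old))
    z <- matrix(runif(24, -1, 1), 8, 3)
    pose <- pose6d(rotation = rnorm(3) * 0.8,
                   translation = c(runif(2, -1, 1), runif(1, 6, 10)))
    x <- project_points(z, pose, K)$uv + matrix(rnorm(16, 0, 0.5), 8, 2)
    list(z = z, x = round(x, 9), grad_pose = round(rnorm(6), 9),
         pose = pose_to_record(pose))
  })
  gpath <- file.path(out_dir, "bpnp_grad_instances.json")
  jsonlite::write_json(inst, gpath, auto_unbox = TRUE, digits = NA)
  paths$grad_instances <- gpath
  invisible(paths)
}

#' Load the BPnP gradient-check instances
#'
#' @param path JSON file written by [make_fixtures()].
#' @return List of instances (`z`, `x`, `grad_pose`, generating `pose`).
#' @export
read_grad_instances <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    list(z = do.call(rbind, lapply(r$z, unlist)),
         x = do.call(rbind, lapply(r$x, unlist)),
         grad_pose = unlist(r$grad_pose),
         pose = pose_from_record(list(
           quaternion_wxyz = unlist(r$pose$quaternion_wxyz),
           translation_xyz = unlist(r$pose$translation_xyz),
           convention = r$pose$convention)))
  })
}
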