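# shared fixture builders; everything is generated in code under fixed seeds

rand_image <- function(side = 64, seed = 1) {
  set.seed(seed)
  matrix(runif(side * side), side, side)
}

small_movie <- function(side = 64, levels = 3, n_harmonics = 8,
                        n_cycles = 2, seed = 4) {
  generate_movie(rand_image(side, seed), levels = levels,
                 n_harmonics = n_harmonics, frames_per_cycle = 200,
                 n_cycles = n_cycles, seed = seed)
}

null_study <- function(n_voxels = 500, seed = 11, n_runs = 3) {
  generate_study(
    spec = roi_spec(names = "NULLROI", n_voxels = n_voxels, fraction = 0,
                    amplitude = 0, category = NA),
    seed = seed, n_runs = n_runs
  )
}

rel_dev <- function(a, b) {
  d <- abs(a - b) / pmax(abs(b), 1e-300)
  d[b == 0] <- abs(a[b == 0])
  max(d)
}
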