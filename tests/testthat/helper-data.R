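# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# Isotropic Gaussian blobs with planted labels.
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 42) {
  set.seed(seed)
  k <- nrow(centers)
  d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(stats::rnorm(n_per * d, mean = rep(centers[j, ], each = n_per),
                        sd = sd), n_per, d)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Minimal 3-spot dataset with recognizable entries.
tiny_dataset <- function() {
  counts <- matrix(c(1, 2, 3,
                     4, 5, 6,
                     7, 8, 9), 3, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("gA", "gB", "gC")))
  spatial_dataset(counts, cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
}

# Small simulated section shared by the cheaper pipeline tests.
small_sim <- function(seed = 7) {
  simulate_tissue(sim_config(n_rows = 15, n_cols = 15, n_domains = 3,
                             n_genes = 120, n_markers_per_domain = 8,
                             n_housekeeping = 10, seed = seed))
}

# Reduced-epoch training for contract tests where convergence quality is
# not what is being asserted.
fast_training <- function() training_config(epochs = c(50L, 30L, 50L))

# Write a 3-spot 10x-style triplet into dir; returns paths.
write_toy_mtx <- function(dir, extra_barcode = FALSE) {
  ds <- tiny_dataset()
  write_dataset(ds, dir)
  if (extra_barcode) {
    pos <- utils::read.csv(file.path(dir, "positions.csv"))
    pos <- rbind(pos, data.frame(spot_id = "ghost", x = 9, y = 9))
    utils::write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  }
  list(mtx = file.path(dir, "matrix.mtx"),
       positions = file.path(dir, "positions.csv"))
}
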