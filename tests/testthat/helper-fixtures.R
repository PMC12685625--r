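# Compact phantom geometry for unit tests (the package defaults are used in
# the end-to-end checks; this grid keeps registration-heavy tests quick).
small_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(36, 44, 32), voxel_spacing = c(3.5, 3.5, 3.5),
         brain_radii = c(52, 66, 44), lesion_center = c(27, 6, 3),
         lesion_radii = c(16, 14, 12)),
    list(...))
  do.call(phantom_config, args)
}

small_atlas <- function() {
  default_atlas(grid_shape = c(36, 44, 32), voxel_spacing = c(3.5, 3.5, 3.5),
                brain_radii = c(52, 66, 44))
}

# A flat test volume with a handful of voxels set explicitly.
flat_volume <- function(shape = c(8, 8, 8), value = 30, spacing = c(2, 2, 2)) {
  ct_volume(array(value, shape), spacing)
}

# Brute-force NWU: explicit voxel loop, independent of compute_nwu's
# vectorized path.
nwu_bruteforce <- function(volume, lesion_roi, reference_roi) {
  d <- dim(volume$data)
  s_l <- n_l <- s_r <- n_r <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lesion_roi$data[i, j, k] == 1) {
      s_l <- s_l + volume$data[i, j, k]; n_l <- n_l + 1
    }
    if (reference_roi$data[i, j, k] == 1) {
      s_r <- s_r + volume$data[i, j, k]; n_r <- n_r + 1
    }
  }
  (1 - (s_l / n_l) / (s_r / n_r)) * 100
}

# Exact Mann-Whitney U and one-sided P(U <= observed) by enumerating every
# assignment of the pooled sample to the two groups.
mwu_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  list(u = u_obs, p_le = mean(us <= u_obs))
}

# Exact Fisher p for a 2x2 table by enumerating all tables with the observed
# margins and summing probabilities no larger than the observed one.
fisher_enumerate <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  p_of <- function(a) stats::dhyper(a, r[1], r[2], cs[1])
  as_range <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  p_obs <- p_of(tab[1, 1])
  sum(vapply(as_range, p_of, numeric(1))[vapply(as_range, p_of, numeric(1)) <=
                                           p_obs * (1 + 1e-7)])
}
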