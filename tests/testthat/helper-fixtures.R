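# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_bundle <- function(variant = "allen", seed = 1) {
  cached(paste0("bundle_", variant, "_", seed),
         make_toy_atlas(seed, variant = variant))
}

demo_homography <- function() {
  matrix(c(1.02, 0.015, -1.5,
           -0.01, 0.985, 1.2,
           2e-5, -1.5e-5, 1), 3, 3, byrow = TRUE)
}

# A rendered synthetic slice with mild projective ground truth.
toy_fixture <- function(seed = 7) {
  cached(paste0("fixture_", seed), {
    make_synthetic_slice(toy_bundle(), slice_plane("coronal", 0),
                         c("2" = 25, "3" = 15, "4" = 10),
                         matrix_transform(demo_homography()), seed = seed)
  })
}

# Independent per-point oracle: map one raw coordinate through the full
# geometric chain (downsample/pad -> planar transform -> pixel -> voxel ->
# label) using nothing but explicit arithmetic and direct array indexing.
brute_force_assign <- function(x_raw, y_raw, f, pad, H, bundle, sp) {
  xp <- x_raw * f + pad[2]
  yp <- y_raw * f + pad[1]
  w <- H[3, 1] * xp + H[3, 2] * yp + H[3, 3]
  xa <- (H[1, 1] * xp + H[1, 2] * yp + H[1, 3]) / w
  ya <- (H[2, 1] * xp + H[2, 2] * yp + H[2, 3]) / w
  r <- floor(ya + 0.5); c <- floor(xa + 0.5)
  dims <- dim(bundle$annotation)
  axs <- switch(sp$plane,
                coronal = c(1L, 2L, 3L), sagittal = c(3L, 2L, 1L),
                transverse = c(2L, 1L, 3L))  # normal, row, col
  nr <- dims[axs[2]]; nc <- dims[axs[3]]
  if (r < 0 || r > nr - 1 || c < 0 || c > nc - 1) return(0L)
  base <- mm_to_index(bundle, sp$position_mm, sp$plane)
  n <- floor(base + tan(sp$ml_tilt_deg * pi / 180) * (c - (nc - 1) / 2) +
               tan(sp$dv_tilt_deg * pi / 180) * (r - (nr - 1) / 2) + 0.5)
  if (n < 0 || n > dims[axs[1]] - 1) return(0L)
  vox <- integer(3)
  vox[axs] <- c(n, r, c)
  as.integer(bundle$annotation[vox[1] + 1, vox[2] + 1, vox[3] + 1])
}
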