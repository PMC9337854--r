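# Shared fixtures, built in code at test time.

# digital solid ball mask as a label_volume (1 um isotropic by default)
make_ball <- function(r_um, voxel = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * (r_um + pad) / voxel) + 1
  ctr <- (n - 1) / 2 * voxel
  g <- array(0L, n)
  dz2 <- ((seq_len(n[1]) - 1) * voxel[1] - ctr[1])^2
  dy2 <- ((seq_len(n[2]) - 1) * voxel[2] - ctr[2])^2
  dx2 <- ((seq_len(n[3]) - 1) * voxel[3] - ctr[3])^2
  d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  g[d2 <= r_um^2] <- 1L
  label_volume(g, voxel)
}

# spherical shell mask r_in < r <= r_out
make_shell <- function(r_in, r_out, voxel = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * (r_out + pad) / voxel) + 1
  ctr <- (n - 1) / 2 * voxel
  dz2 <- ((seq_len(n[1]) - 1) * voxel[1] - ctr[1])^2
  dy2 <- ((seq_len(n[2]) - 1) * voxel[2] - ctr[2])^2
  dx2 <- ((seq_len(n[3]) - 1) * voxel[3] - ctr[3])^2
  d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  g <- array(0L, n)
  g[d2 <= r_out^2 & d2 > r_in^2] <- 1L
  label_volume(g, voxel)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

best_jaccard <- function(gt_mask, labels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(0)
  max(vapply(ids, function(j) jaccard(gt_mask, labels == j), numeric(1)))
}

# brute-force exposed-face surface area oracle: count voxel faces between
# object and background, each weighted by its physical face area
face_count_area <- function(mask, voxel) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  a <- 0
  face <- c(voxel[2] * voxel[3], voxel[1] * voxel[3], voxel[1] * voxel[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3]]
    a <- a + sum(mask & !nb) * face[ceiling(k / 2)]
  }
  a
}

# random compact connected blob: largest component of a thresholded
# smoothed noise field (rough voxel-grown blobs are sponge-like and have
# no well-defined continuum surface to compare against)
make_blob <- function(dim3 = c(26, 26, 26), seed = 1, q = 0.92) {
  with_seed(seed, {
    f <- gaussian_blur3(array(rnorm(prod(dim3)), dim3), 3)
    lab <- othg:::cpp_label_components(f > quantile(f, q),
                                       as.integer(dim3))
    big <- which.max(tabulate(lab[lab > 0]))
    lab == big
  })
}

# minimal single-page 8-bit TIFF with NO voxel-size metadata
write_bare_tiff <- function(path, ny = 4, nx = 5) {
  u16 <- othg:::raw_u16; u32 <- othg:::raw_u32
  entry <- othg:::ifd_entry
  sv <- function(x) c(u16(x), raw(2))
  strip_off <- 8L + 2L + 9L * 12L + 4L
  ent <- list(
    entry(256L, 3L, 1L, sv(nx)), entry(257L, 3L, 1L, sv(ny)),
    entry(258L, 3L, 1L, sv(8L)), entry(259L, 3L, 1L, sv(1L)),
    entry(262L, 3L, 1L, sv(1L)), entry(273L, 4L, 1L, u32(strip_off)),
    entry(277L, 3L, 1L, sv(1L)), entry(278L, 3L, 1L, sv(ny)),
    entry(279L, 4L, 1L, u32(ny * nx)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42L), u32(8L), u16(length(ent)),
             unlist(ent), u32(0L), as.raw(seq_len(ny * nx) %% 256)), con)
  path
}
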