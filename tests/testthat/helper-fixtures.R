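# Shared fixtures and independent oracles for the suite.

# Independent quaternion -> rotation-matrix route (axis-angle + Rodrigues),
# deliberately different from the package's homogeneous-quadratic form.
rodrigues_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; v <- q[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-15) return(diag(3))
  theta <- 2 * atan2(nv, w)
  k <- v / nv
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Random centered point cloud (L x 3).
random_points <- function(L, sd = 5) {
  p <- matrix(rnorm(L * 3, sd = sd), L, 3)
  sweep(p, 2, colMeans(p))
}

# Build a coord_batch directly from a list of L x 3 coordinate matrices
# and an optional mask, bypassing file I/O.
batch_from_coords <- function(coord_list, mask = NULL) {
  n <- length(coord_list)
  L <- nrow(coord_list[[1]])
  coords <- array(0, c(n, L, 3))
  for (i in seq_len(n)) coords[i, , ] <- coord_list[[i]]
  if (is.null(mask)) mask <- matrix(1, n, L)
  structure(list(coords = coords, mask = mask,
                 names = sprintf("mem_%03d", seq_len(n)),
                 failures = character(0)),
            class = "coord_batch")
}

# Reference frame built directly from centered coordinates.
frame_from_coords <- function(ref_coords, centroid = c(0, 0, 0)) {
  structure(list(residue_keys = sprintf("A|%d| ", seq_len(nrow(ref_coords))),
                 ref_coords = ref_coords,
                 ref_centroid = centroid,
                 selection = parse_selection(NULL)),
            class = "reference_frame")
}

# Random instance generator used by the oracle-equivalence checks:
# exact rotated copies of a random reference, plus optional noise and
# deletions, centered by the package's own convention.
make_oracle_instance <- function(L, sigma, delfrac, n = 10, seed = 1) {
  set.seed(seed)
  ref <- random_points(L)
  coords <- array(0, c(n, L, 3))
  mask <- matrix(1, n, L)
  for (i in seq_len(n)) {
    R <- rodrigues_matrix(rnorm(4))
    p <- ref %*% t(R) + matrix(rnorm(L * 3, sd = sigma), L, 3)
    if (delfrac > 0) mask[i, sample(L, round(delfrac * L))] <- 0
    coords[i, , ] <- p
  }
  list(batch = batch_from_coords(lapply(seq_len(n), function(i) coords[i, , ]),
                                 mask),
       frame = frame_from_coords(ref))
}

# Bind N x L x 3 arrays along the first dimension.
abind_1 <- function(...) {
  parts <- list(...)
  L <- dim(parts[[1]])[2]
  n <- sum(vapply(parts, function(a) dim(a)[1], 1L))
  out <- array(0, c(n, L, 3))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# A minimal handwritten PDB text block (3 residues, CA only + one N).
tiny_pdb_lines <- function() {
  c("HEADER    SYNTHETIC TEST",
    "ATOM      1  N   ALA A   1      11.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   2      13.800  10.000  10.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   3      13.800  13.800  10.000  1.00  0.00           C",
    "END")
}

write_tmp_pdb <- function(lines, name = "f.pdb") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
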