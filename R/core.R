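#' Initialize a batch of rotation quaternions
#'
#' Each of the four components is drawn i.i.d. uniform on \[0, 1). The rows
#' are deliberately not normalized: normalization happens inside every
#' rotation evaluation, so the optimizer works on unconstrained vectors.
#'
#' @param n Number of structures.
#' @param seed Integer seed; the draw is reproducible.
#' @return An `n x 4` matrix, columns (w, x, y, z).
#' @export
init_quaternions <- function(n, seed = 0L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  matrix(stats::runif(n * 4L), n, 4L)
}

#' Rotation matrix of a quaternion
#'
#' Hamilton-convention conversion of a (not necessarily unit) quaternion
#' `(w, x, y, z)` to the equivalent proper rotation matrix; the quaternion
#' is normalized implicitly, so `q` and any positive multiple of it give
#' the same matrix, and `q` and `-q` encode the same rotation.
#'
#' @param q Numeric length-4 vector (w, x, y, z).
#' @return A 3 x 3 proper orthogonal matrix.
#' @export
quat_rotation_matrix <- function(q) {
  stopifnot(length(q) == 4L)
  matrix(.quat_rot_cols(matrix(q, 1L, 4L)), 3L, 3L, byrow = TRUE)
}

## Batched quaternion -> rotation entries. q: N x 4 -> N x 9, row-major
## (R11, R12, R13, R21, ..., R33). Division by the squared norm makes the
## map scale-invariant, which is what lets the optimizer run unconstrained.
.quat_rot_cols <- function(q) {
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  s <- w * w + x * x + y * y + z * z
  if (any(s < 1e-24)) {
    stop("degenerate quaternion (zero norm) at row ",
         which(s < 1e-24)[1L], call. = FALSE)
  }
  cbind((w * w + x * x - y * y - z * z) / s,
        2 * (x * y - w * z) / s,
        2 * (x * z + w * y) / s,
        2 * (x * y + w * z) / s,
        (w * w - x * x + y * y - z * z) / s,
        2 * (y * z - w * x) / s,
        2 * (x * z - w * y) / s,
        2 * (y * z + w * x) / s,
        (w * w - x * x - y * y + z * z) / s)
}

#' Rotate a batch of coordinate sets
#'
#' Applies the rotation encoded by row i of `q` to the i-th `L x 3`
#' coordinate slab. Quaternions are normalized internally.
#'
#' @param q `N x 4` quaternion matrix (rows may be unnormalized).
#' @param coords `N x L x 3` array.
#' @return An `N x L x 3` array of rotated coordinates.
#' @export
rotate_batch <- function(q, coords) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[3L] == 3L, nrow(q) == dim(coords)[1L])
  R <- .quat_rot_cols(q)
  cx <- coords[, , 1L, drop = FALSE]; dim(cx) <- dim(coords)[1:2]
  cy <- coords[, , 2L, drop = FALSE]; dim(cy) <- dim(coords)[1:2]
  cz <- coords[, , 3L, drop = FALSE]; dim(cz) <- dim(coords)[1:2]
  out <- array(0, dim(coords))
  out[, , 1L] <- cx * R[, 1L] + cy * R[, 2L] + cz * R[, 3L]
  out[, , 2L] <- cx * R[, 4L] + cy * R[, 5L] + cz * R[, 6L]
  out[, , 3L] <- cx * R[, 7L] + cy * R[, 8L] + cz * R[, 9L]
  out
}

#' Masked RMSD against a reference
#'
#' Per structure i, `sqrt( sum_j mask[i,j] * |coords[i,j,] - ref[j,]|^2 /
#' sum_j mask[i,j] )`. Masked slots contribute nothing, whatever their
#' coordinate values.
#'
#' @param coords `N x L x 3` array.
#' @param ref `L x 3` reference coordinates.
#' @param mask `N x L` binary matrix; every row must have at least one 1.
#' @return Numeric vector of length N, in the units of the coordinates.
#' @export
masked_rmsd <- function(coords, ref, mask) {
  n <- dim(coords)[1L]; L <- dim(coords)[2L]
  stopifnot(nrow(ref) == L, all(dim(mask) == c(n, L)))
  cnt <- rowSums(mask)
  if (any(cnt == 0)) {
    stop("mask row ", which(cnt == 0)[1L], " has no unmasked residues",
         call. = FALSE)
  }
  d2 <- matrix(0, n, L)
  for (d in 1:3) {
    dd <- coords[, , d, drop = FALSE]; dim(dd) <- c(n, L)
    dd <- dd - matrix(ref[, d], n, L, byrow = TRUE)
    d2 <- d2 + dd * dd
  }
  sqrt(rowSums(d2 * mask) / cnt)
}

#' Center a coordinate batch on per-structure masked centroids
#'
#' Each structure's centroid is the mean of its unmasked CA positions only;
#' the centroid is subtracted from unmasked rows and masked rows are reset
#' to exactly zero, so downstream arithmetic never sees masked values.
#'
#' @param batch A `coord_batch` (see [load_coords()]), or any list with
#'   `coords` (N x L x 3) and `mask` (N x L).
#' @return List with `batch` (the centered `coord_batch`) and `centroids`
#'   (N x 3 matrix).
#' @export
center_batch <- function(batch) {
  coords <- batch$coords; mask <- batch$mask
  n <- dim(coords)[1L]; L <- dim(coords)[2L]
  cnt <- rowSums(mask)
  if (any(cnt == 0)) {
    stop("structure ", which(cnt == 0)[1L], " has no unmasked residues",
         call. = FALSE)
  }
  centroids <- matrix(0, n, 3L)
  for (d in 1:3) {
    dd <- coords[, , d, drop = FALSE]; dim(dd) <- c(n, L)
    centroids[, d] <- rowSums(dd * mask) / cnt
    coords[, , d] <- (dd - centroids[, d]) * mask
  }
  batch$coords <- coords
  list(batch = batch, centroids = centroids)
}

#' Two-phase gradient-descent schedule
#'
#' The coarse phase takes large steps to traverse the rotation space; the
#' fine-tuning phase always runs a fixed number of smaller steps to settle
#' into the optimum. The coarse-phase length is a non-increasing function
#' of the number of selected residues: larger selections average away noise
#' in the loss surface and converge in fewer steps, while very small
#' selections (a handful of points) can sit near flat saddle regions of the
#' rotation landscape and need a longer exploration phase.
#'
#' @param phase1_lr Coarse step size (default 0.3). Step sizes are
#'   dimensionless: gradients are rescaled per structure by the mean
#'   squared CA distance to the centroid, so the same defaults work for
#'   20-residue peptides and 1000-residue complexes.
#' @param phase2_lr Fine-tuning step size (default 0.1); must be smaller
#'   than `phase1_lr`.
#' @param phase1_steps Coarse-phase length, or `NULL` to use
#'   `clamp(round(6000 / sqrt(L)), 300, 3000)` where L is the number of
#'   selected residues.
#' @param phase2_steps Fixed fine-tuning length (default 200).
#' @param seed Integer seed for quaternion initialization.
#' @return An object of class `optimizer_schedule`.
#' @export
optimizer_schedule <- function(phase1_lr = 0.3, phase2_lr = 0.1,
                               phase1_steps = NULL, phase2_steps = 200L,
                               seed = 0L) {
  stopifnot(phase1_lr > 0, phase2_lr > 0, phase2_steps >= 1L)
  if (phase1_lr <= phase2_lr) {
    stop("phase1_lr must exceed phase2_lr", call. = FALSE)
  }
  structure(
    list(phase1_lr = phase1_lr, phase2_lr = phase2_lr,
         phase1_steps = phase1_steps, phase2_steps = as.integer(phase2_steps),
         seed = as.integer(seed)),
    class = "optimizer_schedule"
  )
}

#' Default coarse-phase length for a selection of L residues
#'
#' @param L Number of selected residues.
#' @return Integer step count, non-increasing in `L`.
#' @export
default_phase1_steps <- function(L) {
  as.integer(pmax(300, pmin(3000, round(6000 / sqrt(L)))))
}

#' Construct a rigid transform
#'
#' The transform maps model coordinates onto the reference frame:
#' `p -> R(quaternion) (p - model_centroid) + ref_centroid`.
#'
#' @param model_centroid Length-3 vector: centroid of the model's selected
#'   (unmasked) CA coordinates.
#' @param ref_centroid Length-3 vector: centroid of the reference selection.
#' @param quaternion Length-4 unit quaternion (w, x, y, z).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(model_centroid, ref_centroid, quaternion) {
  stopifnot(length(model_centroid) == 3L, length(ref_centroid) == 3L,
            length(quaternion) == 4L, all(is.finite(quaternion)))
  structure(
    list(model_centroid = as.numeric(model_centroid),
         ref_centroid = as.numeric(ref_centroid),
         quaternion = as.numeric(quaternion)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to raw coordinates
#'
#' @param transform A `rigid_transform`.
#' @param coords `L x 3` matrix of coordinates.
#' @return `L x 3` matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- quat_rotation_matrix(transform$quaternion)
  p <- sweep(as.matrix(coords), 2L, transform$model_centroid)
  sweep(p %*% t(R), 2L, transform$ref_centroid, FUN = "+")
}

#' Geodesic angle between two rotations, in degrees
#'
#' Computed from the quaternion inner product; insensitive to the q / -q
#' sign ambiguity.
#'
#' @param q1,q2 Length-4 quaternions (normalized internally).
#' @return Angle in degrees, in \[0, 180\].
#' @export
quat_angle <- function(q1, q2) {
  q1 <- q1 / sqrt(sum(q1^2))
  q2 <- q2 / sqrt(sum(q2^2))
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d) * 180 / pi
}

#' Optimize rotation quaternions by two-phase gradient descent
#'
#' Jointly optimizes one quaternion per structure to minimize the masked
#' mean squared deviation of its CA coordinates from the reference — the
#' same minimizer as the masked RMSD, with smoother gradients near zero.
#' All structures are updated simultaneously through batched array
#' operations; no covariance matrices or per-structure decompositions are
#' formed. Gradients are analytic, taken through the scale-invariant
#' quaternion-to-rotation map, and rescaled per structure by the mean
#' squared CA norm so the step sizes are dimensionless.
#'
#' @param batch A `coord_batch`. Centered internally via [center_batch()]
#'   unless `centroids` is supplied (in which case `batch` must already be
#'   centered).
#' @param frame A `reference_frame` (its `ref_coords` are already centered).
#' @param schedule An `optimizer_schedule`; `NULL` for defaults.
#' @param centroids Optional `N x 3` matrix of pre-computed model centroids.
#' @param init Optional `N x 4` initial quaternion matrix (defaults to
#'   [init_quaternions()] with the schedule seed).
#' @param keep_trace If `TRUE`, record the per-structure loss (mean squared
#'   deviation) at every step in a `steps x N` matrix `trace`.
#' @return An object of class `superposition_result`: list with
#'   `transforms` (list of N `rigid_transform`), `rmsd` (length N, masked
#'   CA RMSD at the optimum), `quaternions` (N x 4 unit matrix),
#'   `iterations_used` (length N), `names`, and optionally `trace`.
#' @export
optimize_quaternions <- function(batch, frame, schedule = NULL,
                                 centroids = NULL, init = NULL,
                                 keep_trace = FALSE) {
  stopifnot(inherits(frame, "reference_frame"))
  if (is.null(schedule)) schedule <- optimizer_schedule()
  if (is.null(centroids)) {
    cen <- center_batch(batch)
    batch <- cen$batch
    centroids <- cen$centroids
  }
  coords <- batch$coords
  mask <- batch$mask
  ref <- frame$ref_coords
  n <- dim(coords)[1L]; L <- dim(coords)[2L]
  stopifnot(nrow(ref) == L)
  cnt <- rowSums(mask)
  if (any(cnt < 3)) {
    stop("structure ", which(cnt < 3)[1L],
         " has fewer than 3 unmasked residues", call. = FALSE)
  }

  n1 <- schedule$phase1_steps
  if (is.null(n1)) n1 <- default_phase1_steps(L)
  n2 <- schedule$phase2_steps
  q <- if (is.null(init)) init_quaternions(n, schedule$seed) else init
  stopifnot(nrow(q) == n, ncol(q) == 4L)

  cx <- coords[, , 1L, drop = FALSE]; dim(cx) <- c(n, L)
  cy <- coords[, , 2L, drop = FALSE]; dim(cy) <- c(n, L)
  cz <- coords[, , 3L, drop = FALSE]; dim(cz) <- c(n, L)
  rx <- matrix(ref[, 1L], n, L, byrow = TRUE)
  ry <- matrix(ref[, 2L], n, L, byrow = TRUE)
  rz <- matrix(ref[, 3L], n, L, byrow = TRUE)
  ## per-structure gradient preconditioner: mean squared CA norm (A^2)
  s2 <- rowSums((cx * cx + cy * cy + cz * cz) * mask) / cnt

  lrs <- c(rep(schedule$phase1_lr, n1), rep(schedule$phase2_lr, n2))
  trace <- if (keep_trace) matrix(NA_real_, length(lrs), n) else NULL

  for (step in seq_along(lrs)) {
    w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
    s <- w * w + x * x + y * y + z * z
    R11 <- (w * w + x * x - y * y - z * z) / s
    R12 <- 2 * (x * y - w * z) / s
    R13 <- 2 * (x * z + w * y) / s
    R21 <- 2 * (x * y + w * z) / s
    R22 <- (w * w - x * x + y * y - z * z) / s
    R23 <- 2 * (y * z - w * x) / s
    R31 <- 2 * (x * z - w * y) / s
    R32 <- 2 * (y * z + w * x) / s
    R33 <- (w * w - x * x - y * y + z * z) / s
    dx <- (cx * R11 + cy * R12 + cz * R13 - rx) * mask
    dy <- (cx * R21 + cy * R22 + cz * R23 - ry) * mask
    dz <- (cx * R31 + cy * R32 + cz * R33 - rz) * mask
    ## dLoss/dR, loss = masked mean squared deviation
    G11 <- 2 * rowSums(dx * cx) / cnt
    G12 <- 2 * rowSums(dx * cy) / cnt
    G13 <- 2 * rowSums(dx * cz) / cnt
    G21 <- 2 * rowSums(dy * cx) / cnt
    G22 <- 2 * rowSums(dy * cy) / cnt
    G23 <- 2 * rowSums(dy * cz) / cnt
    G31 <- 2 * rowSums(dz * cx) / cnt
    G32 <- 2 * rowSums(dz * cy) / cnt
    G33 <- 2 * rowSums(dz * cz) / cnt
    GR <- G11 * R11 + G12 * R12 + G13 * R13 +
          G21 * R21 + G22 * R22 + G23 * R23 +
          G31 * R31 + G32 * R32 + G33 * R33
    ## chain rule through R = M(q)/|q|^2 (dM/dq is linear in q)
    gw <- (2 * ( w * (G11 + G22 + G33) - z * G12 + y * G13 + z * G21 -
                 x * G23 - y * G31 + x * G32) - 2 * w * GR) / s
    gx <- (2 * ( x * (G11 - G22 - G33) + y * G12 + z * G13 + y * G21 -
                 w * G23 + z * G31 + w * G32) - 2 * x * GR) / s
    gy <- (2 * (-y * (G11 - G22 + G33) + x * G12 + w * G13 + x * G21 +
                 z * G23 - w * G31 + z * G32) - 2 * y * GR) / s
    gz <- (2 * (-z * (G11 + G22 - G33) - w * G12 + x * G13 + w * G21 +
                 y * G23 + x * G31 + y * G32) - 2 * z * GR) / s
    if (keep_trace) {
      trace[step, ] <- rowSums(dx * dx + dy * dy + dz * dz) / cnt
    }
    q <- q - (lrs[step] / s2) * cbind(gw, gx, gy, gz)
    if (any(!is.finite(q))) {
      stop("non-finite loss during descent at structure ",
           which(rowSums(!is.finite(q)) > 0)[1L], call. = FALSE)
    }
  }

  qn <- q / sqrt(rowSums(q * q))
  rmsd <- masked_rmsd(rotate_batch(qn, coords), ref, mask)
  if (any(!is.finite(rmsd))) {
    stop("non-finite loss during descent at structure ",
         which(!is.finite(rmsd))[1L], call. = FALSE)
  }
  transforms <- lapply(seq_len(n), function(i) {
    rigid_transform(centroids[i, ], frame$ref_centroid, qn[i, ])
  })
  out <- list(transforms = transforms, rmsd = rmsd, quaternions = qn,
              iterations_used = rep.int(n1 + n2, n),
              names = batch$names)
  if (keep_trace) out$trace <- trace
  structure(out, class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result> ", length(x$rmsd), " structures\n",
      "  RMSD: mean ", format(mean(x$rmsd), digits = 4),
      ", sd ", format(stats::sd(x$rmsd), digits = 4),
      ", max ", format(max(x$rmsd), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Closed-form optimal superimposition (Kabsch SVD)
#'
#' Computes the provably optimal proper rotation between two point sets
#' with known correspondence, via SVD of the cross-covariance matrix with
#' the usual determinant correction that excludes reflections. Serves as
#' the exact oracle against which the gradient-descent path is tested, and
#' as an exact single-structure backend.
#'
#' Inputs are used as given (no re-centering): the optimal rotation of the
#' linear objective depends only on the cross-covariance, so the caller's
#' centering convention — model centered on its masked centroid, reference
#' centered once on the full selection — is respected.
#'
#' @param coords `L x 3` model coordinates.
#' @param ref `L x 3` reference coordinates.
#' @param mask Optional binary vector of length L; only unmasked rows
#'   (mask 1) enter the fit. Default: all rows.
#' @return List with `rotation` (3 x 3, det +1) and `rmsd` (over the
#'   unmasked rows, after applying the rotation to `coords`).
#' @export
kabsch_superimpose <- function(coords, ref, mask = NULL) {
  coords <- as.matrix(coords); ref <- as.matrix(ref)
  stopifnot(ncol(coords) == 3L, all(dim(coords) == dim(ref)))
  if (!is.null(mask)) {
    keep <- mask != 0
    coords <- coords[keep, , drop = FALSE]
    ref <- ref[keep, , drop = FALSE]
  }
  if (nrow(coords) < 3L) {
    stop("need at least 3 unmasked points", call. = FALSE)
  }
  sv_p <- svd(sweep(coords, 2L, colMeans(coords)))$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1e-12)) {
    stop("rank-deficient: point set is collinear", call. = FALSE)
  }
  H <- crossprod(coords, ref)            # 3x3 cross-covariance p^T r
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- coords %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((rot - ref)^2))))
}
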