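#' Generate a synthetic self-avoiding CA backbone
#'
#' Builds a protein-like alpha-carbon trace as a self-avoiding random walk
#' with consecutive-CA distances drawn uniformly from 3.65-3.95 Å (around
#' the canonical 3.8 Å trans-peptide spacing) and no two non-consecutive
#' CAs closer than 2.2 Å. Each residue also carries three dummy backbone
#' atoms (N, C, O) at fixed offsets from its CA so that the files exercise
#' the all-atom transform path; the dummy geometry is not stereochemically
#' meaningful. Residues are named ALA, chain A, numbered 1..n.
#'
#' @param n_residues Number of residues (>= 3).
#' @param seed Integer seed; the trace is reproducible.
#' @return A `pdb_structure` (see [parse_pdb()]).
#' @export
make_backbone <- function(n_residues, seed = 0L) {
  stopifnot(n_residues >= 3L)
  set.seed(seed)
  ca <- matrix(0, n_residues, 3L)
  dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
  for (i in 2:n_residues) {
    placed <- FALSE
    for (try in 1:200) {
      ## persistence keeps the walk locally stiff, like a real chain
      cand_dir <- dir * 0.6 + stats::rnorm(3L) * 0.6
      cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
      step <- stats::runif(1L, 3.65, 3.95)
      cand <- ca[i - 1L, ] + cand_dir * step
      if (i > 2L) {
        prev <- ca[seq_len(i - 2L), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2L, cand)^2)
        if (min(d2) < 2.2^2) next
      }
      ca[i, ] <- cand
      dir <- cand_dir
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("backbone generation failed to avoid clashes; try another seed",
           call. = FALSE)
    }
  }

  ## dummy N/C/O companions at fixed offsets from each CA
  off <- rbind(N = c(-0.95, 0.80, 0.60),
               C = c(1.00, -0.85, 0.60),
               O = c(1.30, -0.60, 1.75))
  nm <- c("N", "CA", "C", "O")
  n_at <- n_residues * 4L
  atoms <- data.frame(
    record = "ATOM",
    serial = seq_len(n_at),
    atom_name = rep(nm, n_residues),
    alt_loc = " ",
    res_name = "ALA",
    chain = "A",
    res_seq = rep(seq_len(n_residues), each = 4L),
    i_code = " ",
    x = 0, y = 0, z = 0,
    occupancy = 1,
    stringsAsFactors = FALSE
  )
  xyz <- matrix(0, n_at, 3L)
  for (r in seq_len(n_residues)) {
    base <- (r - 1L) * 4L
    xyz[base + 1L, ] <- ca[r, ] + off["N", ]
    xyz[base + 2L, ] <- ca[r, ]
    xyz[base + 3L, ] <- ca[r, ] + off["C", ]
    xyz[base + 4L, ] <- ca[r, ] + off["O", ]
  }
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  .structure_from_atoms(atoms, path = sprintf("<synthetic backbone n=%d seed=%d>",
                                              n_residues, seed))
}

#' Specification for a set of perturbed synthetic structures
#'
#' Describes how copies of a base structure are perturbed: each copy gets
#' an independent rotation drawn uniformly from SO(3) (via normalized
#' 4-component Gaussian quaternions), a translation with each component
#' uniform on ±`translation_scale`, i.i.d. Gaussian coordinate noise on all
#' atoms, and a random fraction of whole residues deleted.
#'
#' @param n_structures Number of perturbed copies.
#' @param translation_scale Half-width of the uniform translation, Å
#'   (default 20).
#' @param deletion_fraction Fraction of residues to delete, in \[0, 1);
#'   must leave at least 3 residues.
#' @param noise_sigma Standard deviation of the Gaussian coordinate noise,
#'   Å (default 0: exact rigid copies).
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_structures = 10L, translation_scale = 20,
                       deletion_fraction = 0, noise_sigma = 0, seed = 0L) {
  stopifnot(n_structures >= 1L, translation_scale >= 0,
            deletion_fraction >= 0, deletion_fraction < 1,
            noise_sigma >= 0)
  structure(
    list(n_structures = as.integer(n_structures),
         translation_scale = translation_scale,
         deletion_fraction = deletion_fraction,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Draw rotations uniformly from SO(3)
#'
#' Normalized 4-component standard Gaussians are uniform on the unit
#' 3-sphere, hence uniform over rotations under the double cover.
#'
#' @param n Number of quaternions.
#' @return `n x 4` matrix of unit quaternions.
#' @export
random_unit_quaternions <- function(n) {
  q <- matrix(stats::rnorm(n * 4L), n, 4L)
  q / sqrt(rowSums(q * q))
}

#' Perturb a base structure into a set of test copies
#'
#' Applies, per copy: `p' = R p + t` to all atoms (R uniform over SO(3),
#' t componentwise uniform on ±`translation_scale`), then Gaussian noise,
#' then deletion of `round(deletion_fraction * n_residues)` randomly chosen
#' whole residues. The exact rigid motion of each copy is returned, so
#' recovery can be checked against ground truth: for a noise-free copy,
#' `R^T (p' - t)` reproduces the base coordinates.
#'
#' @param base A `pdb_structure` (typically from [make_backbone()]).
#' @param spec A `synth_spec`.
#' @return List with `structures` (list of `pdb_structure`), `truth`
#'   (list of lists with `quaternion`, `translation`), `deleted` (list of
#'   character vectors of deleted residue keys).
#' @export
perturb_structures <- function(base, spec) {
  stopifnot(inherits(base, "pdb_structure"), inherits(spec, "synth_spec"))
  n_res <- length(base$ca_index)
  n_del <- round(spec$deletion_fraction * n_res)
  if (n_res - n_del < 3L) {
    stop("deletion_fraction leaves fewer than 3 residues", call. = FALSE)
  }
  set.seed(spec$seed)
  structures <- vector("list", spec$n_structures)
  truth <- vector("list", spec$n_structures)
  deleted <- vector("list", spec$n_structures)
  res_keys <- names(base$ca_index)
  p0 <- as.matrix(base$atoms[, c("x", "y", "z")])
  for (i in seq_len(spec$n_structures)) {
    q <- random_unit_quaternions(1L)[1L, ]
    R <- quat_rotation_matrix(q)
    tr <- stats::runif(3L, -spec$translation_scale, spec$translation_scale)
    p <- p0 %*% t(R)
    p <- sweep(p, 2L, tr, FUN = "+")
    if (spec$noise_sigma > 0) {
      p <- p + matrix(stats::rnorm(length(p), sd = spec$noise_sigma),
                      nrow(p), 3L)
    }
    atoms <- base$atoms
    atoms$x <- p[, 1L]; atoms$y <- p[, 2L]; atoms$z <- p[, 3L]
    del_keys <- character(0)
    if (n_del > 0L) {
      del_keys <- sample(res_keys, n_del)
      key_of_atom <- paste(atoms$chain, atoms$res_seq, atoms$i_code,
                           sep = "|")
      atoms <- atoms[!(key_of_atom %in% del_keys), , drop = FALSE]
      atoms$serial <- seq_len(nrow(atoms))
    }
    structures[[i]] <- .structure_from_atoms(
      atoms, path = sprintf("<synthetic copy %d>", i))
    truth[[i]] <- list(quaternion = q, translation = tr)
    deleted[[i]] <- del_keys
  }
  list(structures = structures, truth = truth, deleted = deleted)
}

#' Write a synthetic fixture directory with a ground-truth manifest
#'
#' Emits `reference.pdb` (the base backbone), one `model_NNNN.pdb` per
#' perturbed copy, and `manifest.tsv` — a tab-separated table with one row
#' per model: `filename`, quaternion components `qw qx qy qz`, translation
#' `tx ty tz`, and the comma-joined deleted residue keys. Structures are
#' generated and written in chunks so memory does not grow with
#' `n_structures`.
#'
#' @param dir Output directory (created if missing).
#' @param n_residues Residues in the base backbone.
#' @param spec A `synth_spec`.
#' @param chunk_size Structures generated per chunk (default 500).
#' @return Invisibly, a list with `reference` (path), `models` (paths),
#'   `manifest` (path).
#' @export
write_fixture_set <- function(dir, n_residues, spec, chunk_size = 500L) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- make_backbone(n_residues, seed = spec$seed)
  ref_path <- file.path(dir, "reference.pdb")
  write_pdb(base, ref_path)

  n <- spec$n_structures
  model_paths <- character(n)
  rows <- vector("list", n)
  done <- 0L
  chunk_id <- 0L
  while (done < n) {
    take <- min(chunk_size, n - done)
    ## distinct sub-seed per chunk keeps chunked generation reproducible
    sub <- synth_spec(n_structures = take,
                      translation_scale = spec$translation_scale,
                      deletion_fraction = spec$deletion_fraction,
                      noise_sigma = spec$noise_sigma,
                      seed = spec$seed + 10007L * (chunk_id + 1L))
    pert <- perturb_structures(base, sub)
    for (j in seq_len(take)) {
      i <- done + j
      fn <- sprintf("model_%05d.pdb", i)
      model_paths[i] <- file.path(dir, fn)
      write_pdb(pert$structures[[j]], model_paths[i])
      tq <- pert$truth[[j]]$quaternion
      tt <- pert$truth[[j]]$translation
      rows[[i]] <- data.frame(
        filename = fn,
        qw = tq[1L], qx = tq[2L], qy = tq[3L], qz = tq[4L],
        tx = tt[1L], ty = tt[2L], tz = tt[3L],
        deleted = paste(pert$deleted[[j]], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    done <- done + take
    chunk_id <- chunk_id + 1L
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(reference = ref_path, models = model_paths,
                 manifest = manifest_path))
}
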