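#' Parse a PDB file into a structure record
#'
#' Reads the fixed-column ATOM/HETATM records of a PDB file. For files
#' containing multiple MODEL blocks only the first model is parsed; lines
#' preceding the first MODEL record are kept so that headers survive a
#' read/write round trip. Every atom line is retained verbatim, which lets
#' [write_transformed()] reproduce all non-coordinate columns byte for byte.
#'
#' The per-residue alpha-carbon lookup (`ca_index`) contains at most one
#' entry per (chain, residue number, insertion code) key. When alternate
#' locations provide several CA atoms for one residue, the one with the
#' highest occupancy wins; ties are broken by file order. Only ATOM records
#' enter `ca_index`; HETATM atoms are carried along (and transformed on
#' output) but never drive the alignment.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_structure`: a list with elements
#'   `path`, `lines` (retained file lines), `atom_lines` (indices of
#'   ATOM/HETATM lines within `lines`), `atoms` (a data frame with one row
#'   per atom: `record`, `serial`, `atom_name`, `alt_loc`, `res_name`,
#'   `chain`, `res_seq`, `i_code`, `x`, `y`, `z`, `occupancy`), and
#'   `ca_index` (named integer vector mapping residue keys to rows of
#'   `atoms`).
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)

  ## restrict to the first MODEL when an ensemble file is given
  model_at <- which(startsWith(lines, "MODEL"))
  if (length(model_at) > 0L) {
    endmdl_at <- which(startsWith(lines, "ENDMDL"))
    stop_at <- if (length(endmdl_at) > 0L) endmdl_at[1L] else length(lines) + 1L
    keep <- setdiff(seq_len(stop_at - 1L), model_at[1L])
    lines <- lines[keep]
  }

  rec6 <- substr(lines, 1L, 6L)
  is_atom <- rec6 == "ATOM  " | rec6 == "HETATM"
  atom_lines <- which(is_atom)
  al <- lines[atom_lines]

  if (any(nchar(al) < 54L)) {
    bad <- atom_lines[which(nchar(al) < 54L)[1L]]
    stop(path, ": truncated atom record at line ", bad, call. = FALSE)
  }

  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    stop(path, ": malformed coordinate field at line ",
         atom_lines[which(bad)[1L]], call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(substr(al, 55L, 60L)))
  occ[!is.finite(occ)] <- 1.0

  atoms <- data.frame(
    record    = trimws(substr(al, 1L, 6L)),
    serial    = suppressWarnings(as.integer(substr(al, 7L, 11L))),
    atom_name = trimws(substr(al, 13L, 16L)),
    alt_loc   = substr(al, 17L, 17L),
    res_name  = trimws(substr(al, 18L, 20L)),
    chain     = substr(al, 22L, 22L),
    res_seq   = suppressWarnings(as.integer(substr(al, 23L, 26L))),
    i_code    = substr(al, 27L, 27L),
    x = x, y = y, z = z,
    occupancy = occ,
    stringsAsFactors = FALSE
  )

  if (!any(atoms$record == "ATOM")) {
    stop(path, ": no ATOM records", call. = FALSE)
  }

  structure(
    list(path = path, lines = lines, atom_lines = atom_lines,
         atoms = atoms, ca_index = .build_ca_index(atoms)),
    class = "pdb_structure"
  )
}

## Highest occupancy wins among alternate-location CAs; ties go to the
## first record in file order (order() is stable).
.build_ca_index <- function(atoms) {
  is_ca <- atoms$record == "ATOM" & atoms$atom_name == "CA"
  idx <- which(is_ca)
  if (length(idx) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  keys <- paste(atoms$chain[idx], atoms$res_seq[idx], atoms$i_code[idx],
                sep = "|")
  ord <- order(-atoms$occupancy[idx])
  pick <- ord[!duplicated(keys[ord])]
  pick <- pick[order(idx[pick])]         # restore file order of residues
  stats::setNames(idx[pick], keys[pick])
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", x$path, "\n  ",
      nrow(x$atoms), " atoms, ", length(x$ca_index),
      " CA residues\n", sep = "")
  invisible(x)
}

#' Parse a residue selection string
#'
#' Grammar: comma-separated tokens, each one of
#' \describe{
#'   \item{`"A"`}{all residues of chain A}
#'   \item{`"A:10-120"`}{residues 10 to 120 of chain A}
#'   \item{`"10-120"` or `"57"`}{a residue range or single residue on any chain}
#' }
#' e.g. `"A:10-120,B:5-30"` or `"A"`. `NULL` or `"all"` selects every residue.
#'
#' @param text Selection string, or `NULL` for all residues.
#' @return An object of class `selection_spec`.
#' @export
parse_selection <- function(text = NULL) {
  if (is.null(text) || identical(tolower(trimws(text)), "all") ||
      !nzchar(trimws(text))) {
    return(structure(list(items = NULL, text = "all"),
                     class = "selection_spec"))
  }
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  toks <- toks[nzchar(toks)]
  items <- lapply(toks, function(tok) {
    chain <- NA_character_
    range_part <- tok
    if (grepl(":", tok, fixed = TRUE)) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !nzchar(parts[1L])) {
        stop("bad selection token: '", tok, "'", call. = FALSE)
      }
      chain <- parts[1L]
      range_part <- parts[2L]
    }
    if (grepl("^[A-Za-z]$", range_part) && is.na(chain)) {
      return(list(chain = range_part, from = NA_integer_, to = NA_integer_))
    }
    if (!nzchar(range_part)) {
      return(list(chain = chain, from = NA_integer_, to = NA_integer_))
    }
    m <- regmatches(range_part,
                    regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", range_part))[[1L]]
    if (length(m) == 0L) {
      stop("bad selection token: '", tok, "'", call. = FALSE)
    }
    from <- as.integer(m[2L])
    to <- if (nzchar(m[3L])) as.integer(m[3L]) else from
    list(chain = chain, from = from, to = to)
  })
  structure(list(items = items, text = text), class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat("<selection_spec> ", x$text, "\n", sep = "")
  invisible(x)
}

.selection_matches <- function(sel, chain, res_seq) {
  if (is.null(sel$items)) {
    return(rep(TRUE, length(chain)))
  }
  hit <- rep(FALSE, length(chain))
  for (it in sel$items) {
    ok <- rep(TRUE, length(chain))
    if (!is.na(it$chain)) ok <- ok & chain == it$chain
    if (!is.na(it$from)) ok <- ok & res_seq >= it$from & res_seq <= it$to
    hit <- hit | ok
  }
  hit
}

#' Build the reference frame for superimposition
#'
#' Extracts the selected CA residues of the reference structure, in file
#' order, and centers their coordinates on the selection centroid. The
#' residue keys of the frame define the column layout of every coordinate
#' batch: models are matched to these slots by (chain, residue number,
#' insertion code) equality, which assumes equivalent residues are numbered
#' identically across models.
#'
#' @param ref A `pdb_structure`, the reference model.
#' @param selection A `selection_spec` (see [parse_selection()]), a
#'   selection string, or `NULL` for all residues.
#' @return An object of class `reference_frame`: list with `residue_keys`
#'   (character vector, length L), `ref_coords` (L x 3 matrix, centered),
#'   `ref_centroid` (length-3 vector), `selection`.
#' @export
build_reference_frame <- function(ref, selection = NULL) {
  stopifnot(inherits(ref, "pdb_structure"))
  if (!inherits(selection, "selection_spec")) {
    selection <- parse_selection(selection)
  }
  idx <- ref$ca_index
  if (length(idx) == 0L) stop("reference has no CA atoms", call. = FALSE)
  at <- ref$atoms[idx, ]
  keep <- .selection_matches(selection, at$chain, at$res_seq)
  if (!any(keep)) {
    stop("selection '", selection$text,
         "' matches no residues in the reference", call. = FALSE)
  }
  if (sum(keep) < 3L) {
    stop("selection too small: ", sum(keep),
         " residues selected, need at least 3", call. = FALSE)
  }
  coords <- as.matrix(at[keep, c("x", "y", "z")])
  dimnames(coords) <- NULL
  centroid <- colMeans(coords)
  structure(
    list(residue_keys = names(idx)[keep],
         ref_coords = sweep(coords, 2L, centroid),
         ref_centroid = centroid,
         selection = selection),
    class = "reference_frame"
  )
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame> ", length(x$residue_keys),
      " residues, selection: ", x$selection$text, "\n", sep = "")
  invisible(x)
}

#' Load CA coordinates of a set of models against a reference frame
#'
#' Parses each file, looks up the frame's residue keys in its CA index and
#' fills an `N x L x 3` coordinate array plus an `N x L` binary mask.
#' Residues missing from a model (deletions relative to the reference) get
#' mask 0 and a zero coordinate row; residues present in the model but not
#' in the frame (insertions) are ignored. Files that fail to parse, or that
#' match fewer than 3 frame residues, are skipped with a warning and listed
#' in `failures` — one bad file never aborts a large run.
#'
#' @param paths Character vector of PDB file paths.
#' @param frame A `reference_frame`.
#' @return An object of class `coord_batch`: list with `coords`
#'   (N x L x 3), `mask` (N x L), `names` (source paths), `failures`
#'   (named character vector of error messages for skipped paths).
#'   `NULL` when every path failed and `paths` was non-empty is an error.
#' @export
load_coords <- function(paths, frame) {
  stopifnot(inherits(frame, "reference_frame"))
  L <- length(frame$residue_keys)
  n <- length(paths)
  coords <- array(0, dim = c(n, L, 3L))
  mask <- matrix(0, n, L)
  ok <- logical(n)
  fail_msgs <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(parse_pdb(paths[i]), error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", paths[i], ": ", conditionMessage(res),
              call. = FALSE)
      fail_msgs[paths[i]] <- conditionMessage(res)
      next
    }
    hit <- match(frame$residue_keys, names(res$ca_index))
    found <- which(!is.na(hit))
    if (length(found) < 3L) {
      msg <- paste0("only ", length(found),
                    " residues match the reference selection (need 3)")
      warning("skipping ", paths[i], ": ", msg, call. = FALSE)
      fail_msgs[paths[i]] <- msg
      next
    }
    rows <- res$ca_index[hit[found]]
    coords[i, found, ] <- as.matrix(res$atoms[rows, c("x", "y", "z")])
    mask[i, found] <- 1
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no input structure could be loaded", call. = FALSE)
  structure(
    list(coords = coords[ok, , , drop = FALSE],
         mask = mask[ok, , drop = FALSE],
         names = paths[ok],
         failures = fail_msgs),
    class = "coord_batch"
  )
}

#' Stream coordinate batches
#'
#' Returns an iterator over [load_coords()] chunks so that memory use is
#' bounded by `batch_size`, not by the total number of models. Calling the
#' returned function yields the next `coord_batch`, or `NULL` when the
#' input is exhausted. Input order is preserved across batches.
#'
#' @param paths Character vector of PDB file paths.
#' @param frame A `reference_frame`.
#' @param batch_size Maximum structures per batch (default 50000).
#' @return A function with no arguments; each call returns a `coord_batch`
#'   or `NULL`. The iterator has attribute `"n_batches"`.
#' @export
load_batch <- function(paths, frame, batch_size = 50000L) {
  stopifnot(batch_size >= 1L)
  pos <- 0L
  n <- length(paths)
  it <- function() {
    if (pos >= n) return(NULL)
    take <- seq.int(pos + 1L, min(pos + batch_size, n))
    pos <<- pos + length(take)
    load_coords(paths[take], frame)
  }
  attr(it, "n_batches") <- as.integer(ceiling(n / batch_size))
  it
}

#' Apply a rigid transform and write a superimposed PDB file
#'
#' Every atom coordinate (ATOM and HETATM alike) is mapped to
#' `R(q) (p - model_centroid) + ref_centroid` and re-printed into the fixed
#' PDB coordinate columns (`%8.3f`). All other columns are copied verbatim
#' from the input, so the output differs from the source only in columns
#' 31-54 of atom records.
#'
#' @param struct A `pdb_structure`.
#' @param transform A `rigid_transform` (see [rigid_transform()]); its
#'   quaternion must have unit norm within 1e-6.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_transformed <- function(struct, transform, out_path) {
  stopifnot(inherits(struct, "pdb_structure"),
            inherits(transform, "rigid_transform"))
  q <- transform$quaternion
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6) {
    stop("transform quaternion is not unit norm", call. = FALSE)
  }
  R <- quat_rotation_matrix(q)
  p <- as.matrix(struct$atoms[, c("x", "y", "z")])
  p <- sweep(p, 2L, transform$model_centroid)
  p <- p %*% t(R)
  p <- sweep(p, 2L, transform$ref_centroid, FUN = "+")

  lines <- struct$lines
  al <- lines[struct$atom_lines]
  tail_part <- ifelse(nchar(al) > 54L, substr(al, 55L, nchar(al)), "")
  lines[struct$atom_lines] <- paste0(
    substr(al, 1L, 30L),
    sprintf("%8.3f%8.3f%8.3f", p[, 1L], p[, 2L], p[, 3L]),
    tail_part
  )
  con <- tryCatch(file(out_path, "w"),
                  error = function(e) stop("cannot write ", out_path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out_path)
}

## Format an atom table into fixed-column PDB records (used by the
## synthetic-fixture generator; parse_pdb keeps original lines instead).
.format_pdb_lines <- function(atoms) {
  name4 <- ifelse(nchar(atoms$atom_name) < 4L,
                  sprintf(" %-3s", atoms$atom_name),
                  atoms$atom_name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, atoms$serial, name4, atoms$alt_loc, atoms$res_name,
          atoms$chain, atoms$res_seq, atoms$i_code,
          atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
          substr(atoms$atom_name, 1L, 1L))
}

## Build a pdb_structure in memory from an atom table.
.structure_from_atoms <- function(atoms, path = "<synthetic>") {
  lines <- c(.format_pdb_lines(atoms), "END")
  structure(
    list(path = path, lines = lines,
         atom_lines = seq_len(nrow(atoms)),
         atoms = atoms, ca_index = .build_ca_index(atoms)),
    class = "pdb_structure"
  )
}

#' Write a structure record to a PDB file
#'
#' @param struct A `pdb_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "pdb_structure"))
  writeLines(struct$lines, path)
  invisible(path)
}
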