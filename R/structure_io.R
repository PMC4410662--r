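# PDB (ATOM/HETATM/ANISOU), multi-frame XYZ and plain-text matrix I/O.
# Fixed columns follow wwPDB format v3.3; coordinates are orthogonal Angstrom
# and no symmetry expansion is attempted.

.pdb_substr <- function(lines, first, last) {
  out <- substr(lines, first, last)
  trimws(out)
}

.pdb_num <- function(field, lineno, what, default = NA_real_) {
  out <- rep(default, length(field))
  has <- nzchar(field)
  val <- suppressWarnings(as.numeric(field[has]))
  bad <- is.na(val)
  if (any(bad)) {
    abort_parse(sprintf("malformed %s field on line %d: '%s'",
                        what, lineno[has][bad][1], field[has][bad][1]))
  }
  out[has] <- val
  out
}

# Old PDB dialect writes primed atoms with '*' (C4* for C4').
.normalize_atom_name <- function(name) gsub("\\*", "'", name)

.is_hydrogen <- function(element, name) {
  el <- toupper(element)
  known <- el %in% c("H", "D")
  # fall back on the atom name when the element column is blank:
  # first alphabetic character H/D (PDB names like "1HB", "HG1")
  core <- toupper(gsub("^[0-9]*", "", name))
  guess <- !nzchar(el) & substr(core, 1, 1) %in% c("H", "D")
  known | guess
}

#' Parse a PDB file into a structure object
#'
#' Reads `ATOM`, `HETATM` and `ANISOU` records from a PDB file (or a
#' character vector of lines).  Only the first model of a multi-model file is
#' retained.  For alternate locations the highest-occupancy conformer is
#' kept (ties broken by file order).  `ANISOU` tensors are attached to their
#' atom as symmetric 3x3 matrices in Angstrom^2 (stored integers times
#' 1e-4).  Hydrogens are retained here; they are dropped at node selection.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param source_label label recorded on the returned object (defaults to
#'   the file name).
#' @return An object of class `anm_structure`: a list with `atoms` (a
#'   data.frame with one row per atom), `adp` (a list of 3x3 tensors or
#'   `NULL` per atom), `model_id` and `source_label`.
#' @examples
#' pdb <- make_ca_chain(5, seed = 1)
#' s <- parse_pdb(pdb)
#' nrow(s$atoms)
#' @export
parse_pdb <- function(input, source_label = NULL) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    if (is.null(source_label)) source_label <- basename(input)
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(source_label)) source_label <- "<text>"
  }
  lineno <- seq_along(lines)
  rec <- substr(lines, 1, 6)

  # first model only
  model_id <- 1L
  model_at <- which(trimws(rec) == "MODEL")
  if (length(model_at) > 1) {
    endm <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endm)) endm[1] else model_at[2]
    keep <- lineno < stop_at | lineno >= length(lines) + 1
    mid <- suppressWarnings(as.integer(trimws(substr(lines[model_at[1]], 7, 80))))
    if (!is.na(mid)) model_id <- mid
    anm_notify("multi-model file: keeping first model only")
    lines <- lines[keep]
    lineno <- lineno[keep]
    rec <- rec[keep]
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_aniso <- rec == "ANISOU"
  if (!any(is_atom)) abort_parse("empty structure: no ATOM/HETATM record found")

  al <- lines[is_atom]
  an <- lineno[is_atom]
  atoms <- data.frame(
    serial    = as.integer(.pdb_num(.pdb_substr(al, 7, 11), an, "serial")),
    name      = .normalize_atom_name(.pdb_substr(al, 13, 16)),
    alt_loc   = .pdb_substr(al, 17, 17),
    res_name  = .pdb_substr(al, 18, 20),
    chain_id  = .pdb_substr(al, 22, 22),
    res_no    = as.integer(.pdb_num(.pdb_substr(al, 23, 26), an, "residue number")),
    i_code    = .pdb_substr(al, 27, 27),
    x         = .pdb_num(.pdb_substr(al, 31, 38), an, "x coordinate"),
    y         = .pdb_num(.pdb_substr(al, 39, 46), an, "y coordinate"),
    z         = .pdb_num(.pdb_substr(al, 47, 54), an, "z coordinate"),
    occupancy = .pdb_num(.pdb_substr(al, 55, 60), an, "occupancy", default = 1),
    b_factor  = .pdb_num(.pdb_substr(al, 61, 66), an, "B-factor", default = 0),
    element   = .pdb_substr(al, 77, 78),
    record    = ifelse(substr(al, 1, 4) == "ATOM", "ATOM", "HETATM"),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort_parse("non-finite coordinate in ATOM/HETATM record")
  }

  # altloc policy: keep the highest-occupancy conformer, ties -> first in file
  key <- paste(atoms$chain_id, atoms$res_no, atoms$i_code, atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  keep_idx <- sort(ord[!duplicated(key[ord])])
  dropped <- nrow(atoms) - length(keep_idx)
  if (dropped > 0) anm_notify(dropped, " alternate-location conformer(s) dropped")
  atoms <- atoms[keep_idx, , drop = FALSE]
  rownames(atoms) <- NULL

  adp <- vector("list", nrow(atoms))
  if (any(is_aniso)) {
    ul <- lines[is_aniso]
    un <- lineno[is_aniso]
    ukey <- paste(.pdb_substr(ul, 22, 22), as.integer(.pdb_num(.pdb_substr(ul, 23, 26), un, "residue number")),
                  .pdb_substr(ul, 27, 27), .normalize_atom_name(.pdb_substr(ul, 13, 16)),
                  .pdb_substr(ul, 17, 17), sep = "|")
    akey <- paste(atoms$chain_id, atoms$res_no, atoms$i_code, atoms$name,
                  atoms$alt_loc, sep = "|")
    starts <- c(29, 36, 43, 50, 57, 64)
    for (i in seq_along(ul)) {
      j <- match(ukey[i], akey)
      if (is.na(j)) next
      u6 <- vapply(starts, function(s) {
        .pdb_num(.pdb_substr(ul[i], s, s + 6), un[i], "ANISOU integer")
      }, numeric(1)) * 1e-4
      adp[[j]] <- matrix(c(u6[1], u6[4], u6[5],
                           u6[4], u6[2], u6[6],
                           u6[5], u6[6], u6[3]), 3, 3)
    }
  }

  structure(
    list(atoms = atoms, adp = adp, model_id = model_id,
         source_label = source_label),
    class = "anm_structure"
  )
}

#' @export
print.anm_structure <- function(x, ...) {
  cat(sprintf("<anm_structure> %s: %d atoms, %d with ADPs, model %d\n",
              x$source_label, nrow(x$atoms),
              sum(!vapply(x$adp, is.null, logical(1))), x$model_id))
  invisible(x)
}

.fmt_atom_line <- function(record, serial, name, alt, resn, chain, resno,
                           icode, x, y, z, occ, b, element) {
  # atom names of <4 chars start in column 14 by convention
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, alt, resn, chain, resno %% 10000L,
          icode, x, y, z, occ, b, element)
}

.fmt_anisou_line <- function(serial, name, alt, resn, chain, resno, icode,
                             u_int, element) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ANISOU%5d %4s%1s%-3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
          serial %% 100000L, nm, alt, resn, chain, resno %% 10000L, icode,
          u_int[1], u_int[2], u_int[3], u_int[4], u_int[5], u_int[6], element)
}

#' Write a structure back to PDB text
#'
#' Serializes the retained fields (identity, coordinates, occupancy,
#' B-factor, element and any attached ADP tensors) as fixed-column PDB
#' records.
#'
#' @param s an `anm_structure`.
#' @param file optional path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `file` is `NULL`) a character vector
#'   of PDB lines.
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "anm_structure"))
  a <- s$atoms
  out <- character(0)
  for (i in seq_len(nrow(a))) {
    out <- c(out, .fmt_atom_line(a$record[i], a$serial[i], a$name[i],
                                 a$alt_loc[i], a$res_name[i], a$chain_id[i],
                                 a$res_no[i], a$i_code[i], a$x[i], a$y[i],
                                 a$z[i], a$occupancy[i], a$b_factor[i],
                                 a$element[i]))
    U <- s$adp[[i]]
    if (!is.null(U)) {
      u_int <- as.integer(round(c(U[1, 1], U[2, 2], U[3, 3],
                                  U[1, 2], U[1, 3], U[2, 3]) * 1e4))
      out <- c(out, .fmt_anisou_line(a$serial[i], a$name[i], a$alt_loc[i],
                                     a$res_name[i], a$chain_id[i], a$res_no[i],
                                     a$i_code[i], u_int, a$element[i]))
    }
  }
  out <- c(out, "END")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Write network nodes with ADP tensors as a PDB with ANISOU records
#'
#' Emits one `ATOM`/`HETATM` record per node (identity fields carried over
#' from the source atom) followed by an `ANISOU` record.  The B-factor
#' column holds the isotropic equivalent `(8*pi^2/3) * trace(U) * scale` and
#' the ANISOU integers are `round(U_ij * scale * 1e4)`.  Because model
#' fluctuations are in arbitrary units, `scale` maps them onto a
#' crystallographic scale (e.g. the fit from [fit_experimental_b()]).
#'
#' @param nodes an `anm_nodes` set.
#' @param adps an `anm_adps` set (or list of 3x3 tensors), one per node.
#' @param scale positive multiplier applied to the tensors before writing.
#' @param file optional output path.
#' @return Character vector of PDB lines (invisibly when `file` given).
#' @export
write_pdb_with_anisou <- function(nodes, adps, scale = 1, file = NULL) {
  stopifnot(inherits(nodes, "anm_nodes"))
  U <- if (inherits(adps, "anm_adps")) adps$tensors else adps
  if (length(U) != nrow(nodes$nodes)) {
    abort_dimension(sprintf("ADP count (%d) does not match node count (%d)",
                            length(U), nrow(nodes$nodes)))
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort_argument("scale must be a positive number")
  }
  nd <- nodes$nodes
  out <- character(0)
  for (i in seq_len(nrow(nd))) {
    Ui <- U[[i]] * scale
    b <- (8 * pi^2 / 3) * sum(diag(Ui))
    record <- if (nd$class[i] == "LIG") "HETATM" else "ATOM"
    out <- c(out, .fmt_atom_line(record, i, nd$name[i], "", nd$res_name[i],
                                 nd$chain_id[i], nd$res_no[i], nd$i_code[i],
                                 nd$x[i], nd$y[i], nd$z[i], 1, b,
                                 nd$element[i]))
    u_int <- as.integer(round(c(Ui[1, 1], Ui[2, 2], Ui[3, 3],
                                Ui[1, 2], Ui[1, 3], Ui[2, 3]) * 1e4))
    out <- c(out, .fmt_anisou_line(i, nd$name[i], "", nd$res_name[i],
                                   nd$chain_id[i], nd$res_no[i], nd$i_code[i],
                                   u_int, nd$element[i]))
  }
  out <- c(out, "END")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Construct a mode-animation trajectory object
#'
#' @param labels per-node character labels (element symbols).
#' @param frames list of N x 3 coordinate matrices, one per frame.
#' @param comments optional per-frame comment strings.
#' @return An `anm_trajectory`.
#' @export
trajectory <- function(labels, frames, comments = NULL) {
  if (!is.list(frames) || length(frames) < 1 || length(labels) < 1) {
    abort_argument("empty trajectory")
  }
  n <- length(labels)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3,
               logical(1))
  if (!all(ok)) abort_dimension("every frame must be an N x 3 matrix matching labels")
  if (is.null(comments)) {
    comments <- sprintf("frame %d", seq_along(frames) - 1L)
  }
  structure(list(labels = labels, frames = frames, comments = comments),
            class = "anm_trajectory")
}

#' Write a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks: atom count, comment line, then `label x y z` with
#' three decimals, one block per frame in order.
#'
#' @param traj an `anm_trajectory`.
#' @param file optional output path.
#' @return Character vector of lines (invisibly when `file` given).
#' @export
write_xyz_trajectory <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "anm_trajectory"))
  if (length(traj$frames) == 0) abort_argument("empty trajectory")
  n <- length(traj$labels)
  blocks <- lapply(seq_along(traj$frames), function(f) {
    xyz <- traj$frames[[f]]
    c(as.character(n), traj$comments[[f]],
      sprintf("%-3s %12.5f %12.5f %12.5f", traj$labels,
              xyz[, 1], xyz[, 2], xyz[, 3]))
  })
  out <- unlist(blocks, use.names = FALSE)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Read a multi-frame XYZ trajectory
#'
#' Counterpart of [write_xyz_trajectory()]; accepts any conforming XYZ text.
#'
#' @param input path or character vector of lines.
#' @return An `anm_trajectory`.
#' @export
read_xyz_trajectory <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  frames <- list(); comments <- character(0); labels <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort_parse(sprintf("expected atom count on line %d", i))
    if (i + 1 + n > length(lines)) abort_parse("truncated XYZ block")
    comments <- c(comments, lines[i + 1])
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    lab <- vapply(toks, `[`, character(1), 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) abort_parse("non-numeric coordinate in XYZ block")
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) abort_parse("no XYZ frames found")
  trajectory(labels, frames, comments)
}

#' Write a numeric matrix with a "# rows cols" header
#'
#' @param m numeric matrix.
#' @param file optional output path.
#' @param fmt `sprintf` format for entries.
#' @return Character vector of lines (invisibly when `file` given).
#' @export
write_matrix <- function(m, file = NULL, fmt = "%.6e") {
  stopifnot(is.matrix(m))
  out <- c(sprintf("# %d %d", nrow(m), ncol(m)),
           apply(m, 1, function(r) paste(sprintf(fmt, r), collapse = " ")))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Read a whitespace-delimited numeric matrix
#'
#' Accepts an optional leading `# rows cols` header (checked when present);
#' other `#` lines are comments.
#'
#' @param input path or character vector of lines.
#' @return Numeric matrix.
#' @export
read_matrix <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  dims <- NULL
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr)) {
    tk <- strsplit(trimws(sub("^#", "", hdr[1])), "[[:space:]]+")[[1]]
    if (length(tk) == 2 && !anyNA(suppressWarnings(as.integer(tk)))) {
      dims <- as.integer(tk)
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) abort_parse("no numeric rows in matrix input")
  rows <- lapply(strsplit(trimws(body), "[[:space:]]+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v)) abort_parse(sprintf("non-numeric matrix entry: '%s'",
                                      tk[which(is.na(v))[1]]))
    v
  })
  nc <- unique(lengths(rows))
  if (length(nc) != 1) abort_parse("ragged matrix rows")
  m <- do.call(rbind, rows)
  if (!is.null(dims) && any(dim(m) != dims)) {
    abort_parse(sprintf("matrix header says %dx%d but body is %dx%d",
                        dims[1], dims[2], nrow(m), ncol(m)))
  }
  m
}
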