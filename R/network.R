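# Structure -> nodes -> contacts -> Hessian.
#
# The spring network places nodes at selected atoms and joins every pair
# (i, j) with Euclidean separation d0 <= t_i + t_j by an identical harmonic
# spring.  With a uniform half-range t = r_c / 2 this reduces to the
# classical single-cutoff anisotropic network model with cutoff r_c.

.AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
.NUCLEOTIDES <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")

#' Define a node-selection and interaction-range scheme
#'
#' The scheme controls which atoms become network nodes and which half-range
#' `t` each node type carries.  Defaults follow the standard reduction: one
#' C-alpha node per amino-acid residue, three nodes per nucleotide (P, C4',
#' C2), one node per ligand heavy atom, waters excluded, and a uniform
#' cutoff `r_c = 15` Angstrom (so every `t_i = r_c / 2 = 7.5`).
#'
#' Entries of `range_table` are looked up first by full type key
#' (`"class:name"` with class `PRO`, `NUC` or `LIG`, e.g. `"NUC:P"`), then
#' by bare atom name (e.g. `"CA"`), before falling back to `r_c / 2`.
#'
#' @param protein_atoms atom names that become nodes in amino-acid residues.
#' @param nucleotide_atoms atom names that become nodes in nucleotides.
#' @param include_ligands map non-water HETATM heavy atoms to nodes?
#' @param ligand_exclude_residues residue names never turned into ligand
#'   nodes (solvent by default).
#' @param range_table named numeric vector of half-ranges `t` in Angstrom.
#' @param cutoff default cutoff `r_c` in Angstrom; the fallback half-range
#'   is `cutoff / 2`.
#' @return An object of class `anm_scheme`.
#' @examples
#' node_scheme()                        # defaults
#' node_scheme(range_table = c("NUC:P" = 9), cutoff = 15)
#' @export
node_scheme <- function(protein_atoms = "CA",
                        nucleotide_atoms = c("P", "C4'", "C2"),
                        include_ligands = TRUE,
                        ligand_exclude_residues = c("HOH", "WAT", "DOD"),
                        range_table = numeric(0),
                        cutoff = 15) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort_config("cutoff r_c must be a positive number")
  }
  range_table <- unlist(range_table)
  if (length(range_table)) {
    if (is.null(names(range_table)) || any(!nzchar(names(range_table)))) {
      abort_config("range_table entries must be named by type key")
    }
    if (any(!is.finite(range_table) | range_table <= 0)) {
      abort_config("all interaction ranges t must be positive and finite")
    }
  }
  structure(
    list(protein_atoms = toupper(protein_atoms),
         nucleotide_atoms = .normalize_atom_name(toupper(nucleotide_atoms)),
         include_ligands = isTRUE(include_ligands),
         ligand_exclude_residues = toupper(ligand_exclude_residues),
         range_table = range_table,
         cutoff = cutoff),
    class = "anm_scheme"
  )
}

#' Read a half-range table from a plain-text config file
#'
#' One `TYPEKEY value` pair per line (value in Angstrom); `#` starts a
#' comment.  Keys may be full type keys (`NUC:P`) or bare atom names (`CA`).
#'
#' @param path file path.
#' @return Named numeric vector suitable for the `range_table` argument of
#'   [node_scheme()].
#' @export
read_range_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(numeric(0))
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 2
  if (any(bad)) abort_config(sprintf("malformed range-table line: '%s'", lines[bad][1]))
  vals <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 2)))
  if (anyNA(vals)) abort_config("non-numeric range value in range table")
  keys <- vapply(toks, `[`, character(1), 1)
  stats::setNames(vals, keys)
}

#' Select network nodes from a structure
#'
#' Applies the scheme to a parsed structure: every amino-acid residue
#' contributes one node per `protein_atoms` name present, every standard
#' nucleotide (A, C, G, U, T, DA, DC, DG, DT, DU) one node per
#' `nucleotide_atoms` name present (5'-terminal nucleotides lacking P simply
#' contribute fewer nodes, with a notice), and — when ligands are included —
#' every non-hydrogen HETATM whose residue is neither a standard polymer
#' residue nor in the exclusion set becomes a node.  Node order follows
#' file order; hydrogens never become nodes.
#'
#' @param s an `anm_structure`.
#' @param scheme an `anm_scheme` (defaults to [node_scheme()]).
#' @return An `anm_nodes` object: a list with `nodes` (data.frame of
#'   positions, identities, type keys, experimental B) and `N`.
#' @export
select_nodes <- function(s, scheme = node_scheme()) {
  stopifnot(inherits(s, "anm_structure"), inherits(scheme, "anm_scheme"))
  a <- s$atoms
  if (!nrow(a)) abort_degenerate("degenerate network: structure has no atoms")
  name_up <- toupper(a$name)
  res_up <- toupper(a$res_name)
  hyd <- .is_hydrogen(a$element, a$name)

  is_pro <- res_up %in% .AMINO_ACIDS & name_up %in% scheme$protein_atoms & !hyd
  is_nuc <- res_up %in% .NUCLEOTIDES & name_up %in% scheme$nucleotide_atoms & !hyd
  is_lig <- scheme$include_ligands &
    a$record == "HETATM" &
    !(res_up %in% c(.AMINO_ACIDS, .NUCLEOTIDES)) &
    !(res_up %in% scheme$ligand_exclude_residues) &
    !hyd

  class <- rep(NA_character_, nrow(a))
  class[is_pro] <- "PRO"
  class[is_nuc] <- "NUC"
  class[is_lig & is.na(class)] <- "LIG"
  sel <- which(!is.na(class))

  # notice for nucleotides missing scheme atoms (e.g. 5'-terminal P)
  nuc_res <- unique(paste(a$chain_id, a$res_no, a$i_code)[res_up %in% .NUCLEOTIDES])
  if (length(nuc_res)) {
    rkey <- paste(a$chain_id, a$res_no, a$i_code)
    n_missing <- sum(vapply(nuc_res, function(k) {
      present <- name_up[rkey == k & !hyd]
      sum(!(scheme$nucleotide_atoms %in% present))
    }, numeric(1)) > 0)
    if (n_missing > 0) {
      anm_notify(n_missing, " nucleotide(s) lack some scheme atoms; ",
                 "they contribute fewer nodes")
    }
  }

  if (length(sel) < 2) {
    abort_degenerate(sprintf(
      "degenerate network: only %d node(s) selected (need >= 2)", length(sel)))
  }

  nodes <- data.frame(
    index = seq_along(sel) - 1L,
    serial = a$serial[sel],
    name = a$name[sel],
    res_name = a$res_name[sel],
    chain_id = a$chain_id[sel],
    res_no = a$res_no[sel],
    i_code = a$i_code[sel],
    element = ifelse(nzchar(a$element[sel]), a$element[sel],
                     substr(toupper(gsub("^[0-9]*", "", a$name[sel])), 1, 1)),
    class = class[sel],
    type_key = paste0(class[sel], ":", name_up[sel]),
    x = a$x[sel], y = a$y[sel], z = a$z[sel],
    t = NA_real_,
    b_exp = a$b_factor[sel],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, N = nrow(nodes), scheme = scheme),
            class = "anm_nodes")
}

#' @export
print.anm_nodes <- function(x, ...) {
  tab <- table(x$nodes$class)
  cat(sprintf("<anm_nodes> N = %d (%s)\n", x$N,
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Assign per-type interaction ranges to nodes
#'
#' Each node's half-range `t` is taken from the scheme's `range_table` by
#' full type key (`"NUC:P"`), else by bare atom name (`"CA"`), else the
#' uniform fallback `cutoff / 2`.
#'
#' @param nodes an `anm_nodes` object.
#' @param scheme scheme providing the table and cutoff; defaults to the
#'   scheme the nodes were selected with.
#' @return The node set with `t` filled in, order preserved.
#' @export
assign_ranges <- function(nodes, scheme = nodes$scheme) {
  stopifnot(inherits(nodes, "anm_nodes"), inherits(scheme, "anm_scheme"))
  if (!nrow(nodes$nodes)) abort_degenerate("empty node set")
  tab <- scheme$range_table
  nd <- nodes$nodes
  t_full <- unname(tab[nd$type_key])
  t_name <- unname(tab[toupper(nd$name)])
  t <- ifelse(!is.na(t_full), t_full,
              ifelse(!is.na(t_name), t_name, scheme$cutoff / 2))
  if (any(!is.finite(t) | t <= 0)) abort_config("non-positive interaction range")
  nodes$nodes$t <- t
  nodes$scheme <- scheme
  nodes
}

#' Enumerate spring contacts under the pairwise cutoff t_i + t_j
#'
#' Exact all-pairs enumeration: pair (i, j), i < j, is a contact iff its
#' equilibrium separation `d0` satisfies `d0 <= t_i + t_j` (inclusive).
#' Every contact carries the uniform spring constant `gamma`.
#'
#' @param nodes an `anm_nodes` with ranges assigned (see [assign_ranges()]).
#' @param gamma spring constant (arbitrary units; uniform).
#' @return An `anm_contacts` object with integer vectors `i`, `j` (1-based),
#'   distances `d0` and spring constants `gamma`.
#' @export
build_contacts <- function(nodes, gamma = 1) {
  stopifnot(inherits(nodes, "anm_nodes"))
  nd <- nodes$nodes
  if (anyNA(nd$t)) abort_argument("nodes carry no interaction ranges; call assign_ranges() first")
  if (!is.numeric(gamma) || gamma <= 0) abort_argument("gamma must be positive")
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  n <- nrow(xyz)
  pair_idx <- which(upper.tri(dm), arr.ind = TRUE)
  d0 <- dm[pair_idx]
  coincident <- which(d0 < 1e-6)
  if (length(coincident)) {
    k <- coincident[1]
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    abort_argument(sprintf(
      "nodes at identical coordinates: %s %s %d %s and %s %s %d %s",
      nd$chain_id[i], nd$res_name[i], nd$res_no[i], nd$name[i],
      nd$chain_id[j], nd$res_name[j], nd$res_no[j], nd$name[j]))
  }
  cut <- nd$t[pair_idx[, 1]] + nd$t[pair_idx[, 2]]
  keep <- d0 <= cut
  structure(
    list(i = unname(pair_idx[keep, 1]), j = unname(pair_idx[keep, 2]),
         d0 = unname(d0[keep]),
         gamma = rep(gamma, sum(keep)),
         n_nodes = n),
    class = "anm_contacts"
  )
}

#' @export
print.anm_contacts <- function(x, ...) {
  cat(sprintf("<anm_contacts> %d contacts over %d nodes\n",
              length(x$i), x$n_nodes))
  invisible(x)
}

#' Assemble the 3N x 3N network Hessian
#'
#' For each contact (i, j) the off-diagonal 3x3 super-element is
#' `H[i,j] = -(gamma / d0^2) * (r_ij %o% r_ij)` with
#' `r_ij = R_j - R_i`, symmetrized, and each diagonal super-element is minus
#' the sum of its off-diagonal row.  This is the second-derivative matrix of
#' the harmonic network energy `E = sum gamma/2 (|R_i - R_j| - d0)^2` at the
#' equilibrium structure: symmetric, positive semi-definite, with zero 3x3
#' super-row sums (translation invariance).
#'
#' @param nodes an `anm_nodes` with ranges assigned.
#' @param contacts an `anm_contacts` from [build_contacts()].
#' @return An `anm_hessian`: sparse symmetric `Matrix` `H` plus node count.
#' @export
build_hessian <- function(nodes, contacts = build_contacts(nodes)) {
  stopifnot(inherits(nodes, "anm_nodes"), inherits(contacts, "anm_contacts"))
  n <- nodes$N
  if (contacts$n_nodes != n) abort_dimension("contacts were built for a different node set")
  if (length(contacts$i) == 0) abort_disconnected("fully disconnected network: no contacts")
  xyz <- as.matrix(nodes$nodes[, c("x", "y", "z")])
  m <- length(contacts$i)
  # triplets: each contact contributes a 3x3 block at (i,j), (j,i), (i,i), (j,j)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rows <- matrix(0L, 3, 3); cols <- matrix(0L, 3, 3)
  for (a in 1:3) for (b in 1:3) { rows[a, b] <- a; cols[a, b] <- b }
  blk_i <- (contacts$i - 1L) * 3L
  blk_j <- (contacts$j - 1L) * 3L
  r <- xyz[contacts$j, , drop = FALSE] - xyz[contacts$i, , drop = FALSE]
  w <- contacts$gamma / contacts$d0^2
  # 9 entries per block; vectorized over contacts
  for (a in 1:3) for (b in 1:3) {
    v <- -w * r[, a] * r[, b]
    ii <- c(ii, blk_i + a, blk_j + a, blk_i + a, blk_j + a)
    jj <- c(jj, blk_j + b, blk_i + b, blk_i + b, blk_j + b)
    vv <- c(vv, v, v, -v, -v)
  }
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(3 * n, 3 * n))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  structure(list(H = H, N = n), class = "anm_hessian")
}

#' @export
print.anm_hessian <- function(x, ...) {
  cat(sprintf("<anm_hessian> %d x %d (N = %d nodes), %d nonzeros\n",
              3 * x$N, 3 * x$N, x$N, Matrix::nnzero(x$H)))
  invisible(x)
}
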