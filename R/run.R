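# One-shot end-to-end run mirroring the server workflow:
# structure in -> modes, profiles, maps, ADP-PDB and animations out.

#' Run the full network-model pipeline on a structure
#'
#' Parses the input PDB, builds the node network under the given scheme,
#' computes (or imports) modes, derives all observables and writes a
#' deterministic output bundle: `manifest.txt` (resolved configuration plus
#' node/contact/zero-mode counts), `eigenvalues.tsv`, `modes.txt`,
#' `msf_bfactor.tsv`, `correlation.txt`, `distfluct.txt`, `anisou.pdb` and
#' one `mode_<k>.xyz` per animated mode.  Matrices use `%.6e`, profile TSVs
#' `%.4f`, so identical input + configuration reproduce the bundle
#' byte-for-byte.
#'
#' @param input path to a PDB file (or PDB text lines).
#' @param out_dir output directory (created if missing).
#' @param cutoff default cutoff r_c, Angstrom.
#' @param ranges half-range table: named numeric vector or path to a
#'   range-table file (see [read_range_table()]).
#' @param protein_atoms,nucleotide_atoms node atom names per residue class.
#' @param include_ligands,exclude_residues ligand policy.
#' @param n_modes nonzero modes to compute.
#' @param solver `"auto"`, `"dense"` or `"subset"`.
#' @param animate integer mode indices to export as XYZ animations.
#' @param amplitude,frames animation peak displacement (Angstrom) and frame
#'   count per period.
#' @param import_modes optional path to an external mode matrix; replaces
#'   the computed modes for the observable outputs.
#' @param adp_scale scale applied when writing ANISOU tensors.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the intermediate objects (`structure`,
#'   `nodes`, `contacts`, `hessian`, `modes`, `profile`, ...) and `files`.
#' @examples
#' out <- run_anm(make_ca_chain(12, seed = 3), out_dir = tempfile(),
#'                n_modes = 5)
#' out$modes$eigenvalues
#' @export
run_anm <- function(input, out_dir,
                    cutoff = 15, ranges = NULL,
                    protein_atoms = "CA",
                    nucleotide_atoms = c("P", "C4'", "C2"),
                    include_ligands = TRUE,
                    exclude_residues = c("HOH", "WAT", "DOD"),
                    n_modes = 20, solver = "auto",
                    animate = integer(0), amplitude = 2.0, frames = 20,
                    import_modes = NULL, adp_scale = 1, seed = 0) {
  if (is.character(ranges) && length(ranges) == 1 && file.exists(ranges)) {
    range_table <- read_range_table(ranges)
    ranges_label <- ranges
  } else if (is.numeric(ranges)) {
    range_table <- ranges
    ranges_label <- paste(names(ranges), ranges, sep = "=", collapse = ",")
  } else {
    range_table <- numeric(0)
    ranges_label <- "<none>"
  }
  scheme <- node_scheme(protein_atoms = protein_atoms,
                        nucleotide_atoms = nucleotide_atoms,
                        include_ligands = include_ligands,
                        ligand_exclude_residues = exclude_residues,
                        range_table = range_table,
                        cutoff = cutoff)

  s <- parse_pdb(input)
  nodes <- assign_ranges(select_nodes(s, scheme))
  contacts <- build_contacts(nodes)
  h <- build_hessian(nodes, contacts)
  modes <- compute_modes(h, n_modes = n_modes, solver = solver)
  if (!is.null(import_modes)) {
    modes_used <- import_external_modes(import_modes, nodes)
  } else {
    modes_used <- modes
  }

  profile <- square_fluctuations(modes_used)
  bfit <- tryCatch(fit_experimental_b(profile, nodes$nodes$b_exp),
                   anm_error = function(e) list(scale = NA_real_, r = NA_real_))
  adps <- adp_tensors(modes_used)
  cmap <- cross_correlation_map(modes_used)
  dmap <- distance_fluctuation_map(modes_used)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)
  files <- character(0)

  manifest <- c(
    sprintf("input: %s", s$source_label),
    sprintf("cutoff: %.4f", cutoff),
    sprintf("ranges: %s", ranges_label),
    sprintf("protein_atoms: %s", paste(scheme$protein_atoms, collapse = ",")),
    sprintf("nucleotide_atoms: %s", paste(scheme$nucleotide_atoms, collapse = ",")),
    sprintf("include_ligands: %s", scheme$include_ligands),
    sprintf("exclude_residues: %s", paste(scheme$ligand_exclude_residues, collapse = ",")),
    sprintf("n_modes: %d", n_modes),
    sprintf("solver: %s", solver),
    sprintf("animate: %s", paste(animate, collapse = ",")),
    sprintf("amplitude: %.4f", amplitude),
    sprintf("frames: %d", frames),
    sprintf("import_modes: %s", if (is.null(import_modes)) "<none>" else "<provided>"),
    sprintf("adp_scale: %.4f", adp_scale),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("n_nodes: %d", nodes$N),
    sprintf("n_contacts: %d", length(contacts$i)),
    sprintf("n_zero: %d", modes$n_zero_skipped),
    sprintf("modes_source: %s", modes_used$source),
    sprintf("modes_used: %d", length(modes_used$eigenvalues)),
    sprintf("b_fit_scale: %.6e", bfit$scale),
    sprintf("b_fit_r: %.6f", bfit$r)
  )
  writeLines(manifest, fp("manifest.txt")); files <- c(files, "manifest.txt")

  writeLines(c("mode\teigenvalue",
               sprintf("%d\t%.6e", seq_along(modes$eigenvalues),
                       modes$eigenvalues)),
             fp("eigenvalues.tsv")); files <- c(files, "eigenvalues.tsv")
  write_modes(modes, fp("modes.txt")); files <- c(files, "modes.txt")
  write_fluct_tsv(profile, nodes, fp("msf_bfactor.tsv"))
  files <- c(files, "msf_bfactor.tsv")
  write_matrix(cmap, fp("correlation.txt")); files <- c(files, "correlation.txt")
  write_matrix(dmap, fp("distfluct.txt")); files <- c(files, "distfluct.txt")
  write_pdb_with_anisou(nodes, adps, scale = adp_scale, file = fp("anisou.pdb"))
  files <- c(files, "anisou.pdb")

  for (k in animate) {
    traj <- animate_mode(nodes, modes_used, k, amplitude = amplitude,
                         n_frames = frames)
    nm <- sprintf("mode_%d.xyz", k)
    write_xyz_trajectory(traj, fp(nm)); files <- c(files, nm)
  }

  invisible(list(structure = s, nodes = nodes, contacts = contacts,
                 hessian = h, modes = modes, modes_used = modes_used,
                 profile = profile, b_fit = bfit, adps = adps,
                 correlation = cmap, dist_fluct = dmap,
                 out_dir = out_dir, files = files))
}
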