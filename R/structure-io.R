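#' @importFrom stats rnorm runif sd quantile setNames aggregate
#' @importFrom utils head read.csv write.csv
NULL

.roles_required <- c("MHC", "PEPTIDE", "TCRA", "TCRB")
.roles_all <- c(.roles_required, "OTHER")

#' Construct a chain-role map
#'
#' @param ... Named chain assignments, e.g. `chain_roles(M = "MHC", P =
#'   "PEPTIDE", A = "TCRA", B = "TCRB")`, or a single named character vector.
#'   Roles must cover MHC, PEPTIDE, TCRA and TCRB exactly once; additional
#'   chains may be tagged OTHER (ignored downstream, e.g. beta-2
#'   microglobulin).
#' @return Named character vector mapping chain id to role.
#' @export
chain_roles <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("chain_roles() requires named chain -> role assignments")
  }
  x <- toupper(x)
  bad <- setdiff(unique(x), .roles_all)
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  for (r in .roles_required) {
    n <- sum(x == r)
    if (n != 1L) stop("role ", r, " must map to exactly one chain (got ", n, ")")
  }
  x
}

#' Read chain-role maps from CSV
#'
#' @param path CSV with header `complex_id,chain_id,role`.
#' @return Named list of role maps, one per complex id.
#' @export
read_chain_roles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("complex_id", "chain_id", "role")
  if (!all(need %in% names(df))) {
    stop("roles CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$complex_id), function(d) {
    chain_roles(stats::setNames(d$role, d$chain_id))
  })
  out
}

#' Read affinity annotations from CSV
#'
#' Each row carries at least one of a dissociation constant (`kd_uM`), an
#' IC50 (`ic50_nM`) or an explicit `label`. Missing labels are derived from
#' Kd where available (see [label_from_kd()]).
#'
#' @param path CSV with header `complex_id,kd_uM,ic50_nM,label`.
#' @return data.frame with columns complex_id, kd_uM, ic50_nM, label.
#' @export
read_affinities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"complex_id" %in% names(df)) stop("affinity CSV needs complex_id")
  for (col in c("kd_uM", "ic50_nM")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df$label[df$label %in% c("", "NA")] <- NA_character_
  empty <- is.na(df$kd_uM) & is.na(df$ic50_nM) & is.na(df$label)
  if (any(empty)) {
    stop("rows with no affinity information: ",
         paste(df$complex_id[empty], collapse = ", "))
  }
  derive <- is.na(df$label) & !is.na(df$kd_uM)
  df$label[derive] <- vapply(df$kd_uM[derive], label_from_kd, character(1))
  df
}

#' Binding label from a dissociation constant
#'
#' Complexes with Kd below 200 uM are classified as strong-binding, above as
#' weak-binding. The boundary value 200 uM is assigned to the weak class.
#'
#' @param kd_uM Dissociation constant in micromolar; positive and finite.
#' @return `"strong"` or `"weak"`.
#' @export
label_from_kd <- function(kd_uM) {
  if (!is.numeric(kd_uM) || length(kd_uM) != 1L || !is.finite(kd_uM) ||
      kd_uM <= 0) {
    stop("kd_uM must be a single positive finite number")
  }
  if (kd_uM < 200) "strong" else "weak"
}

#' log50k transform of an IC50 and binder call
#'
#' Maps a peptide-MHC IC50 (nM) to `1 - log(ic50)/log(50000)`, clamped to
#' `[0, 1]`. Peptides with IC50 below 500 nM are binders, equivalently a
#' transformed score above 1 - log(500)/log(50000) (about 0.426). The
#' boundary IC50 of exactly 500 nM is a non-binder.
#'
#' @param ic50_nM IC50 in nanomolar; positive.
#' @return List with `score` in `[0,1]` and logical `binder`.
#' @export
log50k_score <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || length(ic50_nM) != 1L || !is.finite(ic50_nM) ||
      ic50_nM <= 0) {
    stop("ic50_nM must be a single positive finite number")
  }
  score <- 1 - log(ic50_nM) / log(50000)
  score <- min(1, max(0, score))
  list(score = score, binder = ic50_nM < 500)
}

#' The binder boundary on the log50k scale
#' @return `1 - log(500)/log(50000)`, about 0.4256.
#' @export
log50k_binder_threshold <- function() 1 - log(500) / log(50000)

# element symbol from a PDB atom name when the element column is absent
.element_from_name <- function(atom_name) {
  a <- gsub("[0-9']", "", atom_name)
  sub("^(Cl|Br|Fe|Zn|Mg|Se|[A-Z]).*", "\\1", a)
}

#' Parse a TCR-pMHC-I complex structure from PDB text
#'
#' Reads ATOM/HETATM records, strips hydrogens, resolves alternate locations
#' by keeping the highest-occupancy conformer per atom, maps common
#' non-standard residues to their parent amino acid (e.g. MSE to MET) and
#' drops unmappable residues with a warning. Residues are ordered by
#' (res_seq, icode) within each chain; author numbering is kept verbatim.
#'
#' @param pdb_text PDB file content as a single string or character vector of
#'   lines.
#' @param roles Chain-role map from [chain_roles()].
#' @param complex_id Identifier for the complex.
#' @param source `"experimental"` or `"predicted"`.
#' @param resolution Optional resolution in Angstroms.
#' @return A `complex_structure`: list with `complex_id`, `atoms`
#'   (data.frame: chain_id, res_seq, icode, res_name, atom_name, element,
#'   x, y, z, occupancy), `roles`, `source`, `resolution`.
#' @export
parse_structure <- function(pdb_text, roles, complex_id = "complex",
                            source = c("experimental", "predicted"),
                            resolution = NA_real_) {
  source <- match.arg(source)
  roles <- chain_roles(roles)
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    chain_id = as.character(at$chain),
    res_seq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    res_name = as.character(at$resid),
    atom_name = as.character(at$elety),
    element = as.character(at$elesy),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
  noel <- is.na(atoms$element) | atoms$element == ""
  atoms$element[noel] <- .element_from_name(atoms$atom_name[noel])

  # keep only role-mapped chains (OTHER chains ignored downstream)
  keep_chains <- names(roles)[roles %in% .roles_required]
  missing_atoms <- setdiff(keep_chains, unique(atoms$chain_id))
  if (length(missing_atoms)) {
    miss_roles <- roles[missing_atoms]
    stop("no atoms found for role chain(s): ",
         paste(sprintf("%s (chain %s)", miss_roles, missing_atoms), collapse = ", "))
  }
  atoms <- atoms[atoms$chain_id %in% keep_chains, , drop = FALSE]

  # strip hydrogens / deuterium
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

  # non-standard residues: map common ones, drop the rest
  atoms$res_name <- map_nonstandard_residue(atoms$res_name)
  atoms$atom_name[atoms$atom_name == "SE"] <- "SD"  # MSE selenium -> MET SD
  nonstd <- !is_standard_aa(atoms$res_name)
  if (any(nonstd)) {
    dropped <- unique(atoms$res_name[nonstd])
    warning("dropping non-standard residue(s): ", paste(dropped, collapse = ", "))
    atoms <- atoms[!nonstd, , drop = FALSE]
  }

  # alternate locations: retain the highest-occupancy conformer per atom
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain_id, atoms$res_seq, atoms$icode, atoms$atom_name, sep = "\r")
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  }
  atoms$altloc <- NULL

  # order residues by (chain, res_seq, icode)
  atoms <- atoms[order(atoms$chain_id, atoms$res_seq, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL

  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure ", complex_id)
  }
  for (ch in keep_chains) {
    if (!sum(atoms$chain_id == ch)) stop("zero-atom chain ", ch)
  }
  pep_chain <- names(roles)[roles == "PEPTIDE"]
  pep_len <- nrow(unique(atoms[atoms$chain_id == pep_chain,
                               c("res_seq", "icode")]))
  if (pep_len < 8) {
    warning("peptide chain has only ", pep_len,
            " residues (class I peptides are typically 8-11)")
  }

  structure(
    list(complex_id = complex_id, atoms = atoms, roles = roles,
         source = source, resolution = resolution),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain_id", "res_seq", "icode")]))
  cat("complex_structure", x$complex_id, "-", nres, "residues,",
      nrow(x$atoms), "heavy atoms\n")
  for (ch in names(x$roles)) {
    n <- sum(x$atoms$chain_id == ch)
    cat(sprintf("  chain %s [%s]: %d atoms\n", ch, x$roles[ch], n))
  }
  invisible(x)
}

#' Write a complex structure to PDB
#'
#' @param cs A `complex_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(cs, path) {
  a <- cs$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$res_seq, resid = a$res_name, elety = a$atom_name,
    chain = a$chain_id, insert = ifelse(a$icode == "", NA, a$icode),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

# residue table: one row per residue, in chain order
residue_table <- function(cs, chains = NULL) {
  a <- cs$atoms
  if (!is.null(chains)) a <- a[a$chain_id %in% chains, , drop = FALSE]
  u <- unique(a[, c("chain_id", "res_seq", "icode", "res_name")])
  rownames(u) <- NULL
  u
}

residue_key <- function(chain_id, res_seq, icode) {
  paste(chain_id, res_seq, icode, sep = ":")
}
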