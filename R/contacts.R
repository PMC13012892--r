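#' Interaction-type and potential parameters
#'
#' Thresholds for the binary interaction-type flags and parameters of the
#' pairwise potentials. Hydrogen bond: donor/acceptor heavy-atom pair below
#' 3.5 A. Salt bridge: Asp/Glu carboxylate oxygen to Lys/Arg/His basic
#' nitrogen below 4.0 A. Hydrophobic contact: two apolar side-chain carbons
#' below 5.0 A. The Coulomb term uses unit formal charges distributed over
#' the charged-group atoms; the van der Waals term is a generic 12-6
#' Lennard-Jones with per-element sigma and a single epsilon, with the
#' interatomic distance floored at `lj_floor` to keep the r^-12 branch
#' finite on imperfect geometries.
#'
#' @param hbond_max,salt_max,hydrophobic_max Distance thresholds (A).
#' @param lj_epsilon Lennard-Jones well depth (arbitrary energy units).
#' @param lj_floor Minimum interatomic distance (A) used in the potentials.
#' @return List of parameters.
#' @export
interaction_params <- function(hbond_max = 3.5, salt_max = 4.0,
                               hydrophobic_max = 5.0,
                               lj_epsilon = 0.1, lj_floor = 2.0) {
  list(hbond_max = hbond_max, salt_max = salt_max,
       hydrophobic_max = hydrophobic_max,
       lj_epsilon = lj_epsilon, lj_floor = lj_floor)
}

.lj_sigma <- c(C = 3.40, N = 3.25, O = 2.96, S = 3.50)

# atoms of one role chain with residue indices; optionally side-chain only
.role_atoms <- function(cs, role, contact_atoms) {
  ch <- names(cs$roles)[cs$roles == role]
  if (!length(ch)) stop("role ", role, " absent from structure")
  a <- cs$atoms[cs$atoms$chain_id == ch, , drop = FALSE]
  if (contact_atoms == "sidechain_heavy") {
    a <- a[!(a$atom_name %in% .backbone_atoms), , drop = FALSE]
  }
  a$res_key <- residue_key(a$chain_id, a$res_seq, a$icode)
  a
}

#' Detect cross-chain residue contacts
#'
#' A residue pair is in contact when the minimum Euclidean distance over its
#' heavy-atom pairs is at or below the cutoff. Two atom-set conventions are
#' supported: all heavy atoms (default) or side-chain heavy atoms only
#' (glycine then has no eligible atoms).
#'
#' @param cs A `complex_structure`.
#' @param role_a,role_b Chain roles (e.g. `"MHC"`, `"PEPTIDE"`).
#' @param cutoff_A Distance cutoff in Angstroms (default 8).
#' @param contact_atoms `"all_heavy"` or `"sidechain_heavy"`.
#' @return data.frame with one row per contacting residue pair: keys,
#'   residue identifiers of both partners and `min_dist`.
#' @export
detect_contacts <- function(cs, role_a, role_b, cutoff_A = 8.0,
                            contact_atoms = c("all_heavy", "sidechain_heavy")) {
  contact_atoms <- match.arg(contact_atoms)
  stopifnot(cutoff_A > 0)
  aa <- .role_atoms(cs, role_a, contact_atoms)
  ab <- .role_atoms(cs, role_b, contact_atoms)
  empty <- data.frame(key_a = character(0), key_b = character(0),
                      min_dist = numeric(0))
  if (!nrow(aa) || !nrow(ab)) return(empty)
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  fa <- factor(aa$res_key, levels = unique(aa$res_key))
  fb <- factor(ab$res_key, levels = unique(ab$res_key))
  # min over atom pairs per residue pair
  dmin <- matrix(Inf, nlevels(fa), nlevels(fb),
                 dimnames = list(levels(fa), levels(fb)))
  ia <- as.integer(fa); ib <- as.integer(fb)
  for (r in seq_len(nlevels(fa))) {
    rows <- which(ia == r)
    m <- d2[rows, , drop = FALSE]
    colmin <- apply(m, 2, min)
    dmin[r, ] <- pmin(dmin[r, ], tapply(colmin, ib, min))
  }
  dmin <- sqrt(dmin)
  hit <- which(dmin <= cutoff_A, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(key_a = rownames(dmin)[hit[, 1]],
                    key_b = colnames(dmin)[hit[, 2]],
                    min_dist = dmin[hit], stringsAsFactors = FALSE)
  out[order(out$key_a, out$key_b), , drop = FALSE]
}

# pairwise atom distances between two residue atom tables
.atom_dists <- function(ra, rb) {
  pa <- as.matrix(ra[, c("x", "y", "z")])
  pb <- as.matrix(rb[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(pmax(d2, 0))
}

# interaction-type flags and potentials for one residue pair
.edge_chemistry <- function(ra, rb, params) {
  D <- .atom_dists(ra, rb)
  don_a <- is_hbond_donor(ra$res_name, ra$atom_name)
  acc_a <- is_hbond_acceptor(ra$res_name, ra$atom_name)
  don_b <- is_hbond_donor(rb$res_name, rb$atom_name)
  acc_b <- is_hbond_acceptor(rb$res_name, rb$atom_name)
  hbond <- any(D[don_a, acc_b, drop = FALSE] < params$hbond_max) ||
    any(D[acc_a, don_b, drop = FALSE] < params$hbond_max)
  aco_a <- is_acidic_oxygen(ra$res_name, ra$atom_name)
  bn_a <- is_basic_nitrogen(ra$res_name, ra$atom_name)
  aco_b <- is_acidic_oxygen(rb$res_name, rb$atom_name)
  bn_b <- is_basic_nitrogen(rb$res_name, rb$atom_name)
  salt <- any(D[aco_a, bn_b, drop = FALSE] < params$salt_max) ||
    any(D[bn_a, aco_b, drop = FALSE] < params$salt_max)
  ap_a <- is_apolar_carbon(ra$res_name, ra$atom_name, ra$element)
  ap_b <- is_apolar_carbon(rb$res_name, rb$atom_name, rb$element)
  hydro <- any(D[ap_a, ap_b, drop = FALSE] < params$hydrophobic_max)

  Df <- pmax(D, params$lj_floor)
  # unit formal charge distributed over the residue's charged-group atoms
  qa <- numeric(nrow(ra)); qb <- numeric(nrow(rb))
  qa[aco_a] <- -1 / max(1, sum(aco_a)); qa[bn_a] <- 1 / max(1, sum(bn_a))
  qb[aco_b] <- -1 / max(1, sum(aco_b)); qb[bn_b] <- 1 / max(1, sum(bn_b))
  coul <- sum(outer(qa, qb) / Df)
  sig_a <- .lj_sigma[ra$element]; sig_a[is.na(sig_a)] <- 3.4
  sig_b <- .lj_sigma[rb$element]; sig_b[is.na(sig_b)] <- 3.4
  sig <- outer(sig_a, sig_b, "+") / 2
  sr6 <- (sig / Df)^6
  vdw <- sum(4 * params$lj_epsilon * (sr6^2 - sr6))
  c(hbond = as.numeric(hbond), salt_bridge = as.numeric(salt),
    hydrophobic = as.numeric(hydro), electrostatic = coul, vdw = vdw)
}

# inter-residue orientation: angle (degrees) between the Calpha->side-chain
# direction vectors of the two residues (90 when a residue has no side chain)
.edge_angle <- function(ra, rb) {
  dir1 <- .sc_direction(ra)
  dir2 <- .sc_direction(rb)
  if (is.null(dir1) || is.null(dir2)) return(90)
  cosang <- sum(dir1 * dir2) / (sqrt(sum(dir1^2)) * sqrt(sum(dir2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

.sc_direction <- function(ra) {
  ca <- ra[ra$atom_name == "CA", c("x", "y", "z")]
  if (!nrow(ca)) return(NULL)
  if ("CB" %in% ra$atom_name) {
    cb <- ra[ra$atom_name == "CB", c("x", "y", "z")][1, ]
    return(as.numeric(cb) - as.numeric(ca[1, ]))
  }
  sc <- ra[!(ra$atom_name %in% .backbone_atoms), c("x", "y", "z")]
  if (!nrow(sc)) return(NULL)
  colMeans(sc) - as.numeric(ca[1, ])
}
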