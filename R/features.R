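.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, Se = 1.90)

# near-uniform unit sphere points (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Rolling-probe SASA with a 1.4 A probe: each atom's solvent sphere is
#' sampled with a golden-spiral point set and the accessible fraction is the
#' share of points outside every neighbouring atom's solvent sphere.
#'
#' @param atoms Atom data.frame (columns element, x, y, z).
#' @param probe Probe radius in Angstroms.
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-atom SASA (A^2).
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 64) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .vdw_radius[atoms$element]
  rad[is.na(rad)] <- 1.7
  rs <- rad + probe
  sp <- .sphere_points(n_points)
  out <- numeric(n)
  # neighbour search via cutoff on pairwise distances
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  maxr <- max(rs)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= (rs[i] + maxr)^2)
    nb <- setdiff(nb[sqrt(pmax(d2[i, nb], 0)) <= rs[i] + rs[nb]], i)
    pts <- sweep(sp * rs[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj > rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * mean(acc)
  }
  out
}

# per-residue surface features: SASA in complex, buried surface area
# (chain-alone SASA minus in-complex SASA) and residue depth (Calpha
# distance to the nearest solvent-exposed atom of the complex)
.surface_features <- function(cs, res_tab) {
  a <- cs$atoms
  sasa_cplx <- atom_sasa(a)
  sasa_alone <- numeric(nrow(a))
  for (ch in unique(a$chain_id)) {
    idx <- a$chain_id == ch
    sasa_alone[idx] <- atom_sasa(a[idx, , drop = FALSE])
  }
  akey <- residue_key(a$chain_id, a$res_seq, a$icode)
  rkey <- residue_key(res_tab$chain_id, res_tab$res_seq, res_tab$icode)
  sasa_r <- tapply(sasa_cplx, akey, sum)[rkey]
  bsa_r <- pmax(0, tapply(sasa_alone - sasa_cplx, akey, sum)[rkey])
  exposed <- as.matrix(a[sasa_cplx > 1e-6, c("x", "y", "z"), drop = FALSE])
  depth <- vapply(seq_len(nrow(res_tab)), function(i) {
    ri <- a[akey == rkey[i], , drop = FALSE]
    ca <- ri[ri$atom_name == "CA", c("x", "y", "z")]
    p <- if (nrow(ca)) as.numeric(ca[1, ]) else colMeans(ri[, c("x", "y", "z")])
    if (!nrow(exposed)) return(0)
    sqrt(min(colSums((t(exposed) - p)^2)))
  }, numeric(1))
  cbind(sasa = unname(sasa_r), bsa = unname(bsa_r), depth = depth)
}

# backbone dihedrals, sin/cos encoded; zero when N/C atoms are absent
# (synthetic pseudo-structures carry Calpha + side-chain atoms only)
.backbone_features <- function(cs, res_tab) {
  a <- cs$atoms
  out <- matrix(0, nrow(res_tab), 4,
                dimnames = list(NULL, c("phi_sin", "phi_cos", "psi_sin", "psi_cos")))
  get_atom <- function(ch, rs, ic, nm) {
    m <- a[a$chain_id == ch & a$res_seq == rs & a$icode == ic &
             a$atom_name == nm, c("x", "y", "z")]
    if (nrow(m)) as.numeric(m[1, ]) else NULL
  }
  dihed <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }
  for (ch in unique(res_tab$chain_id)) {
    rt <- res_tab[res_tab$chain_id == ch, , drop = FALSE]
    for (k in seq_len(nrow(rt))) {
      i <- which(res_tab$chain_id == ch)[k]
      rs <- rt$res_seq[k]; ic <- rt$icode[k]
      N <- get_atom(ch, rs, ic, "N"); CA <- get_atom(ch, rs, ic, "CA")
      C <- get_atom(ch, rs, ic, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) next
      if (k > 1) {
        Cp <- get_atom(ch, rt$res_seq[k - 1], rt$icode[k - 1], "C")
        if (!is.null(Cp)) {
          phi <- dihed(Cp, N, CA, C)
          out[i, 1:2] <- c(sin(phi), cos(phi))
        }
      }
      if (k < nrow(rt)) {
        Nn <- get_atom(ch, rt$res_seq[k + 1], rt$icode[k + 1], "N")
        if (!is.null(Nn)) {
          psi <- dihed(N, CA, C, Nn)
          out[i, 3:4] <- c(sin(psi), cos(psi))
        }
      }
    }
  }
  out
}

#' Residue-level node features for a complex
#'
#' Computes the full node feature set for every residue of the role-mapped
#' chains: 20-dim amino-acid one-hot, physicochemical descriptors (formal
#' charge, Kyte-Doolittle hydropathy, polarity, side-chain volume,
#' isoelectric point, residue mass), surface features (SASA, buried surface
#' area, residue depth) and sin/cos-encoded backbone dihedrals. Node
#' coordinates are Calpha positions (residue centroid fallback).
#'
#' @param cs A `complex_structure`.
#' @return List with `res_tab` (residue table with `role`), `features`
#'   (matrix) and `coords` (n x 3).
#' @export
complex_node_features <- function(cs) {
  res_tab <- residue_table(cs)
  res_tab$role <- unname(cs$roles[res_tab$chain_id])
  tab <- aa_table()
  onehot <- matrix(0, nrow(res_tab), 20,
                   dimnames = list(NULL, paste0("aa_", aa_order())))
  onehot[cbind(seq_len(nrow(res_tab)), match(res_tab$res_name, aa_order()))] <- 1
  phys <- as.matrix(tab[res_tab$res_name,
                        c("charge", "hydropathy", "polarity",
                          "sidechain_volume", "pI", "mass")])
  rownames(phys) <- NULL
  surf <- .surface_features(cs, res_tab)
  bb <- .backbone_features(cs, res_tab)
  a <- cs$atoms
  akey <- residue_key(a$chain_id, a$res_seq, a$icode)
  rkey <- residue_key(res_tab$chain_id, res_tab$res_seq, res_tab$icode)
  coords <- t(vapply(rkey, function(k) {
    ri <- a[akey == k, , drop = FALSE]
    ca <- ri[ri$atom_name == "CA", c("x", "y", "z")]
    if (nrow(ca)) as.numeric(ca[1, ]) else colMeans(ri[, c("x", "y", "z")])
  }, numeric(3)))
  dimnames(coords) <- NULL
  list(res_tab = res_tab, features = cbind(onehot, phys, surf, bb),
       coords = coords)
}
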