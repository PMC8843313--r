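#' Protein-ligand structural analysis
#'
#' Implements the contact criteria used to profile inhibitor binding:
#' hydrogen-bond candidates as N/O/S...N/O/S pairs within 3.3 A, nonpolar
#' contacts as pairs of hydrophobic carbons (carbons whose covalent
#' neighbours are all carbon or hydrogen) within 4.2 A, plus backbone
#' least-squares superposition (Kabsch), ligand RMSD in the superposed
#' protein frame, and ligand B-factor profiling. Hydrogen-bond detection is
#' distance-only (deposited models carry no hydrogens); no angle term is
#' applied.
#'
#' @name structure_interactions
NULL

# Covalent radii (A), standard single-bond values.
.cov_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
                B = 0.84, ZN = 1.22, FE = 1.32, MG = 1.41, "NA" = 1.66,
                K = 2.03, CA = 1.76)

.radius_of <- function(element) {
  r <- .cov_radii[toupper(element)]
  r[is.na(r)] <- 0.77
  unname(r)
}

.element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  toupper(substr(s, 1, 1))
}

#' Parse a PDB file into a structure model
#'
#' Reads the first model of a standard PDB file (via bio3d), resolves
#' alternate locations to a single conformer per atom (highest occupancy,
#' ties broken by altloc letter), and infers covalent bonds by the
#' covalent-radius distance rule `d < r(a) + r(b) + 0.4 A`.
#'
#' @param file Path to a PDB file.
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame: `eleno`, `name`, `element`, `resname`, `resno`, `insert`,
#'   `chain`, `x`, `y`, `z`, `occ`, `b`, `het`, `altloc`) and `bonds`
#'   (two-column index matrix).
#' @export
parse_structure <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("parse error: no ATOM/HETATM records in ", file)
  # validate coordinate fields of every atom record, reporting line numbers
  coords_txt <- substr(lines[rec], 31, 54)
  bad <- which(is.na(suppressWarnings(
    as.numeric(substr(coords_txt, 1, 8)) +
    as.numeric(substr(coords_txt, 9, 16)) +
    as.numeric(substr(coords_txt, 17, 24)))))
  if (length(bad))
    stop("parse error: unparseable coordinates at line(s) ",
         paste(which(rec)[bad], collapse = ", "))
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  miss <- is.na(element) | element == ""
  element[miss] <- .element_from_name(at$elety[miss])
  atoms <- data.frame(eleno = at$eleno, name = at$elety,
                      element = toupper(element), resname = at$resid,
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      het = at$type == "HETATM",
                      altloc = ifelse(is.na(at$alt), "", at$alt),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("parse error: non-finite coordinates")
  # resolve altlocs: one conformer per (chain, resno, insert, resname, name)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
               atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$eleno), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = .infer_bonds(atoms)),
            class = "structure_model")
}

.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(), 0, 2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .radius_of(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + 0.4
  hit <- which(d < cut & d > 0.1 & upper.tri(d), arr.ind = TRUE)
  unname(cbind(hit[, 1], hit[, 2]))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms (%d hetero), %d inferred bonds, chains %s\n",
              nrow(x$atoms), sum(x$atoms$het), nrow(x$bonds),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

.ligand_idx <- function(model, resname, chain = NULL) {
  a <- model$atoms
  idx <- which(a$het & a$resname %in% resname &
               !a$resname %in% c("HOH", "WAT") &
               (if (is.null(chain)) TRUE else a$chain %in% chain))
  if (!length(idx))
    stop("selection error: no ligand atoms match resname ",
         paste(resname, collapse = "/"))
  idx
}

.atom_label <- function(a, i) {
  sprintf("%s/%s%d%s/%s", a$chain[i], a$resname[i], a$resno[i],
          a$insert[i], a$name[i])
}

.bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

.contact_pairs <- function(model, prot_idx, lig_idx, cutoff, kind) {
  a <- model$atoms
  if (!length(prot_idx) || !length(lig_idx))
    return(data.frame(protein_atom = character(), ligand_atom = character(),
                      distance_A = numeric(), kind = character(),
                      protein_idx = integer(), ligand_idx = integer(),
                      stringsAsFactors = FALSE))
  P <- as.matrix(a[prot_idx, c("x", "y", "z")])
  L <- as.matrix(a[lig_idx, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(protein_atom = character(), ligand_atom = character(),
                      distance_A = numeric(), kind = character(),
                      protein_idx = integer(), ligand_idx = integer(),
                      stringsAsFactors = FALSE))
  pi_ <- prot_idx[hit[, 1]]; li_ <- lig_idx[hit[, 2]]
  bonded <- .bond_key(pi_, li_) %in% .bond_key(model$bonds[, 1],
                                               model$bonds[, 2])
  keep <- !bonded
  out <- data.frame(
    protein_atom = vapply(pi_[keep], function(i) .atom_label(a, i), ""),
    ligand_atom = vapply(li_[keep], function(i) .atom_label(a, i), ""),
    distance_A = sqrt(pmax(d2[hit][keep], 0)),
    kind = kind,
    protein_idx = pi_[keep], ligand_idx = li_[keep],
    stringsAsFactors = FALSE)
  out[order(out$distance_A), ]
}

#' Hydrogen-bond candidate contacts
#'
#' All protein N/O/S ... ligand N/O/S atom pairs within the cutoff,
#' excluding covalently bonded pairs (so the covalent warhead linkage to
#' the catalytic cysteine is not counted as a hydrogen bond). Distance-only
#' criterion; no donor/acceptor or angle assignment.
#'
#' @param model A [parse_structure()] model.
#' @param resname Ligand residue name(s) (HETATM).
#' @param chain Optional chain restriction for the ligand.
#' @param cutoff Distance cutoff (A), default 3.3.
#' @return Data frame of contacts: `protein_atom`, `ligand_atom`,
#'   `distance_A`, `kind`.
#' @export
find_hbond_candidates <- function(model, resname, chain = NULL,
                                  cutoff = 3.3) {
  a <- model$atoms
  lig <- .ligand_idx(model, resname, chain)
  polar <- a$element %in% c("N", "O", "S")
  prot <- which(!a$het & polar)
  lig <- lig[polar[lig]]
  .contact_pairs(model, prot, lig, cutoff, "hbond_candidate")
}

#' Nonpolar (hydrophobic) contacts
#'
#' Carbon-carbon pairs within the cutoff in which both carbons are
#' hydrophobic: every covalent neighbour of each carbon is carbon or
#' hydrogen. Covalently bonded pairs are excluded.
#'
#' @inheritParams find_hbond_candidates
#' @param cutoff Distance cutoff (A), default 4.2.
#' @return Data frame of contacts with `kind = "nonpolar_contact"`.
#' @export
find_nonpolar_contacts <- function(model, resname, chain = NULL,
                                   cutoff = 4.2) {
  a <- model$atoms
  lig <- .ligand_idx(model, resname, chain)
  nb <- vector("list", nrow(a))
  if (nrow(model$bonds)) {
    for (k in seq_len(nrow(model$bonds))) {
      i <- model$bonds[k, 1]; j <- model$bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  hydrophobic <- vapply(seq_len(nrow(a)), function(i) {
    a$element[i] == "C" && all(a$element[nb[[i]]] %in% c("C", "H"))
  }, TRUE)
  prot <- which(!a$het & hydrophobic)
  lig <- lig[hydrophobic[lig]]
  .contact_pairs(model, prot, lig, cutoff, "nonpolar_contact")
}

#' Generic heavy-atom contacts
#'
#' Any protein ... ligand heavy-atom pair within the cutoff (excluding
#' covalently bonded pairs); the permissive contact list of which
#' hydrogen-bond candidates are a subset.
#'
#' @inheritParams find_hbond_candidates
#' @param cutoff Distance cutoff (A), default 4.2.
#' @return Data frame of contacts with `kind = "generic_contact"`.
#' @export
find_contacts <- function(model, resname, chain = NULL, cutoff = 4.2) {
  a <- model$atoms
  lig <- .ligand_idx(model, resname, chain)
  heavy <- a$element != "H"
  prot <- which(!a$het & heavy)
  lig <- lig[heavy[lig]]
  .contact_pairs(model, prot, lig, cutoff, "generic_contact")
}

#' Least-squares backbone superposition (Kabsch)
#'
#' Matches backbone atoms (N, CA, C) of the two models by chain, residue
#' number and insertion code, and computes the optimal rigid rotation and
#' translation of `model_b` onto `model_a` by singular value decomposition
#' of the cross-covariance (orthogonal Procrustes with reflection guard).
#'
#' @param model_a,model_b [parse_structure()] models (a is the fixed
#'   reference).
#' @param chains Optional chain restriction.
#' @param resno_range Optional `c(lo, hi)` residue-number window.
#' @return An object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (A) over the matched backbone atoms,
#'   `n_atoms_matched`. Transformed coordinates of any atom set from
#'   `model_b` are `xyz %*% rotation + translation` (see
#'   [apply_superposition()]).
#' @export
superpose_backbone <- function(model_a, model_b, chains = NULL,
                               resno_range = NULL) {
  pick <- function(m) {
    a <- m$atoms
    sel <- !a$het & a$name %in% c("N", "CA", "C") &
      (if (is.null(chains)) TRUE else a$chain %in% chains) &
      (if (is.null(resno_range)) TRUE
       else a$resno >= resno_range[1] & a$resno <= resno_range[2])
    d <- a[sel, ]
    d$key <- paste(d$chain, d$resno, d$insert, d$name, sep = "|")
    d
  }
  da <- pick(model_a); db <- pick(model_b)
  m <- merge(da, db, by = "key", suffixes = c(".a", ".b"))
  n_res <- length(unique(paste(m$chain.a, m$resno.a, m$insert.a)))
  if (n_res < 3)
    stop("insufficient overlap: fewer than 3 matched residues")
  A <- as.matrix(m[, c("x.a", "y.a", "z.a")])
  B <- as.matrix(m[, c("x.b", "y.b", "z.b")])
  cenA <- colMeans(A); cenB <- colMeans(B)
  Ac <- sweep(A, 2, cenA); Bc <- sweep(B, 2, cenB)
  M <- crossprod(Bc, Ac)            # maximize tr(R' M) over rotations R
  sv <- svd(M)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  trans <- cenA - drop(cenB %*% R)
  rmsd <- sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 n_atoms_matched = nrow(m)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.3f A over %d backbone atoms\n",
              x$rmsd, x$n_atoms_matched))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sup A [superpose_backbone()] result.
#' @param xyz n x 3 coordinate matrix (from the mobile model).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(xyz %*% sup$rotation, 2, sup$translation, "+")
}

#' Ligand RMSD in the superposed protein frame
#'
#' Superposes the protein backbones (unless a superposition is supplied),
#' applies that transform to the ligand of `model_b`, and computes the
#' heavy-atom RMSD against the ligand of `model_a`, matching atoms by
#' name. No refit is performed on the ligand itself, so the value measures
#' how identically the ligand sits in the two binding sites.
#'
#' @param model_a,model_b [parse_structure()] models.
#' @param resname Ligand residue name(s).
#' @param chain Optional ligand chain restriction.
#' @param superposition Optional precomputed [superpose_backbone()] result.
#' @return Ligand heavy-atom RMSD (A).
#' @export
ligand_rmsd <- function(model_a, model_b, resname, chain = NULL,
                        superposition = NULL) {
  if (is.null(superposition))
    superposition <- superpose_backbone(model_a, model_b)
  la <- model_a$atoms[.ligand_idx(model_a, resname, chain), ]
  lb <- model_b$atoms[.ligand_idx(model_b, resname, chain), ]
  la <- la[la$element != "H", ]; lb <- lb[lb$element != "H", ]
  if (!setequal(la$name, lb$name) || anyDuplicated(la$name) ||
      anyDuplicated(lb$name))
    stop("mapping error: ligand heavy-atom names do not match one-to-one")
  la <- la[order(la$name), ]; lb <- lb[order(lb$name), ]
  A <- as.matrix(la[, c("x", "y", "z")])
  B <- apply_superposition(superposition,
                           as.matrix(lb[, c("x", "y", "z")]))
  sqrt(mean(rowSums((A - B)^2)))
}

#' Ligand B-factor profile
#'
#' Per-atom B-factors of the ligand, the atom with the maximum B (ties
#' resolved by atom-name order), and optional per-substructure means.
#'
#' @param model A [parse_structure()] model.
#' @param resname Ligand residue name(s).
#' @param chain Optional ligand chain restriction.
#' @param groups Optional named character vector mapping atom names to
#'   substructure labels.
#' @return A list of class `bfactor_profile`: `atoms` (data frame `name`,
#'   `element`, `b`, ordered by atom name), `max_atom`, `group_means`
#'   (data frame or `NULL`).
#' @export
bfactor_profile <- function(model, resname, chain = NULL, groups = NULL) {
  lig <- model$atoms[.ligand_idx(model, resname, chain), ]
  tab <- data.frame(name = lig$name, element = lig$element, b = lig$b,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$name), ]
  rownames(tab) <- NULL
  max_atom <- tab$name[which.max(tab$b)]
  gm <- NULL
  if (!is.null(groups)) {
    g <- groups[tab$name]
    known <- !is.na(g)
    gm <- stats::aggregate(list(mean_b = tab$b[known]),
                           by = list(group = g[known]), FUN = mean)
  }
  structure(list(atoms = tab, max_atom = max_atom, group_means = gm),
            class = "bfactor_profile")
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat(sprintf("Ligand B-factor profile: %d atoms, max B = %.1f at %s\n",
              nrow(x$atoms), max(x$atoms$b), x$max_atom))
  if (!is.null(x$group_means)) print(x$group_means)
  invisible(x)
}

#' Write atoms to a minimal PDB file
#'
#' Fixed-column PDB writer for building small synthetic structure
#' fixtures in code (tests, examples). Not a general-purpose exporter.
#'
#' @param atoms Data frame with columns `name`, `element`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z` and optionally `b`, `occ`, `het`,
#'   `altloc`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(atoms, file) {
  n <- nrow(atoms)
  b <- if ("b" %in% names(atoms)) atoms$b else rep(20, n)
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, n)
  het <- if ("het" %in% names(atoms)) atoms$het else rep(FALSE, n)
  alt <- if ("altloc" %in% names(atoms)) atoms$altloc else rep("", n)
  lines <- vapply(seq_len(n), function(i) {
    nm <- atoms$name[i]
    nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het[i]) "HETATM" else "ATOM", i, nm4, alt[i],
            atoms$resname[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], b[i],
            toupper(atoms$element[i]))
  }, "")
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Paths to the packaged synthetic demo complex pair
#'
#' Two miniature synthetic protein-ligand complexes (a short peptide
#' scaffold plus a small ligand) constructed for demonstrations and
#' structural regression tests. They are not derived from any deposited
#' crystal structure: model "b" is a rigidly moved copy of model "a" whose
#' ligand is additionally displaced by 1 A and whose B-factors differ.
#'
#' @return Named character vector with elements `a` and `b`.
#' @export
demo_structure_paths <- function() {
  c(a = system.file("extdata", "synthetic_complex_a.pdb",
                    package = "covkin"),
    b = system.file("extdata", "synthetic_complex_b.pdb",
                    package = "covkin"))
}
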