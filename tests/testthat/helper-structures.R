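# Code-built miniature structures for the structural tests.

toy_pdb <- function(atoms) {
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(atoms, f)
  f
}

toy_atoms <- function(name, element, x, y, z, resname = "ALA", resno = 1,
                      chain = "A", het = FALSE, b = 20) {
  data.frame(name = name, element = element, resname = resname,
             resno = resno, chain = chain, x = x, y = y, z = z,
             b = b, het = het, stringsAsFactors = FALSE)
}

# Minimal 4-residue backbone (N, CA, C) as a coordinate-generating function
toy_backbone <- function() {
  do.call(rbind, lapply(1:4, function(k) {
    x0 <- 3.8 * (k - 1)
    toy_atoms(c("N", "CA", "C"), c("N", "C", "C"),
              x = x0 + c(0, 1.46, 2.40),
              y = c(0, 0, 1.00), z = c(0, 0.40, 0),
              resno = k)
  }))
}

rigid_move <- function(df, angle = 0.6, axis = c(0, 0, 1), shift = c(4, -2, 7)) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% R
  df[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  df
}

# Brute-force rigid-superposition oracle: exhaustive Euler-angle grid with
# local refinement, translations handled by centering. Independent of the
# SVD route used by the package.
euler_R <- function(ang) {
  ca <- cos(ang); sa <- sin(ang)
  Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
  Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

brute_force_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) sqrt(mean(rowSums((Ac - Bc %*% euler_R(ang))^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
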