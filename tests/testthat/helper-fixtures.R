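# Shared test scaffolding: hand-written PDB text and synthetic
# conformations with exactly controlled geometry.

# Minimal well-formed PDB ATOM line (strict column layout).
pdb_line <- function(serial, name, resname, resno, x, y, z, record = "ATOM") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, name4, resname, resno, x, y, z)
}

# A 3-residue glycine chain as raw PDB text (backbone only).
three_residue_pdb <- function() {
  k <- 0
  lines <- character(0)
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    lines <- c(lines,
               pdb_line(k + 1, "N", "GLY", i, x0, 0, 0),
               pdb_line(k + 2, "CA", "GLY", i, x0 + 1.2, 1.0, 0),
               pdb_line(k + 3, "C", "GLY", i, x0 + 2.4, 0.2, 0),
               pdb_line(k + 4, "O", "GLY", i, x0 + 2.4, -1.0, 0.5))
    k <- k + 4
  }
  c(lines, "END")
}

write_pdb_text <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

# Sparse synthetic conformation: each residue is a set of atoms placed at
# explicit coordinates; amide hydrogens are assigned directly so that
# counting geometry is fully controlled. `atoms` is a data frame with
# resno, elety, x, y, z. `amide_h` is a named list resno -> coords.
sparse_conformation <- function(n, atoms, amide_h = list()) {
  base <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(resno = i, resid = "ALA", elety = "N",
               x = 1000 * i, y = 0, z = 0, stringsAsFactors = FALSE)
  }))
  if (!is.null(atoms)) {
    atoms$resid <- "ALA"
    base <- rbind(base, atoms[, c("resno", "resid", "elety", "x", "y", "z")])
  }
  base <- base[order(base$resno), ]
  conf <- new_conformation(base, label = "sparse")
  for (key in names(amide_h)) {
    conf$amide_h[as.integer(key), ] <- amide_h[[key]]
  }
  conf
}

# Independent O(n^2) recount of hydrogen bonds and contacts, written as a
# plain double loop with its own exclusion logic.
brute_force_counts <- function(conf, i, hbond_cutoff = 2.4,
                               contact_cutoff = 6.5, window = 2) {
  h <- conf$amide_h[i, ]
  nh <- 0L
  nc <- 0L
  for (r in seq_len(nrow(conf$atoms))) {
    j <- conf$atoms$resno[r]
    if (j >= i - window && j <= i + window) next
    d <- sqrt((conf$atoms$x[r] - h[1])^2 + (conf$atoms$y[r] - h[2])^2 +
                (conf$atoms$z[r] - h[3])^2)
    if (conf$atoms$elety[r] == "O" && d <= hbond_cutoff) nh <- nh + 1L
    if (conf$atoms$is_heavy[r] && d <= contact_cutoff) nc <- nc + 1L
  }
  c(nh = nh, nc = nc)
}

# Random rigid-body transform applied to a conformation's atoms.
random_rigid_transform <- function(conf, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  ang <- runif(1, 10, 170)
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- pfkit:::rotate_about_axis(xyz, c(0, 0, 0), ax, ang)
  xyz <- sweep(xyz, 2, shift, "+")
  conf$atoms[, c("x", "y", "z")] <- xyz
  hsel <- which(stats::complete.cases(conf$amide_h))
  if (length(hsel) > 0) {
    hh <- pfkit:::rotate_about_axis(conf$amide_h[hsel, , drop = FALSE],
                                    c(0, 0, 0), ax, ang)
    conf$amide_h[hsel, ] <- sweep(hh, 2, shift, "+")
  }
  conf
}

backbone_xyz <- function(conf) {
  as.matrix(conf$atoms[conf$atoms$elety %in% c("N", "CA", "C"),
                       c("x", "y", "z")])
}
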