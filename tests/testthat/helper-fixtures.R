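# fixtures built in code: small PDB/XYZ texts and a constructed active-site
# frame with exactly known criterion distances and hydride angle

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          altloc = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %s%s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial,
          ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name)),
          altloc, resname, chain, resid, x, y, z, 1, 0, element)
}

three_atom_pdb <- function() {
  c(pdb_atom_line(1, "N", "ALA", "A", 1, 1.0, 2.0, 3.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2.5, 2.0, 3.0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 3.0, 3.5, 3.0),
    "END")
}

two_model_pdb <- function() {
  atoms <- three_atom_pdb()[1:3]
  c("MODEL        1", atoms, "ENDMDL",
    "MODEL        2", atoms, "ENDMDL", "END")
}

write_lines_tmp <- function(lines, ext = ".pdb", gz = FALSE) {
  path <- tempfile(fileext = if (gz) paste0(ext, ".gz") else ext)
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# active-site frame on synthetic_topology() with exact criterion distances
# (Angstrom) and hydride angle (degrees); mirrors the generator's published
# placement scheme but is written independently here as a fixture
site_frame <- function(d_tyr = 3.0, d_thr = 3.0, d_lys = 3.0, d_hyd = 3.4,
                       hydride_angle = 135) {
  top <- synthetic_topology()
  key <- paste(top$resname, top$name, sep = ".")
  fr <- matrix(0, nrow = nrow(top), ncol = 3)
  O2 <- c(0, 0, 0)
  C2 <- O2 + 1.43 * c(-1, -1, 0) / sqrt(2)
  NZ <- c(4, 4, 4)
  fr[key == "HEX.O2", ] <- O2
  fr[key == "HEX.C2", ] <- C2
  fr[key == "LYS.NZ", ] <- NZ
  fr[key == "TYR.OH", ] <- O2 + d_tyr * c(1, 0, 0)
  fr[key == "THR.OG1", ] <- O2 + d_thr * c(0, 1, 0)
  fr[key == "NAD.O2R", ] <- NZ + d_lys * c(1, 1, -1) / sqrt(3)
  fr[key == "NAD.O3R", ] <- NZ + (d_lys + 1) * c(-1, 1, 1) / sqrt(3)
  C4 <- C2 + d_hyd * c(0, 0, 1)
  fr[key == "NAD.C4", ] <- C4
  alpha <- hydride_angle * pi / 180
  gam <- asin(min(1, 1.09 * sin(alpha) / d_hyd))
  beta <- pi - alpha - gam
  fr[key == "HEX.H2", ] <- C2 + 1.09 * (cos(beta) * c(0, 0, 1) +
                                          sin(beta) * c(1, 0, 0))
  fr[key == "HEX.O3", ] <- c(1.2, -1.2, 0.5)
  fr[key == "HEX.O4", ] <- c(2.2, 0.8, -0.4)
  fr[key == "ASN.CG", ] <- c(5, -5, 5)
  fr[key == "GLN.CD", ] <- c(5, 5, -5)
  fr[key == "VAL.O", ] <- c(-5, 5, 5)
  fr[key == "MET.O", ] <- c(-5, -5, 5)
  pp <- rbind(c(-0.8, 1.386, 0), c(0, 0, 0), c(1.6, 0, 0), c(2.4, 1.2, 0.4))
  fr[top$resname == "CDP", ] <- sweep(pp, 2, c(10, 10, 10), `+`)
  fr[top$resname == "PYR", ] <- sweep(build_ring(0.57, 0, 0), 2,
                                      c(-10, -10, -10), `+`)
  list(topology = top, frame = fr)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
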