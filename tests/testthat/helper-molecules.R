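# Programmatic construction of tiny V2000 SDF records for feature
# perception tests.

sdf_record <- function(title, atoms, bonds, charges = NULL) {
  # atoms: data.frame(elem, x, y, z); bonds: data.frame(a1, a2, order)
  # charges: data.frame(atom, charge)
  lines <- c(title, "  testthat", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(atoms), nrow(bonds)))
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], atoms$z[i], atoms$elem[i]))
  }
  for (i in seq_len(nrow(bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$a1[i], bonds$a2[i],
                              bonds$order[i]))
  }
  if (!is.null(charges)) {
    for (i in seq_len(nrow(charges))) {
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", charges$atom[i],
                                charges$charge[i]))
    }
  }
  c(lines, "M  END", "$$$$")
}

write_sdf <- function(..., path = tempfile(fileext = ".sdf")) {
  writeLines(unlist(list(...)), path)
  path
}

benzene_record <- function(title = "benzene") {
  ang <- (0:5) * pi / 3
  atoms <- data.frame(elem = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang),
                      z = 0)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  sdf_record(title, atoms, bonds)
}

methane_record <- function(title = "methane") {
  atoms <- data.frame(
    elem = c("C", "H", "H", "H", "H"),
    x = c(0, 0.63, -0.63, -0.63, 0.63),
    y = c(0, 0.63, -0.63, 0.63, -0.63),
    z = c(0, 0.63, 0.63, -0.63, -0.63))
  bonds <- data.frame(a1 = 1, a2 = 2:5, order = 1)
  sdf_record(title, atoms, bonds)
}

acetate_record <- function(title = "acetate") {
  atoms <- data.frame(
    elem = c("C", "C", "O", "O"),
    x = c(0, 1.52, 2.13, 2.13),
    y = c(0, 0, 1.08, -1.08),
    z = 0)
  bonds <- data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1, 2, 1))
  sdf_record(title, atoms, bonds, charges = data.frame(atom = 4, charge = -1))
}

# n-pentane: one hydrophobic chain of 5 carbons, no other features
pentane_record <- function(title = "pentane") {
  atoms <- data.frame(elem = "C", x = 1.53 * (0:4), y = rep(c(0, 0.5), 3)[1:5],
                      z = 0)
  bonds <- data.frame(a1 = 1:4, a2 = 2:5, order = 1)
  sdf_record(title, atoms, bonds)
}

# ethanol: HBD + HBA on the hydroxyl oxygen, no hydrophobic (chain of 2)
ethanol_record <- function(title = "ethanol") {
  atoms <- data.frame(elem = c("C", "C", "O"),
                      x = c(0, 1.53, 2.2), y = c(0, 0, 1.2), z = 0)
  bonds <- data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1)
  sdf_record(title, atoms, bonds)
}
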