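# Fixtures built in code: idealized geometries, small structure files and
# synthetic feature tables shared across test files.

# The construction lengths used for the idealized keto-enol ring fixture.
IDEAL_LENGTHS <- c(r_OH = 0.99, r_CO = 1.33, r_CC_double = 1.37,
                   r_CC_single = 1.44, r_CO_double = 1.24)

keto_enol_fixture <- function(torsion = 180, lengths = IDEAL_LENGTHS) {
  perceive_bonds(generate_fragment_geometry(lengths, torsion_deg = torsion))
}

write_xyz_file <- function(mol, path) {
  n <- length(mol$elements)
  lines <- c(as.character(n), mol$name,
             sprintf("%s %.10f %.10f %.10f", mol$elements,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
  writeLines(lines, path)
  path
}

# Benzene at ideal geometry: C ring radius 1.39 (C-C bond 1.39), H radially
# outward at 1.09.
benzene_molecule <- function() {
  ang <- (0:5) * pi / 3
  cc <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hh <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  molecule3d(c(rep("C", 6), rep("H", 6)), rbind(cc, hh), name = "benzene")
}

# Minimal single-record ethanol MOL V2000 text (9 atoms, 8 bonds).
ethanol_mol_lines <- function() {
  atoms <- rbind(
    c(-0.888, 0.167, -0.027, "C"), c(0.465, -0.514, -0.037, "C"),
    c(1.431, 0.316, 0.543, "O"), c(-1.217, 0.419, 0.987, "H"),
    c(-0.850, 1.094, -0.611, "H"), c(-1.634, -0.491, -0.478, "H"),
    c(0.441, -1.448, 0.537, "H"), c(0.786, -0.741, -1.062, "H"),
    c(2.297, -0.113, 0.494, "H"))
  bonds <- rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(1, 5, 1),
                 c(1, 6, 1), c(2, 7, 1), c(2, 8, 1), c(3, 9, 1))
  c("ethanol", "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 9L, 8L),
    apply(atoms, 1, function(a)
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              as.numeric(a[1]), as.numeric(a[2]), as.numeric(a[3]), a[4])),
    apply(bonds, 1, function(b)
      sprintf("%3d%3d%3d  0  0  0  0", b[1], b[2], b[3])),
    "M  END")
}

# A feature table where only bond ii (r_CO) carries the pKa signal; the
# other four bonds are independent noise.
single_signal_dataset <- function(n = 40, slope = 93.381,
                                  intercept = -127.71, noise_sd = 0.1,
                                  seed = 0) {
  set.seed(seed)
  r_co <- runif(n, 1.30, 1.36)
  df <- data.frame(
    id = paste0("s", seq_len(n)),
    pka_exp = slope * r_co + intercept + rnorm(n, 0, noise_sd),
    r_OH = runif(n, 0.96, 1.02),
    r_CO = r_co,
    r_CC_double = runif(n, 1.34, 1.40),
    r_CC_single = runif(n, 1.42, 1.48),
    r_CO_double = runif(n, 1.21, 1.27))
  aibl_dataset(df)
}

# Noise-free multivariate linear response for fitter contract tests.
linear_xy <- function(n = 30, p = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  beta <- seq_len(p)
  list(X = X, y = drop(X %*% beta) + 2)
}
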