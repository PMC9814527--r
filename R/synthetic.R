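# Congeneric-series synthetic data: linear bond-length/pKa structure with
# correlated five-bond feature vectors, plus an idealized keto-enol
# geometry builder for testing the geometry module end to end.

# Default per-bond length windows (Angstrom), chemically plausible for the
# enolized 1,3-dione fragment; frozen here.
DEFAULT_LENGTH_WINDOWS <- list(
  r_OH        = c(0.96, 1.02),
  r_CO        = c(1.30, 1.36),
  r_CC_double = c(1.34, 1.40),
  r_CC_single = c(1.42, 1.48),
  r_CO_double = c(1.21, 1.27)
)

#' Default feature cross-correlation matrix
#'
#' Encodes the sign pattern of bond-length co-variation along the acidity
#' axis -- more acidic compounds have longer O-H and C=C bonds but shorter
#' C-O distances -- as a single-factor correlation structure with loadings
#' of magnitude 0.9 on the C-O axis: corr(r_CO, r_OH) = corr(r_CO,
#' r_CC_double) = -0.9 and corr(r_CO, r_CC_single) = corr(r_CO,
#' r_CO_double) = +0.9.  Positive definite by construction.
#'
#' @return A 5x5 correlation matrix in feature order
#'   (r_OH, r_CO, r_CC_double, r_CC_single, r_CO_double).
#' @export
default_cross_correlations <- function() {
  loadings <- c(r_OH = -0.9, r_CO = 1, r_CC_double = -0.9,
                r_CC_single = 0.9, r_CO_double = 0.9)
  R <- tcrossprod(loadings) + diag(1 - loadings^2)
  dimnames(R) <- list(names(loadings), names(loadings))
  R
}

#' Specify a synthetic congeneric series
#'
#' Defaults emulate the modeled study conditions: 49 compounds, the
#' published C-O model line (slope 93.381 pKa/Angstrom, intercept -127.71),
#' C-O lengths uniform over 1.30-1.36 Angstrom and Gaussian pKa noise with
#' s.d. 0.3 (the scale of the cross-validated single-bond errors).
#'
#' @param label series tag.
#' @param n_compounds number of compounds, >= 3.
#' @param slope,intercept the linear pKa-vs-r(CO) relationship.
#' @param length_range (min, max) window for r_CO in Angstrom.
#' @param noise_sd Gaussian pKa noise, >= 0.
#' @param cross_correlations 5x5 feature correlation matrix (symmetric,
#'   positive semi-definite, unit diagonal).
#' @param seed integer seed.
#' @return A \code{series_spec} list.
#' @export
series_spec <- function(label = "syn", n_compounds = 49, slope = 93.381,
                        intercept = -127.71,
                        length_range = DEFAULT_LENGTH_WINDOWS$r_CO,
                        noise_sd = 0.3,
                        cross_correlations = default_cross_correlations(),
                        seed = 0) {
  if (n_compounds < 3L) stop2("n_compounds must be >= 3")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (length_range[1] >= length_range[2]) stop2("invalid length_range")
  R <- as.matrix(cross_correlations)
  if (nrow(R) != 5L || ncol(R) != 5L || max(abs(R - t(R))) > 1e-10 ||
      max(abs(diag(R) - 1)) > 1e-10)
    stop2("cross_correlations must be a symmetric 5x5 unit-diagonal matrix")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop2("cross_correlations must be positive semi-definite")
  structure(list(label = label, n_compounds = as.integer(n_compounds),
                 slope = slope, intercept = intercept,
                 length_range = length_range, noise_sd = noise_sd,
                 cross_correlations = R, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic congeneric series
#'
#' Draws correlated standard-normal scores with the spec's cross-correlation
#' matrix (Gaussian copula), maps the C-O score to a uniform draw over
#' \code{length_range}, maps the other four bonds into their default
#' windows, and sets pKa = slope * r_CO + intercept + N(0, noise_sd).
#' Fully deterministic given the spec's seed.
#'
#' @param spec a \code{\link{series_spec}}.
#' @return An \code{\link{aibl_dataset}} with ids \code{<label>1..n}.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  n <- spec$n_compounds
  R <- spec$cross_correlations
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Z <- with_seed(spec$seed, {
    z <- matrix(rnorm(n * 5L), n, 5L) %*% A
    eps <- rnorm(n, 0, spec$noise_sd)
    list(z = z, eps = eps)
  })
  z <- Z$z
  colnames(z) <- names(FEATURE_COLUMNS)  # i..v in order
  r_co <- spec$length_range[1] +
    pnorm(z[, 2]) * diff(spec$length_range)
  feat <- matrix(NA_real_, n, 5L, dimnames = list(NULL, unname(FEATURE_COLUMNS)))
  feat[, "r_CO"] <- r_co
  for (j in c(1L, 3L, 4L, 5L)) {
    w <- DEFAULT_LENGTH_WINDOWS[[unname(FEATURE_COLUMNS[j])]]
    feat[, j] <- mean(w) + diff(w) / 6 * z[, j]  # +/- 3 sd spans the window
  }
  pka <- spec$slope * r_co + spec$intercept + Z$eps
  df <- data.frame(id = paste0(spec$label, seq_len(n)), series = spec$label,
                   pka_exp = pka, feat, stringsAsFactors = FALSE)
  aibl_dataset(df, provenance = sprintf(
    "synthetic series '%s' (n=%d, slope=%g, intercept=%g, noise_sd=%g, seed=%d)",
    spec$label, n, spec$slope, spec$intercept, spec$noise_sd, spec$seed))
}

#' Generate two congeneric series with a slope ratio
#'
#' The second series reuses the base spec with its slope multiplied by
#' \code{slope_ratio} (e.g. 1.22 for a 22 percent steeper trend) and seed
#' offset by one, emulating two substituent families whose bond-length/pKa
#' lines share structure but differ in steepness.
#'
#' @param spec_base a \code{\link{series_spec}} for the first series.
#' @param slope_ratio positive slope multiplier for the second series.
#' @return An \code{\link{aibl_dataset}} holding both labeled series.
#' @export
generate_two_series <- function(spec_base, slope_ratio = 1.22) {
  stopifnot(inherits(spec_base, "series_spec"))
  if (slope_ratio <= 0) stop2("slope_ratio must be positive")
  spec2 <- spec_base
  spec2$label <- paste0(spec_base$label, "b")
  spec2$slope <- spec_base$slope * slope_ratio
  # anchor the second line at the window midpoint so the two series stay in
  # the same pKa range despite the steeper slope
  mid <- mean(spec_base$length_range)
  spec2$intercept <- spec_base$intercept - (spec2$slope - spec_base$slope) * mid
  spec2$seed <- spec_base$seed + 1L
  d1 <- generate_series(spec_base)
  d2 <- generate_series(spec2)
  df <- rbind(as.data.frame(d1), as.data.frame(d2))
  aibl_dataset(df, provenance = sprintf(
    "two synthetic series, slope ratio %g (seeds %d, %d)",
    slope_ratio, spec_base$seed, spec2$seed))
}

# ---------------------------------------------------------------------------
# Idealized fragment geometry builder.

# Circumradius of the planar cyclic polygon with the given side lengths:
# solve sum(2 asin(s_i / 2R)) = 2 pi.
cyclic_polygon_radius <- function(sides) {
  if (max(sides) >= sum(sides) - max(sides))
    stop2("impossible ring closure: one side exceeds the sum of the others")
  f <- function(R) sum(2 * asin(pmin(sides / (2 * R), 1))) - 2 * pi
  lo <- max(sides) / 2 * (1 + 1e-12)
  hi <- sum(sides)  # f(hi) < 0 for any polygon
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

# Place atom D given positions A, B, C, the distance |CD|, the angle B-C-D
# (degrees) and the dihedral A-B-C-D (degrees).  Standard internal
# coordinate (NeRF) construction.
place_atom <- function(A, B, C, dist, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- dihedral_deg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-dist * cos(th), dist * sin(th) * cos(ph), dist * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized planar keto-enol ring geometry
#'
#' Constructs a planar six-membered carbocycle whose C1=C2 and C2-C3 sides
#' take the requested bond-iii and bond-iv lengths (remaining ring bonds
#' 1.52 Angstrom), attaches the enol oxygen at C1 (bond ii) and the keto
#' oxygen at C3 (bond v) along the in-plane exterior bisectors, and places
#' the hydroxyl hydrogen at the bond-i distance with a 109.47-degree
#' C1-O-H angle and the requested C2-C1-O-H torsion.  Measured back with
#' \code{\link{extract_features}}, the construction parameters are
#' recovered to numerical precision.
#'
#' @param lengths a five-element feature vector (see
#'   \code{\link{validate_feature_vector}}): r_OH, r_CO, r_CC_double,
#'   r_CC_single, r_CO_double in Angstrom.
#' @param torsion_deg the C2-C1-O-H torsion in degrees (0 = syn,
#'   180 = anti).
#' @param name molecule name.
#' @return A \code{\link{molecule3d}} of 9 atoms (6 C, 2 O, 1 H), bonds
#'   unperceived.
#' @export
generate_fragment_geometry <- function(lengths, torsion_deg = 180,
                                       name = "keto-enol fixture") {
  v <- validate_feature_vector(lengths)
  ring_cc <- 1.52
  sides <- c(v[["r_CC_double"]], v[["r_CC_single"]],
             ring_cc, ring_cc, ring_cc, ring_cc)
  R <- cyclic_polygon_radius(sides)
  central <- 2 * asin(sides / (2 * R))
  ang <- cumsum(c(0, central))[seq_len(6)]
  ring <- cbind(R * cos(ang), R * sin(ang), 0)  # C1, C2, C3, C4, C5, C6
  centroid <- colMeans(ring)

  # in-plane exterior bisector at a ring vertex
  outward <- function(i, prev, nxt) {
    u <- ring[prev, ] - ring[i, ]; u <- u / sqrt(sum(u^2))
    w <- ring[nxt, ] - ring[i, ]; w <- w / sqrt(sum(w^2))
    b <- -(u + w)
    if (sqrt(sum(b^2)) < 1e-12) b <- ring[i, ] - centroid
    b / sqrt(sum(b^2))
  }
  o_enol <- ring[1, ] + v[["r_CO"]] * outward(1, 6, 2)
  o_keto <- ring[3, ] + v[["r_CO_double"]] * outward(3, 2, 4)
  h <- place_atom(ring[2, ], ring[1, ], o_enol, v[["r_OH"]], 109.47,
                  torsion_deg)
  coords <- rbind(ring, o_enol, o_keto, h)
  molecule3d(c(rep("C", 6), "O", "O", "H"), coords, name = name)
}
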