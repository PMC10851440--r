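## Structural comparison of optimized intersection geometries: multi-frame
## XYZ I/O, optimal-superposition RMSD (Kabsch, proper rotations only),
## signed dihedral angles, and ensemble RMSD/dihedral reports.
## Geometry coordinates are in Angstrom throughout this file.

#' Molecular geometry container
#'
#' @param elements Character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param label Free-text label (system / ensemble-member tag); stored on
#'   the XYZ comment line.
#' @return A `geometry` object.
#' @export
geometry <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching elements")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(elements = as.character(elements),
                 coords = unname(coords), label = as.character(label)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("Geometry '%s': %d atoms (%s)\n", x$label,
              length(x$elements),
              paste(unique(x$elements), collapse = " ")))
  invisible(x)
}

#' Read / write multi-frame XYZ files
#'
#' Standard XYZ layout: atom-count line, comment line (used as the frame
#' label), then one `element x y z` line per atom; frames concatenate.
#' Malformed counts or truncated frames raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @return `read_xyz`: a list of [geometry()] objects (one per frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("XYZ parse error at line ", i, ": expected a positive atom count")
    if (i + 1L + n > length(lines))
      stop("XYZ parse error at line ", i, ": frame declares ", n,
           " atoms but the file ends early")
    label <- lines[i + 1L]
    el <- character(n); xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop("XYZ parse error at line ", ln,
             ": expected 'element x y z'")
      vals <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(vals)))
        stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
      el[k] <- tok[1]; xyz[k, ] <- vals
    }
    out[[length(out) + 1L]] <- geometry(el, xyz, label)
    i <- i + 2L + n
  }
  if (!length(out)) stop("no XYZ frames found in ", path)
  out
}

#' @rdname read_xyz
#' @param geometries A [geometry()] or list of them.
#' @param digits Printed coordinate precision.
#' @return `write_xyz`: the path, invisibly.
#' @export
write_xyz <- function(geometries, path, digits = 10L) {
  if (inherits(geometries, "geometry")) geometries <- list(geometries)
  fmt <- paste0("%-3s %", digits + 8L, ".", digits, "f %",
                digits + 8L, ".", digits, "f %", digits + 8L, ".", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geometries) {
    writeLines(as.character(length(g$elements)), con)
    writeLines(g$label, con)
    writeLines(sprintf(fmt, g$elements, g$coords[, 1], g$coords[, 2],
                       g$coords[, 3]), con)
  }
  invisible(path)
}

#' Optimal-superposition RMSD between two geometries
#'
#' Kabsch least-squares alignment: both structures are centered, the
#' optimal proper rotation is obtained from the SVD of the covariance
#' matrix with the usual determinant correction (reflections are never
#' applied, so enantiomers keep a nonzero RMSD), and the returned RMSD is
#' the global minimum over rigid motions.
#'
#' @param a,b [geometry()] objects with the same element sequence (after
#'   masking).  `b` is rotated onto `a`.
#' @param atom_mask Optional integer vector of atom indices (1-based) to
#'   superpose on, e.g. heavy atoms only.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3, det +1),
#'   `translation` (so `coords_b %*% t(rotation) + translation` aligns onto
#'   `a`), and `flags` (contains `"degenerate"` for collinear or otherwise
#'   rank-deficient point sets, where the rotation is not unique; the RMSD
#'   itself is still the optimum).
#' @export
#' @examples
#' a <- geometry(c("C","C","O","H"), matrix(rnorm(12), 4, 3))
#' superpose_rmsd(a, a)$rmsd   # 0
superpose_rmsd <- function(a, b, atom_mask = NULL) {
  if (!is.null(atom_mask)) {
    a <- geometry(a$elements[atom_mask], a$coords[atom_mask, , drop = FALSE],
                  a$label)
    b <- geometry(b$elements[atom_mask], b$coords[atom_mask, , drop = FALSE],
                  b$label)
  }
  if (length(a$elements) != length(b$elements) ||
      !all(a$elements == b$elements))
    stop("element sequences differ; superposition is by file order")
  n <- nrow(a$coords)
  ca <- colMeans(a$coords); cb <- colMeans(b$coords)
  A <- sweep(a$coords, 2, ca); Bm <- sweep(b$coords, 2, cb)
  flags <- character()
  H <- t(Bm) %*% A
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # maps centered b onto centered a
  ## rank deficiency of either point set: rotation not unique
  if (n < 3L || min(svd(A)$d) < 1e-8 * max(svd(A)$d, 1e-12) ||
      min(svd(Bm)$d) < 1e-8 * max(svd(Bm)$d, 1e-12))
    flags <- c(flags, "degenerate")
  fitted <- Bm %*% R
  rmsd <- sqrt(sum((fitted - A)^2) / n)
  list(rmsd = rmsd, rotation = t(R),
       translation = ca - drop(cb %*% R),
       flags = flags)
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC convention: looking from atom j to atom k, the angle from the
#' i-j-k plane to the j-k-l plane, positive clockwise, in `(-180, 180]`
#' degrees.
#'
#' @param g A [geometry()].
#' @param i,j,k,l Four distinct 1-based atom indices.
#' @return Angle in degrees.
#' @export
dihedral <- function(g, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (length(unique(idx)) != 4L) stop("dihedral needs four distinct atoms")
  p <- g$coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20)
    stop("undefined torsion: consecutive atoms coincide")
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined torsion: collinear atoms")
  ang <- atan2(sum(b2 / sqrt(sum(b2^2)) * pracma_cross(n1, n2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## smallest signed angular difference a - b on the circle, in (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Ensemble RMSD and dihedral report
#'
#' Superposes every ensemble member onto a reference member, tracks one
#' dihedral angle per member, and reports the Spearman rank correlation
#' between the absolute dihedral change (relative to the reference, on the
#' circle) and the RMSD.  Rank correlation is used because the association
#' is expected to be monotone, not linear.
#'
#' @param ensemble List of [geometry()] objects.
#' @param reference_label Label of the reference member (must be present).
#' @param dihedral_spec Four 1-based atom indices of the tracked dihedral.
#' @param atom_mask Optional superposition mask, as in [superpose_rmsd()].
#' @return An `rmsd_report`: data frame `members` (label, rmsd,
#'   dihedral, dihedral_change, flags), `reference_label`, and
#'   `correlation` (Spearman rho, `NA` with `correlation_note` when
#'   undefined, e.g. all members identical).
#' @export
ensemble_structure_report <- function(ensemble, reference_label,
                                      dihedral_spec, atom_mask = NULL) {
  labels <- vapply(ensemble, function(g) g$label, character(1))
  ref_i <- match(reference_label, labels)
  if (is.na(ref_i)) stop("reference '", reference_label,
                         "' not found in ensemble")
  ref <- ensemble[[ref_i]]
  ref_dih <- dihedral(ref, dihedral_spec[1], dihedral_spec[2],
                      dihedral_spec[3], dihedral_spec[4])
  ## order-invariant content: members reported sorted by label
  ord <- order(labels)
  rows <- lapply(ord, function(ii) {
    g <- ensemble[[ii]]
    sp <- superpose_rmsd(ref, g, atom_mask)
    dih <- dihedral(g, dihedral_spec[1], dihedral_spec[2],
                    dihedral_spec[3], dihedral_spec[4])
    data.frame(label = g$label, rmsd = sp$rmsd, dihedral = dih,
               dihedral_change = abs(angle_diff(dih, ref_dih)),
               flags = paste(sp$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, rows)
  non_ref <- members$label != reference_label
  corr <- NA_real_; note <- ""
  x <- members$dihedral_change[non_ref]; y <- members$rmsd[non_ref]
  if (length(x) >= 2 && stats::sd(x) > 1e-9 && stats::sd(y) > 1e-9) {
    corr <- stats::cor(x, y, method = "spearman")
  } else {
    note <- "not applicable: no variation across members"
  }
  structure(list(reference_label = reference_label, members = members,
                 dihedral_spec = dihedral_spec,
                 correlation = corr, correlation_note = note),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat("Structural report vs '", x$reference_label, "' (",
      nrow(x$members), " members)\n", sep = "")
  cat(sprintf("  rmsd: %.4f - %.4f Angstrom; Spearman(|d-dihedral|, rmsd) = %s\n",
              min(x$members$rmsd), max(x$members$rmsd),
              if (is.na(x$correlation)) x$correlation_note
              else sprintf("%.3f", x$correlation)))
  invisible(x)
}

#' Write an RMSD report as CSV
#'
#' @param report An `rmsd_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rmsd_csv <- function(report, path) {
  m <- report$members
  lines <- c("label,rmsd_angstrom,dihedral_deg,dihedral_change_deg,flags",
             sprintf("%s,%.12g,%.12g,%.12g,%s", m$label, m$rmsd, m$dihedral,
                     m$dihedral_change, m$flags))
  writeLines(lines, path)
  invisible(path)
}
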