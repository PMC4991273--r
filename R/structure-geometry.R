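#' Labelled Cartesian atom set
#'
#' @param labels unique atom identifiers.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates
#'   (Angstrom).
#' @return An object of class \code{"atom_set"}.
#' @export
atom_set <- function(labels, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("'coords' must have 3 columns (x, y, z)")
  if (length(labels) != nrow(coords))
    stop("one label per coordinate row required")
  if (anyDuplicated(labels)) stop("atom labels must be unique")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  rownames(coords) <- labels
  structure(list(labels = as.character(labels), coords = coords),
            class = "atom_set")
}

#' Torsion (dihedral) angle of four atoms
#'
#' Standard torsion angle about the b-c bond, reported as an unsigned
#' angle in [0, 180] degrees (the convention used when comparing
#' crystallographic and modelled conformations, e.g. the
#' C_alkyl-C-N-C_morph linker twist).
#'
#' @param a,b,c,d numeric length-3 coordinates (Angstrom).
#' @return Angle in degrees, in [0, 180].
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1))  # 180
#' @export
dihedral_angle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  stopifnot(length(a) == 3, length(b) == 3, length(c) == 3,
            length(d) == 3)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  if (vnorm(n1) < 1e-10 * vnorm(b1) * vnorm(b2) ||
      vnorm(n2) < 1e-10 * vnorm(b2) * vnorm(b3))
    stop("three consecutive atoms are collinear; dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(crossprod3(n1, b2 / vnorm(b2)) * n2)
  abs(atan2(y, x)) * 180 / pi
}

crossprod3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

vnorm <- function(u) sqrt(sum(u * u))

#' Interatomic distance
#'
#' Euclidean distance between two points (Angstrom).
#'
#' @param a,b numeric length-3 coordinates.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3, length(b) == 3)
  vnorm(a - b)
}

#' Read an XYZ-format coordinate file
#'
#' Plain "element x y z" rows; an optional leading atom-count line and
#' comment line (standard XYZ) are detected and skipped. Duplicate
#' element symbols are disambiguated with a numeric suffix.
#'
#' @param path file path.
#' @return An \code{\link{atom_set}}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ## standard XYZ header: count line + comment line
  if (length(lines) >= 1 && grepl("^[0-9]+$", lines[1])) {
    nat <- as.integer(lines[1])
    lines <- lines[-(1:2)]
    if (length(lines) < nat)
      stop("XYZ header declares ", nat, " atoms but only ",
           length(lines), " rows follow")
    lines <- lines[seq_len(nat)]
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 0L) < 4)
  if (length(bad))
    stop("malformed XYZ row at line ", bad[1], ": '", lines[bad[1]], "'")
  el <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz)))
    stop("non-numeric coordinate in XYZ file")
  labels <- make.unique(el, sep = "")
  atom_set(labels, xyz)
}
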