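#' Absorption spectrum
#'
#' Container for a raw X-ray absorption spectrum: absorption coefficient
#' \eqn{\mu} versus incident photon energy. This is the common currency of
#' the XANES and EXAFS stages; every reader and generator returns one.
#'
#' @param energies Numeric vector of photon energies in eV, strictly
#'   increasing.
#' @param mu Numeric vector of absorption values (arbitrary units), same
#'   length as `energies`.
#' @param label Free-text label carried through the analysis.
#'
#' @return An object of class `xas_spectrum`: a list with elements
#'   `energies`, `mu` and `label`.
#' @export
#' @examples
#' s <- xas_spectrum(seq(7500, 8100, by = 2), rep(0.5, 301), "flat")
xas_spectrum <- function(energies, mu, label = "") {
  energies <- as.numeric(energies)
  mu <- as.numeric(mu)
  if (length(energies) != length(mu))
    stop("energies and mu must have the same length")
  if (length(energies) < 16L)
    stop("spectrum too short: need at least 16 points, got ", length(energies))
  if (!all(is.finite(energies)) || !all(is.finite(mu)))
    stop("spectrum contains non-finite values")
  if (any(diff(energies) <= 0))
    stop("energies must be strictly increasing")
  structure(list(energies = energies, mu = mu, label = as.character(label)[1]),
            class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("<xas_spectrum> '%s': %d points, E = [%.1f, %.1f] eV\n",
              x$label, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Circular-dichroism thermal scan
#'
#' Mean residue ellipticity at 222 nm versus temperature, as recorded during
#' a thermal denaturation experiment (nominally one reading every 0.5 degC).
#'
#' @param temperatures Numeric vector, degC, strictly increasing.
#' @param theta222 Ellipticity at 222 nm (deg cm^2 dmol^-1), same length.
#' @param label Free-text label.
#'
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperatures, theta222, label = "") {
  temperatures <- as.numeric(temperatures)
  theta222 <- as.numeric(theta222)
  if (length(temperatures) != length(theta222))
    stop("temperatures and theta222 must have the same length")
  if (!all(is.finite(temperatures)) || !all(is.finite(theta222)))
    stop("melting curve contains non-finite values")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  structure(list(temperatures = temperatures, theta222 = theta222,
                 label = as.character(label)[1]),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> '%s': %d points, T = [%.1f, %.1f] degC\n",
              x$label, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Atom records for a metal site
#'
#' Builds the atom table used by the site-geometry operations: one row per
#' atom with element symbol, orthogonal coordinates in Angstrom, and residue
#' bookkeeping. Coordinates are taken as-is (no symmetry expansion).
#'
#' @param elem Character vector of element symbols.
#' @param x,y,z Numeric coordinate vectors, Angstrom.
#' @param resname Residue names (default `"LIG"`).
#' @param resno Residue numbers (default sequential).
#' @param atom Atom names (default element symbol).
#'
#' @return A `data.frame` of class `atom_records` with columns `elem`, `x`,
#'   `y`, `z`, `resname`, `resno`, `atom`.
#' @export
atom_records <- function(elem, x, y, z, resname = "LIG",
                         resno = seq_along(elem), atom = elem) {
  elem <- as.character(elem)
  if (length(elem) && any(!nzchar(elem)))
    stop("element symbols must be non-empty")
  if (!all(is.finite(c(x, y, z))))
    stop("atom coordinates must be finite")
  df <- data.frame(elem = elem, x = as.numeric(x), y = as.numeric(y),
                   z = as.numeric(z),
                   resname = rep_len(as.character(resname), length(elem)),
                   resno = rep_len(as.integer(resno), length(elem)),
                   atom = rep_len(as.character(atom), length(elem)),
                   stringsAsFactors = FALSE)
  class(df) <- c("atom_records", "data.frame")
  df
}

# numeric-token check used by the XY parser
.is_num <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

#' Read a two-column XY text file
#'
#' Reads whitespace-delimited ASCII data with `#` comment lines, the dialect
#' produced by beamline and spectropolarimeter export tools. The first two
#' numeric columns are used (extra columns ignored); rows are sorted by the
#' abscissa and rows with exactly duplicated abscissae -- as produced by
#' multi-scan merges -- are averaged.
#'
#' @param path Path to the file.
#' @param kind `"spectrum"` (energy/mu) or `"melt"` (temperature/theta).
#'
#' @return An [xas_spectrum] or [melting_curve], per `kind`.
#' @export
read_xy <- function(path, kind = c("spectrum", "melt")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("no data rows in ", path)
  xs <- numeric(0); ys <- numeric(0)
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 2L || !all(.is_num(tok[1:2])))
      stop("non-numeric data on line ", i, " of ", path, ": '",
           trimws(lines[i]), "'")
    xs <- c(xs, as.numeric(tok[1]))
    ys <- c(ys, as.numeric(tok[2]))
  }
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  # average exact duplicates
  if (anyDuplicated(xs)) {
    ys <- as.numeric(tapply(ys, match(xs, unique(xs)), mean))
    xs <- unique(xs)
  }
  if (length(xs) < 16L)
    stop("too few points in ", path, ": need at least 16, got ", length(xs))
  lab <- sub("\\.[^.]*$", "", basename(path))
  if (kind == "spectrum") xas_spectrum(xs, ys, lab) else melting_curve(xs, ys, lab)
}

#' Write a spectrum or melting curve as XY text
#'
#' Inverse of [read_xy]: two whitespace-separated columns with a `#` header.
#' Values are written with enough digits to round-trip.
#'
#' @param x An [xas_spectrum] or [melting_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(x, path) {
  if (inherits(x, "xas_spectrum")) {
    ab <- x$energies; oc <- x$mu
    hdr <- sprintf("# %s | energy_eV mu", x$label)
  } else if (inherits(x, "melting_curve")) {
    ab <- x$temperatures; oc <- x$theta222
    hdr <- sprintf("# %s | temperature_C theta222", x$label)
  } else stop("x must be an xas_spectrum or melting_curve")
  writeLines(c(hdr, sprintf("%.12g %.12g", ab, oc)), path)
  invisible(path)
}

# element from a PDB atom name: first alphabetic character run, stripped of
# digits/primes; greek-position letters after the chemical symbol are dropped
# (e.g. "OE1" -> O, "CA" in an amino acid -> C). Two-letter symbols are only
# kept for common hetero elements so calcium ions ("CA" in ion residues)
# still resolve.
.elem_from_name <- function(name, resname = "") {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nzchar(nm)) return("")
  two <- substr(nm, 1, 2)
  ions <- c("FE", "CO", "NI", "CU", "ZN", "MN", "MG", "CA", "NA", "CL", "SE")
  if (two %in% ions && toupper(resname) %in% c(two, paste0(two, "2"), "ION"))
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  substr(nm, 1, 1)
}

#' Read a metal-site structure from a PDB file
#'
#' Parses ATOM/HETATM records into an [atom_records] table. Element symbols
#' come from PDB columns 77-78 when present, falling back to parsing the
#' atom name (so `OE1` resolves to O even in minimal files). Coordinates are
#' treated as orthogonal Angstrom.
#'
#' @param path Path to a PDB file.
#' @return An [atom_records] data frame, one row per ATOM/HETATM record.
#' @export
read_site_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM/HETATM records in ", path)
  elem <- trimws(as.character(at$elesy))
  elem[is.na(elem)] <- ""
  fix <- !nzchar(elem)
  if (any(fix))
    elem[fix] <- mapply(.elem_from_name, at$elety[fix], at$resid[fix])
  if (any(!nzchar(elem)))
    stop("could not determine element for some atoms in ", path)
  # normalize case: "CO" -> "Co"
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  atom_records(elem, at$x, at$y, at$z,
               resname = at$resid, resno = at$resno, atom = at$elety)
}

#' Write atom records as a minimal PDB file
#'
#' @param atoms An [atom_records] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_pdb <- function(atoms, path) {
  if (!inherits(atoms, "atom_records")) stop("atoms must be atom_records")
  n <- nrow(atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("HETATM", n),
    resno = atoms$resno, resid = atoms$resname,
    eleno = seq_len(n), elety = atoms$atom,
    elesy = atoms$elem, chain = rep("A", n))
  invisible(path)
}

#' Assemble a stability record
#'
#' Joins the per-sample metadata with the melting-temperature and XANES
#' bound-fraction outputs. The allowed Co2+ equivalents reflect the titration
#' design (none, 0.3, 0.8 or 1.6 metal ions per protein molecule).
#'
#' @param name Sample name, e.g. `"wt_90_0.8"`.
#' @param fragment Protein fragment, `"81-210"` or `"90-210"`.
#' @param equivalents One of `"none"`, `"0.3"`, `"0.8"`, `"1.6"`.
#' @param tms Numeric vector of melting temperatures, degC (length 1 or 2).
#' @param delta_tm Tm shift versus the metal-free partner, degC
#'   (`NA` when no partner exists).
#' @param bound_fraction Optional bound-metal fraction from XANES LCF.
#' @return A one-row `data.frame` of class `stability_record`.
#' @export
stability_record <- function(name, fragment, equivalents, tms,
                             delta_tm = NA_real_, bound_fraction = NA_real_) {
  fragment <- match.arg(as.character(fragment), c("81-210", "90-210"))
  equivalents <- match.arg(as.character(equivalents),
                           c("none", "0.3", "0.8", "1.6"))
  tms <- as.numeric(tms)
  if (!length(tms) || length(tms) > 2L || any(!is.finite(tms)))
    stop("tms must contain 1 or 2 finite values")
  df <- data.frame(name = as.character(name), fragment = fragment,
                   equivalents = equivalents, delta_tm = as.numeric(delta_tm),
                   bound_fraction = as.numeric(bound_fraction),
                   stringsAsFactors = FALSE)
  df$tms <- list(sort(tms))
  class(df) <- c("stability_record", "data.frame")
  df
}

# render a Tm vector the way two-step melts are tabulated
.format_tms <- function(tms) {
  if (length(tms) == 1L) sprintf("%.4g", tms)
  else paste(sprintf("Tm%d=%.4g", seq_along(tms), tms), collapse = "; ")
}

#' Write the joint stability report
#'
#' Tab-separated table with one row per sample: name, fragment, metal
#' equivalents, melting temperature(s), Tm shift versus the metal-free
#' partner, and the XANES bound fraction where computed. Two-transition
#' melts are rendered as `Tm1=...; Tm2=...`.
#'
#' @param records A list of [stability_record] rows (or a single record).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (inherits(records, "stability_record")) records <- list(records)
  if (!length(records)) stop("cannot write a report from an empty record list")
  hdr <- paste(c("name", "fragment", "equivalents", "tm_C", "delta_tm_C",
                 "bound_fraction"), collapse = "\t")
  rows <- vapply(records, function(r) {
    paste(c(r$name, r$fragment, r$equivalents, .format_tms(r$tms[[1]]),
            ifelse(is.na(r$delta_tm), "NA", sprintf("%.4g", r$delta_tm)),
            ifelse(is.na(r$bound_fraction), "NA",
                   sprintf("%.4g", r$bound_fraction))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
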