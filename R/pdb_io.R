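#' Read a PDB file into structure3d objects
#'
#' Parses ATOM/HETATM records (via bio3d) into a [structure3d()]. The
#' temperature-factor (B-factor) column is interpreted as the per-atom
#' restraint weight in kcal/mol/A^2: `-1` marks frozen atoms, `0` free
#' atoms, positive values harmonic restraint force constants. Elements are
#' taken from the element column when present and otherwise inferred from
#' the atom name; names that cannot be resolved are an error, never a
#' silent guess.
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record.
#' @param label label attached to the returned structure(s); defaults to
#'   the file name.
#' @return A `structure3d` for single-model files; a list of `structure3d`
#'   (one per MODEL, in file order) for multi-model files.
#' @seealso [write_pdb()], [read_xyz()]
#' @export
read_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("no parsable ATOM/HETATM records in ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("no parsable ATOM/HETATM records in ", path)
  elesy <- trimws(as.character(a$elesy))
  need <- is.na(elesy) | elesy == ""
  if (any(need)) {
    inferred <- tryCatch(
      bio3d::atom2ele(a$elety[need], rescue = FALSE),
      error = function(e) stop("cannot infer element from atom name(s): ",
                               paste(unique(a$elety[need]), collapse = ", "),
                               call. = FALSE))
    elesy[need] <- inferred
  }
  b <- as.numeric(a$b)
  b[is.na(b)] <- 0
  build <- function(xyz_row) {
    structure3d(
      element = elesy,
      coords = matrix(xyz_row, ncol = 3, byrow = TRUE),
      residue_name = a$resid,
      residue_id = a$resno,
      chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
      atom_name = a$elety,
      restraint_weight = b,
      label = label
    )
  }
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    lapply(seq_len(nrow(xyz)), function(i) build(xyz[i, ]))
  } else {
    build(as.numeric(xyz))
  }
}

#' Write structures to a PDB file
#'
#' The restraint weight of every atom is written to the temperature-factor
#' column with two decimals, so a frozen atom appears as `-1.00` and an
#' active pocket atom with the default harmonic weight as `5.00`; files
#' written here round-trip through [read_pdb()]. A list of structures with
#' identical atom tables is written as a multi-model file (MODEL/ENDMDL
#' blocks in list order), the canonical container for a ranked pose set.
#'
#' @param s a `structure3d`, or a list of conformers of one structure.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  if (inherits(s, "structure3d")) s <- list(s)
  stopifnot(length(s) >= 1,
            all(vapply(s, inherits, logical(1), "structure3d")))
  a <- s[[1]]$atoms
  if (nrow(a) == 0) stop("cannot write an empty structure")
  xyz <- do.call(rbind, lapply(s, function(si) {
    if (nrow(si$atoms) != nrow(a))
      stop("all models must have the same atom count")
    as.vector(t(get_coords(si)))
  }))
  if (nrow(xyz) == 1) xyz <- as.vector(xyz)
  ok <- tryCatch({
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                     type = rep("ATOM", nrow(a)),
                     resno = a$residue_id, resid = a$residue_name,
                     eleno = seq_len(nrow(a)), elety = a$atom_name,
                     chain = a$chain_id, o = rep(1, nrow(a)),
                     b = a$restraint_weight,
                     elesy = pdb_element_case(a$element))
    TRUE
  }, error = function(e) stop("cannot write PDB to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

# PDB element column is right-justified, first letter upper case ("Cl").
pdb_element_case <- function(el) {
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

#' Read an XYZ file
#'
#' Plain XYZ: an atom-count line, a comment line, then `element x y z`
#' rows; multiple concatenated frames give a list of structures.
#'
#' @param path path to an XYZ file.
#' @param label label for the returned structure(s).
#' @return a `structure3d`, or a list of them for multi-frame files.
#' @export
read_xyz <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1 || i + 1L + n > length(lines) + 0L)
      stop("malformed XYZ header at line ", i, " of ", path)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    if (any(lengths(rows) < 4))
      stop("malformed XYZ coordinate line in ", path)
    el <- vapply(rows, `[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinates in ", path)
    frames[[length(frames) + 1L]] <- structure3d(el, xyz, label = label)
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames in XYZ file ", path)
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write structures to an XYZ file
#'
#' @param s a `structure3d` or list of conformers (written as concatenated
#'   frames).
#' @param path output file path.
#' @param comment comment line written in each frame header.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(s, path, comment = "") {
  if (inherits(s, "structure3d")) s <- list(s)
  out <- unlist(lapply(s, function(si) {
    xyz <- get_coords(si)
    c(sprintf("%d", nrow(xyz)), comment,
      sprintf("%-2s %14.8f %14.8f %14.8f",
              si$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}
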