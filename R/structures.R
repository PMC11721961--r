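# Structure and trajectory I/O. A "structure frame" is a data frame of
# atoms: name, element, residue number/name, chain, coordinates (Angstrom),
# mass, and a ligand flag (HETATM records that are not water). Multi-model
# PDB parsing is delegated to bio3d; XYZ is parsed directly.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.9,
                   NA. = 22.99, MG = 24.305, K = 39.098, CA. = 40.078,
                   ZN = 65.38, FE = 55.845)

.element_mass <- function(elem) {
  key <- toupper(elem)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  unname(.ELEMENT_MASS[key])
}

# infer the element symbol from a PDB atom name
.elem_from_name <- function(name) {
  s <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(s, 1, 2))
  out <- toupper(substr(s, 1, 1))
  known2 <- c("CL", "BR", "ZN", "MG", "FE")
  out[two %in% known2] <- two[two %in% known2]
  out
}

.new_frame <- function(df) {
  need <- c("atom", "elem", "resno", "resname", "chain", "x", "y", "z",
            "mass", "ligand")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  class(df) <- c("structure_frame", "data.frame")
  df
}

#' Read a multi-model structure file into a list of frames
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model, via bio3d) or `"xyz"`. Guessed from
#'   the file extension when omitted.
#' @return list of `structure_frame` data frames (atoms x fields), one per
#'   model/frame, all with identical atom counts. In PDB input, HETATM
#'   records other than water (HOH/WAT) are flagged as ligand atoms. XYZ
#'   input carries no residue information; each atom becomes its own
#'   residue.
#' @export
read_structures <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") .read_pdb_frames(path) else .read_xyz_frames(path)
}

.read_pdb_frames <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("frame-mismatch or parse error reading PDB: ",
                             conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- .elem_from_name(at$elety)
  } else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- .elem_from_name(at$elety[miss])
  }
  elem <- toupper(trimws(elem))
  water <- toupper(at$resid) %in% c("HOH", "WAT")
  base <- data.frame(atom = at$elety, elem = elem, resno = at$resno,
                     resname = at$resid,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     mass = .element_mass(elem),
                     ligand = at$type == "HETATM" & !water,
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    .new_frame(cbind(base[, c("atom", "elem", "resno", "resname", "chain")],
                     data.frame(x = m[, 1], y = m[, 2], z = m[, 3]),
                     base[, c("mass", "ligand"), drop = FALSE]))
  })
}

.read_xyz_frames <- function(path) {
  raw <- readLines(path)
  frames <- list()
  i <- 1L
  n_ref <- NA_integer_
  while (i <= length(raw)) {
    if (!nzchar(trimws(raw[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(raw[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("parse error at line %d: expected atom count", i))
    if (is.na(n_ref)) n_ref <- n
    if (n != n_ref)
      stop("frame-mismatch: models have different atom counts")
    if (i + 1L + n > length(raw))
      stop(sprintf("parse error at line %d: truncated frame", i))
    block <- strsplit(trimws(raw[(i + 2L):(i + 1L + n)]), "\\s+")
    if (any(lengths(block) < 4))
      stop(sprintf("parse error at line %d: need element + 3 coordinates",
                   i + 1L + which(lengths(block) < 4)[1]))
    elem <- toupper(vapply(block, `[`, "", 1))
    co <- matrix(as.numeric(vapply(block, function(b) b[2:4], character(3))),
                 ncol = 3, byrow = TRUE)
    if (any(!is.finite(co)))
      stop(sprintf("parse error near line %d: non-numeric coordinate", i + 2L))
    frames[[length(frames) + 1L]] <- .new_frame(data.frame(
      atom = elem, elem = elem, resno = seq_len(n), resname = "UNK",
      chain = "A", x = co[, 1], y = co[, 2], z = co[, 3],
      mass = .element_mass(elem), ligand = FALSE, stringsAsFactors = FALSE))
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("parse error: no frames in XYZ file")
  frames
}

#' Write frames as a multi-model PDB file
#'
#' Deterministic fixed-width writer (byte-identical output for identical
#' input), sufficient for the toy structures this package generates.
#'
#' @param frames list of `structure_frame` objects with identical atoms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    rec <- ifelse(fr$ligand | toupper(fr$resname) %in% c("HOH", "WAT"),
                  "HETATM", "ATOM  ")
    lines <- sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     rec, seq_len(nrow(fr)), substr(fr$atom, 1, 4),
                     substr(fr$resname, 1, 3), substr(fr$chain, 1, 1),
                     fr$resno, fr$x, fr$y, fr$z, substr(fr$elem, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Coordinate matrix of a frame (optionally a selection)
#'
#' @param frame a `structure_frame`.
#' @param selection integer/logical index into the atoms, or NULL for all.
#' @return n x 3 coordinate matrix, Angstrom.
#' @export
coords <- function(frame, selection = NULL) {
  if (!is.null(selection)) frame <- frame[selection, , drop = FALSE]
  if (nrow(frame) == 0) stop("selection error: empty selection")
  out <- as.matrix(frame[, c("x", "y", "z")])
  if (anyNA(out)) stop("selection error: selection outside the frame")
  out
}

#' Select atoms of a frame
#'
#' @param frame a `structure_frame`.
#' @param resno residue numbers to keep (NULL = all).
#' @param heavy keep only non-hydrogen atoms.
#' @param ligand NULL = all atoms; TRUE / FALSE filter on the ligand flag.
#' @return integer atom indices.
#' @export
select_atoms <- function(frame, resno = NULL, heavy = FALSE, ligand = NULL) {
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(resno)) keep <- keep & frame$resno %in% resno
  if (heavy) keep <- keep & frame$elem != "H"
  if (!is.null(ligand)) keep <- keep & frame$ligand == ligand
  which(keep)
}
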