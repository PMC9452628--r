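## Structure I/O. Parsing and writing of PDB records is delegated to bio3d;
## this layer validates the file, normalises the atom table to the package's
## column contract and assigns the internal 0-based residue indexing.

.ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "K")

## Infer an element symbol from a PDB atom name (used when the element column
## is absent): strip leading digits, take the first letter (CA -> C, OD1 -> O,
## 1HB -> H).
.inferElement <- function(name) {
  nm <- toupper(sub("^[0-9']+", "", trimws(name)))
  first <- substr(nm, 1L, 1L)
  ifelse(first %in% .ELEMENTS, first, substr(nm, 1L, 1L))
}

## Validate raw ATOM/HETATM records; stop with the 1-based line number of the
## first malformed record.
.checkAtomRecords <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (!length(idx)) stop("no ATOM records found in file")
  for (k in idx) {
    ln <- lines[k]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record at line ", k, ": record too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record at line ", k, ": unparsable coordinates")
  }
  invisible(idx)
}

## bio3d atom table -> cnaflex atom table (+ internal resid indexing)
.normaliseAtoms <- function(at) {
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  ele <- at$elesy
  bad <- is.na(ele) | !nzchar(trimws(ele))
  ele[bad] <- .inferElement(at$elety[bad])
  ele <- toupper(trimws(ele))
  out <- data.frame(serial = at$eleno,
                    name = trimws(at$elety),
                    element = ele,
                    resno = at$resno,
                    resname = trimws(at$resid),
                    chain = chain,
                    stringsAsFactors = FALSE)
  ## 0-based sequential residue index within each chain, order of appearance
  out$resid <- NA_integer_
  for (ch in unique(out$chain)) {
    sel <- out$chain == ch
    key <- paste(out$resno[sel], at$insert[sel])
    out$resid[sel] <- match(key, unique(key)) - 1L
  }
  out$heavy <- out$element != "H"
  out[, c(.ATOM_COLS, "resno")]
}

#' Read a single-model PDB file
#'
#' @param path path to a PDB file containing exactly one model.
#' @return a \linkS4class{StructureSnapshot}; atom order is preserved and the
#'   element is inferred from the atom name where the element column is absent.
#' @export
readPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .checkAtomRecords(lines)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .normaliseAtoms(pdb$atom)
  xyz <- matrix(as.numeric(pdb$xyz), ncol = 3L, byrow = TRUE)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  new("StructureSnapshot", atoms = atoms, coords = xyz)
}

#' Read a multi-model PDB file as an ensemble
#'
#' One snapshot per MODEL block; the topology (atom count and ordering) must be
#' identical across models. A file without MODEL records yields an ensemble of
#' length one.
#'
#' @param path path to a (multi-model) PDB file.
#' @param construct construct label stored in the ensemble metadata.
#' @param runId run identifier stored in the ensemble metadata.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
readEnsemble <- function(path, construct = "unknown", runId = "run1") {
  lines <- readLines(path, warn = FALSE)
  .checkAtomRecords(lines)
  ## per-model atom counts must agree
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) != 1L)
      stop("topology mismatch: models contain differing atom counts (",
           paste(unique(counts), collapse = ", "), ")")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- .normaliseAtoms(pdb$atom)
  xyzmat <- pdb$xyz                      # n_models x (3*n_atoms)
  if (is.null(dim(xyzmat))) xyzmat <- matrix(xyzmat, nrow = 1L)
  nm <- nrow(xyzmat); na <- nrow(atoms)
  arr <- array(NA_real_, dim = c(na, 3L, nm),
               dimnames = list(NULL, c("x", "y", "z"), NULL))
  for (m in seq_len(nm))
    arr[, , m] <- matrix(xyzmat[m, ], ncol = 3L, byrow = TRUE)
  new("StructureEnsemble", atoms = atoms, coords = arr,
      construct = construct, runId = runId)
}

.formatAtomLine <- function(serial, name, resname, chain, resno, xyz, element) {
  ## PDB fixed-width ATOM record; atom names of <4 chars start in column 14
  nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial %% 100000L, nm, resname, chain, resno %% 10000L,
          xyz[1], xyz[2], xyz[3], element)
}

.writeModelLines <- function(atoms, xyz) {
  vapply(seq_len(nrow(atoms)), function(i)
    .formatAtomLine(atoms$serial[i], atoms$name[i], atoms$resname[i],
                    atoms$chain[i], atoms$resno[i], xyz[i, ],
                    atoms$element[i]),
    character(1))
}

#' Write a snapshot to a single-model PDB file
#' @param snapshot a \linkS4class{StructureSnapshot}
#' @param path output path
#' @export
writePDB <- function(snapshot, path) {
  writeLines(c(.writeModelLines(snapshot@atoms, snapshot@coords), "END"), path)
  invisible(path)
}

#' Write an ensemble to a multi-model PDB file
#' @param ensemble a \linkS4class{StructureEnsemble}
#' @param path output path
#' @export
writeEnsemble <- function(ensemble, path) {
  out <- character(0)
  for (m in seq_len(nFrames(ensemble))) {
    out <- c(out, sprintf("MODEL     %4d", m),
             .writeModelLines(ensemble@atoms, ensemble@coords[, , m]),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

## Internal constructor used by generators and tests: build a snapshot from
## parallel vectors. resno defaults to resid + 1 (file numbering is 1-based).
.makeSnapshot <- function(name, element, resname, chain, resid, coords,
                          resno = resid + 1L) {
  n <- length(name)
  atoms <- data.frame(serial = seq_len(n), name = name, element = element,
                      resid = as.integer(resid), resname = resname,
                      chain = chain, heavy = element != "H",
                      resno = as.integer(resno), stringsAsFactors = FALSE)
  colnames(coords) <- c("x", "y", "z")
  new("StructureSnapshot", atoms = atoms, coords = coords)
}

## Ensemble from a shared snapshot topology plus a coordinate array
.makeEnsemble <- function(snapshot, coordsArray, construct = "synthetic",
                          runId = "run1") {
  new("StructureEnsemble", atoms = snapshot@atoms, coords = coordsArray,
      construct = construct, runId = runId)
}
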