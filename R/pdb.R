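#' Read the alpha-carbon trace of a PDB file
#'
#' Parses `ATOM` records naming a `CA` atom and returns one ordered coordinate
#' set per chain. Only the first `MODEL` of a multi-model file is used,
#' `HETATM` records (waters, calcium ions, ligands) are ignored, alternate
#' locations are resolved to the highest-occupancy copy (ties go to altloc
#' `"A"`), insertion-coded residues are kept in file order, and residues
#' without a CA atom are skipped.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param source_id Optional structure identifier stored on the result;
#'   defaults to the file name when `pdb` is a path.
#' @return An object of class `"ca_structure"`: a list with elements
#'   `chains` (named list; each chain has `resid`, a character vector of
#'   residue identifiers including insertion codes, and `xyz`, an n x 3
#'   coordinate matrix in Angstrom) and `source_id`.
#' @examples
#' pdb <- write_ca_pdb(list(A = make_helix_trace(12)), tempfile(fileext = ".pdb"))
#' str <- read_ca_trace(pdb)
#' nrow(str$chains[[1]]$xyz)
#' @seealso [decompose_chain()], [build_protein_tensor()], [write_ca_pdb()]
#' @export
read_ca_trace <- function(pdb, source_id = NULL) {
  stopifnot(is.character(pdb), length(pdb) >= 1)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(source_id)) source_id <- basename(pdb)
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  }
  if (is.null(source_id)) source_id <- "structure"

  rec <- substr(lines, 1, 6)
  in_model <- 0L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      in_model <- in_model + 1L
      if (in_model > 1L) break
    } else if (startsWith(r, "ENDMDL")) {
      break
    } else if (r == "ATOM  ") {
      keep[i] <- TRUE
    }
  }
  idx <- which(keep)
  if (length(idx) == 0) stop("no CA atoms found: input has no ATOM records")

  fx <- function(l, a, b) substr(l, a, b)
  al <- lines[idx]
  name <- trimws(fx(al, 13, 16))
  ca <- name == "CA"
  idx <- idx[ca]; al <- al[ca]
  if (length(idx) == 0) stop("no CA atoms found among ATOM records")

  bad <- nchar(al) < 54
  if (any(bad)) {
    stop(sprintf("unreadable ATOM record at line %d: too short", idx[which(bad)[1]]))
  }
  num <- function(a, b) suppressWarnings(as.numeric(fx(al, a, b)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  resseq <- suppressWarnings(as.integer(fx(al, 23, 26)))
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resseq)
  if (any(bad)) {
    stop(sprintf("unreadable ATOM record at line %d: non-numeric field", idx[which(bad)[1]]))
  }
  occ <- num(55, 60); occ[is.na(occ)] <- 1
  altloc <- fx(al, 17, 17)
  chain <- fx(al, 22, 22)
  icode <- trimws(fx(al, 27, 27))
  key <- paste(chain, resseq, icode, sep = "|")

  # resolve alternate locations: highest occupancy, ties -> altloc 'A',
  # then file order
  ord <- order(match(key, unique(key)), -occ, altloc != "A", seq_along(key))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])

  chains <- list()
  for (i in sel) {
    ch <- chain[i]
    if (is.null(chains[[ch]])) {
      chains[[ch]] <- list(resid = character(), xyz = NULL)
    }
    chains[[ch]]$resid <- c(chains[[ch]]$resid,
                            paste0(resseq[i], ifelse(icode[i] == "", "", icode[i])))
    chains[[ch]]$xyz <- rbind(chains[[ch]]$xyz, c(x[i], y[i], z[i]))
  }
  for (ch in names(chains)) {
    dimnames(chains[[ch]]$xyz) <- list(NULL, c("x", "y", "z"))
    if (anyDuplicated(chains[[ch]]$resid)) {
      stop(sprintf("duplicate residue identifier in chain %s", ch))
    }
  }
  structure(list(chains = chains, source_id = source_id), class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("CA-trace structure:", x$source_id, "\n")
  for (ch in names(x$chains)) {
    cat(sprintf("  chain %s: %d residues\n", ch, nrow(x$chains[[ch]]$xyz)))
  }
  invisible(x)
}

# one fixed-width CA ATOM record; b is the B-factor field
.ca_atom_line <- function(serial, chain, resno, xyz, b = 0, resname = "ALA") {
  sprintf("ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, resname, chain, resno, xyz[1], xyz[2], xyz[3], 1, b)
}

#' Write a CA-only PDB file
#'
#' Emits one `ATOM`/`CA` record per residue with `TER` records separating
#' chains. Coordinates must fit the fixed 8.3 PDB field
#' (-999.999 to 9999.999 Angstrom). [read_ca_trace()] round-trips the
#' coordinates to within the 0.001 Angstrom precision of the format.
#'
#' @param coords A `"ca_structure"`, or a list of n x 3 coordinate matrices
#'   (one per chain; names become chain IDs, defaulting to A, B, ...).
#' @param path Output file path.
#' @param b Optional per-residue B-factor values: a list of numeric vectors
#'   parallel to `coords` (or a single vector for one chain). Default 0.
#' @return `path`, invisibly.
#' @examples
#' f <- write_ca_pdb(list(make_helix_trace(10)), tempfile(fileext = ".pdb"))
#' readLines(f)[1]
#' @export
write_ca_pdb <- function(coords, path, b = NULL) {
  if (inherits(coords, "ca_structure")) {
    coords <- lapply(coords$chains, `[[`, "xyz")
  }
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(is.list(coords), length(coords) >= 1)
  if (is.null(names(coords)) || any(names(coords) == "")) {
    names(coords) <- LETTERS[seq_along(coords)]
  }
  if (!is.null(b) && is.numeric(b)) b <- list(b)
  lines <- character()
  serial <- 0L
  for (ci in seq_along(coords)) {
    xyz <- as.matrix(coords[[ci]])
    stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
    if (any(xyz >= 1e4 - 5e-4) || any(xyz <= -1e3 + 5e-4)) {
      stop("coordinate overflows the fixed-width PDB field (must be in (-1000, 10000) Angstrom)")
    }
    bb <- if (is.null(b)) rep(0, nrow(xyz)) else b[[ci]]
    stopifnot(length(bb) == nrow(xyz))
    for (i in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, .ca_atom_line(serial, names(coords)[ci], i, xyz[i, ], bb[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      ALA %s%4d", serial,
                              names(coords)[ci], nrow(xyz)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
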