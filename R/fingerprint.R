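# --- circular-substructure (ECFP-style) fingerprints -------------------------
#
# SMILES handling (parsing, canonicalization, explicit hydrogens) is delegated
# to OpenBabel through ChemmineOB/ChemmineR; the iterative neighborhood hashing
# is implemented here. All hash arithmetic stays below 2^53 so it is exact in
# doubles.

.ATOMIC_NUMBER <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                    F = 9, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
                    Cl = 17, K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27,
                    Ni = 28, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
                    I = 53)

# deterministic integer hash of an integer vector, exact in double arithmetic
.hash_ints <- function(v) {
  h <- 2166136261 %% 2147483647
  for (x in v) {
    h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  }
  h
}

.smiles_syntax_ok <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || nchar(trimws(s)) == 0) {
    return("empty SMILES string")
  }
  s <- trimws(s)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]", s)) {
    return("illegal character in SMILES")
  }
  ch <- strsplit(s, "")[[1]]
  if (sum(ch == "(") != sum(ch == ")")) return("unbalanced parentheses")
  if (sum(ch == "[") != sum(ch == "]")) return("unbalanced brackets")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0)) return("unbalanced parentheses")
  # ring-closure digits outside brackets must pair up
  inbr <- cumsum((ch == "[") - c(0, head(ch == "]", -1))) > 0
  ring <- ch[grepl("[0-9]", ch) & !inbr]
  if (length(ring) %% 2 != 0) return("unpaired ring-closure digit")
  NULL
}

#' Canonicalize a SMILES string
#'
#' Validates basic SMILES syntax and returns the OpenBabel canonical form, so
#' that any valid SMILES of the same molecule maps to the same string.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @export
canonicalize_smiles <- function(smiles) {
  err <- .smiles_syntax_ok(smiles)
  if (!is.null(err)) stop(sprintf("invalid ligand '%s': %s", smiles, err))
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = trimws(smiles)),
    error = function(e) "")
  out <- trimws(out)
  if (nchar(out) == 0) stop(sprintf("invalid ligand '%s': not parseable", smiles))
  out
}

# molecule graph with explicit hydrogens folded into per-heavy-atom counts
.parse_molecule <- function(smiles_can) {
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", source = smiles_can,
                                       options = data.frame(names = c("h", "gen2D"),
                                                            args = c("", "")))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n_atoms <- length(elements)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  charge <- numeric(n_atoms)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", l)), "[[:space:]]+")[[1]])
    if (length(f) >= 3) {
      for (j in seq_len(f[1])) charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  heavy <- which(elements != "H")
  hmap <- match(seq_len(n_atoms), heavy)  # heavy index or NA
  nH <- integer(length(heavy))
  adj <- vector("list", length(heavy))    # list of (neighbor heavy idx, order)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]; o <- bonds[r, 3]
    ha <- hmap[a]; hb <- hmap[b]
    if (!is.na(ha) && is.na(hb)) nH[ha] <- nH[ha] + 1L
    if (is.na(ha) && !is.na(hb)) nH[hb] <- nH[hb] + 1L
    if (!is.na(ha) && !is.na(hb)) {
      adj[[ha]] <- rbind(adj[[ha]], c(hb, o))
      adj[[hb]] <- rbind(adj[[hb]], c(ha, o))
    }
  }
  # ring membership: bond is in a ring iff its endpoints stay connected
  # without it
  in_ring <- logical(length(heavy))
  hb_idx <- which(!is.na(hmap[bonds[, 1]]) & !is.na(hmap[bonds[, 2]]))
  for (r in hb_idx) {
    a <- hmap[bonds[r, 1]]; b <- hmap[bonds[r, 2]]
    seen <- logical(length(heavy)); seen[a] <- TRUE; queue <- a
    while (length(queue) && !seen[b]) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in adj[[v]][, 1]) {
        if ((v == a && nb == b) || (v == b && nb == a)) {
          if (sum(adj[[v]][, 1] == nb) < 2) next  # skip the bond itself
        }
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    if (seen[b]) in_ring[a] <- in_ring[b] <- TRUE
  }
  list(elements = elements[heavy], nH = nH, charge = charge[heavy],
       adj = adj, in_ring = in_ring, n_heavy = length(heavy))
}

.atomic_number <- function(el) {
  z <- .ATOMIC_NUMBER[el]
  ifelse(is.na(z), 200 + vapply(el, function(e) .hash_ints(utf8ToInt(e)) %% 50, 0), z)
}

#' Circular-substructure fingerprint of a ligand
#'
#' Hashes atom-centered circular environments of radius 0..`radius` (the
#' extended-connectivity scheme: iterative neighborhood identifier updates
#' with duplicate-environment removal) into a fixed-length binary vector.
#' The fingerprint depends only on the molecular graph: any valid SMILES of
#' the same molecule yields identical bits, and growing the radius only adds
#' bits.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (default 2, the ECFP4-equivalent).
#' @param n_bits Folded fingerprint length (default 1024).
#' @return An object of class `"ligand_fp"`: list with `bits` (logical
#'   vector of length `n_bits`), `smiles_canonical`, `radius`, `n_bits` and
#'   `n_features` (distinct environments before folding).
#' @examples
#' fp <- ecfp_fingerprint("CCO")
#' sum(fp$bits)
#' tanimoto(fp, ecfp_fingerprint("OCC"))  # 1: same molecule
#' @export
ecfp_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(radius >= 0, n_bits >= 1)
  can <- canonicalize_smiles(smiles)
  mol <- .parse_molecule(can)
  if (mol$n_heavy == 0) stop(sprintf("invalid ligand '%s': no heavy atoms", smiles))

  ids <- vapply(seq_len(mol$n_heavy), function(a) {
    .hash_ints(c(.atomic_number(mol$elements[a]),
                 if (is.null(mol$adj[[a]])) 0L else nrow(mol$adj[[a]]),
                 mol$nH[a], mol$charge[a], as.integer(mol$in_ring[a])))
  }, numeric(1))

  features <- ids
  seen_sets <- vapply(seq_len(mol$n_heavy), function(a) paste(a), "")
  cover <- as.list(seq_len(mol$n_heavy))  # atoms within current radius
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      new_cover <- cover
      for (a in seq_len(mol$n_heavy)) {
        nb <- mol$adj[[a]]
        if (is.null(nb)) {
          new_ids[a] <- .hash_ints(c(r, ids[a]))
          next
        }
        tup <- cbind(nb[, 2], ids[nb[, 1]])
        tup <- tup[order(tup[, 1], tup[, 2]), , drop = FALSE]
        new_ids[a] <- .hash_ints(c(r, ids[a], as.vector(t(tup))))
        new_cover[[a]] <- sort(unique(c(cover[[a]], unlist(cover[nb[, 1]]))))
      }
      ids <- new_ids
      cover <- new_cover
      for (a in seq_len(mol$n_heavy)) {
        key <- paste(cover[[a]], collapse = ",")
        if (!(key %in% seen_sets)) {   # duplicate-environment removal
          features <- c(features, ids[a])
          seen_sets <- c(seen_sets, key)
        }
      }
    }
  }
  bits <- logical(n_bits)
  bits[unique(features %% n_bits) + 1] <- TRUE
  structure(list(bits = bits, smiles_canonical = can, radius = as.integer(radius),
                 n_bits = as.integer(n_bits),
                 n_features = length(unique(features))),
            class = "ligand_fp")
}

#' @export
print.ligand_fp <- function(x, ...) {
  cat(sprintf("ligand fingerprint: %s | %d/%d bits set (radius %d, %d environments)\n",
              x$smiles_canonical, sum(x$bits), x$n_bits, x$radius, x$n_features))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a & b| / |a | b|`. Two all-zero fingerprints are defined as identical
#' (similarity 1, reported with a message).
#'
#' @param a,b `"ligand_fp"` objects or logical/binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  va <- if (inherits(a, "ligand_fp")) a$bits else as.logical(a)
  vb <- if (inherits(b, "ligand_fp")) b$bits else as.logical(b)
  if (length(va) != length(vb)) {
    stop("fingerprint lengths differ: ", length(va), " vs ", length(vb))
  }
  un <- sum(va | vb)
  if (un == 0) {
    message("both fingerprints empty; Tanimoto defined as 1 by convention")
    return(1)
  }
  sum(va & vb) / un
}

#' Fingerprint a set of SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @inheritParams ecfp_fingerprint
#' @return A logical matrix, one row per ligand, `n_bits` columns; row names
#'   are the input SMILES.
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, n_bits = 1024L) {
  m <- t(vapply(smiles,
                function(s) ecfp_fingerprint(s, radius, n_bits)$bits,
                logical(n_bits)))
  rownames(m) <- smiles
  m
}
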