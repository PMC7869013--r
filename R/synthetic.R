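# --- synthetic fixtures with known ground truth ------------------------------

#' Ideal helical CA trace with closed-form curvature/torsion
#'
#' Points `(radius * cos(theta_i), radius * sin(theta_i), i * rise)` with
#' `theta_i = i * twist`. For a circular helix of radius `a` and axial slope
#' `b = rise / twist` (in Angstrom per radian) the exact curve geometry is
#' `kappa = a / (a^2 + b^2)` and `tau = b / (a^2 + b^2)`; both are attached
#' as attributes `kappa_oracle` / `tau_oracle` for use as test oracles. The
#' defaults are ideal alpha-helix parameters (radius 2.3 A, rise 1.5 A,
#' twist 100 degrees per residue, consecutive CA-CA distance ~3.8 A).
#'
#' @param n Number of residues (>= 4).
#' @param radius Helix radius in Angstrom.
#' @param rise Rise per residue in Angstrom.
#' @param twist Twist per residue in degrees; 0 gives a straight line
#'   (oracles 0).
#' @return n x 3 coordinate matrix with oracle attributes.
#' @examples
#' h <- make_helix_trace(50)
#' attr(h, "kappa_oracle")  # 0.3815...
#' @export
make_helix_trace <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  if (n < 4) stop("a helix trace needs n >= 4 residues (cubic-spline minimum)")
  stopifnot(radius > 0)
  tw <- twist * pi / 180
  i <- seq_len(n) - 1
  xyz <- cbind(x = radius * cos(i * tw), y = radius * sin(i * tw), z = i * rise)
  if (tw == 0) {
    k0 <- 0; t0 <- 0
  } else {
    b <- rise / tw
    k0 <- radius / (radius^2 + b^2)
    t0 <- b / (radius^2 + b^2)
  }
  attr(xyz, "kappa_oracle") <- k0
  attr(xyz, "tau_oracle") <- t0
  xyz
}

#' Smoothed correlated-random-walk coil trace
#'
#' Background "random coil" backbone: a direction-correlated random walk
#' whose positions are lightly smoothed (1-2-1 moving average) and re-scaled
#' to a fixed CA-CA step, avoiding the sharp kinks and self-coincidences a
#' raw walk produces.
#'
#' @param n Number of residues (>= 4).
#' @param step CA-CA distance in Angstrom (default 3.8).
#' @param persistence Direction correlation in `[0, 1)`; higher is straighter.
#' @return n x 3 coordinate matrix.
#' @export
make_coil_trace <- function(n, step = 3.8, persistence = 0.5) {
  stopifnot(n >= 4, step > 0, persistence >= 0, persistence < 1)
  unit <- function(v) v / sqrt(sum(v^2))
  dirs <- matrix(0, n - 1, 3)
  dirs[1, ] <- unit(rnorm(3))
  for (i in seq_len(n - 2)) {
    dirs[i + 1, ] <- unit(persistence * dirs[i, ] + (1 - persistence) * unit(rnorm(3)))
  }
  pos <- rbind(0, apply(dirs * step, 2, cumsum))
  if (n > 2) {  # 1-2-1 smoothing of interior positions
    sm <- pos
    sm[2:(n - 1), ] <- (pos[1:(n - 2), ] + 2 * pos[2:(n - 1), ] + pos[3:n, ]) / 4
    pos <- sm
  }
  d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  d <- d / sqrt(rowSums(d^2)) * step  # re-scale steps after smoothing
  out <- rbind(0, apply(d, 2, cumsum))
  colnames(out) <- c("x", "y", "z")
  out
}

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# coil backbone with an ideal-helix segment spliced in (step vectors of the
# rotated helix template replace the coil steps, keeping the trace connected)
.planted_trace <- function(n, motif_start, motif_length) {
  coil <- make_coil_trace(n)
  if (is.na(motif_start)) return(coil)
  helix <- make_helix_trace(max(motif_length, 4))
  hstep <- (helix[-1, , drop = FALSE] - helix[-nrow(helix), , drop = FALSE])
  hstep <- hstep[seq_len(motif_length - 1), , drop = FALSE] %*% t(.random_rotation())
  steps <- coil[-1, , drop = FALSE] - coil[-n, , drop = FALSE]
  steps[motif_start - 1 + seq_len(motif_length - 1), ] <- hstep
  out <- rbind(0, apply(steps, 2, cumsum))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Planted-rule synthetic protein-ligand dataset
#'
#' Generates a desk-scale benchmark with fully known ground truth. Proteins
#' are single-chain coil backbones; a random `motif_fraction` of them carry
#' an ideal alpha-helix motif of `motif_length` residues spliced in at a
#' random position. Ligands are random sparse bit vectors; a random
#' `key_fraction` of them carry one designated key bit. The binding label of
#' a (protein, ligand) pair is the conjunction "motif present AND key bit
#' set", then flipped with probability `noise`. The conjunction means
#' neither a protein-only nor a ligand-only model can exceed chance-level
#' ranking by much, so recovering the labels requires the joint embedding;
#' the manifest records the motif location per protein for attribution
#' (Grad-CAM localization) tests.
#'
#' @param n_proteins,n_ligands Library sizes (default 200 x 50).
#' @param residues_per_protein Chain length (default 100).
#' @param motif_length Helix motif length in residues (default 30).
#' @param motif_fraction,key_fraction Fraction of proteins with the motif /
#'   ligands with the key bit (default 0.5 each; the pre-noise positive
#'   fraction is their product).
#' @param n_bits Fingerprint length (default 1024).
#' @param bit_density Background probability of each fingerprint bit.
#' @param key_bit Index of the planted bit (default: drawn at random).
#' @param noise Label flip probability epsilon in `[0, 0.5)`.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return List with `tensors` (named list of `"protein_tensor"`),
#'   `fingerprints` (0/1 matrix, one named row per ligand), `pairs` (data
#'   frame `protein_id`, `ligand_id`, `label` over the full cross),
#'   `traces` (named list of coordinate matrices) and `manifest` (ground
#'   truth: per-protein motif location, per-ligand key status, `key_bit`,
#'   `noise`).
#' @export
make_synthetic_dataset <- function(n_proteins = 200L, n_ligands = 50L,
                                   residues_per_protein = 100L,
                                   motif_length = 30L,
                                   motif_fraction = 0.5, key_fraction = 0.5,
                                   n_bits = 1024L, bit_density = 0.05,
                                   key_bit = NULL, noise = 0.02, seed = 0L) {
  stopifnot(noise >= 0, noise < 0.5,
            motif_length >= 4, residues_per_protein >= motif_length + 10)
  n_motif <- round(motif_fraction * n_proteins)
  n_key <- round(key_fraction * n_ligands)
  if (n_motif < 1 || n_motif > n_proteins - 1 || n_key < 1 || n_key > n_ligands - 1) {
    stop("infeasible positive fraction: need at least one protein/ligand on each side of the rule")
  }
  set.seed(seed)
  if (is.null(key_bit)) key_bit <- sample.int(n_bits, 1)

  protein_id <- sprintf("prot%03d", seq_len(n_proteins))
  has_motif <- seq_len(n_proteins) %in% sample.int(n_proteins, n_motif)
  motif_start <- ifelse(has_motif,
                        sample(5:(residues_per_protein - motif_length - 4),
                               n_proteins, replace = TRUE), NA)
  traces <- vector("list", n_proteins)
  tensors <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    traces[[i]] <- .planted_trace(residues_per_protein, motif_start[i], motif_length)
    tensors[[i]] <- build_protein_tensor(decompose_chain(traces[[i]]))
  }
  names(traces) <- names(tensors) <- protein_id

  ligand_id <- sprintf("lig%03d", seq_len(n_ligands))
  has_key <- seq_len(n_ligands) %in% sample.int(n_ligands, n_key)
  fp <- matrix(runif(n_ligands * n_bits) < bit_density, n_ligands, n_bits)
  fp[, key_bit] <- has_key
  storage.mode(fp) <- "integer"
  rownames(fp) <- ligand_id

  pairs <- expand.grid(protein_id = protein_id, ligand_id = ligand_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rule <- has_motif[match(pairs$protein_id, protein_id)] &
    has_key[match(pairs$ligand_id, ligand_id)]
  flip <- runif(nrow(pairs)) < noise
  pairs$label <- as.integer(xor(rule, flip))

  list(tensors = tensors, fingerprints = fp, pairs = pairs, traces = traces,
       manifest = list(
         proteins = data.frame(protein_id = protein_id, has_motif = has_motif,
                               motif_start = motif_start,
                               motif_end = ifelse(has_motif,
                                                  motif_start + motif_length - 1L, NA)),
         ligands = data.frame(ligand_id = ligand_id, has_key = has_key),
         key_bit = key_bit, noise = noise, rule = rule, seed = seed))
}
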