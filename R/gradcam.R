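# --- Grad-CAM residue attribution --------------------------------------------

#' Grad-CAM residue heatmap for a protein-ligand pair
#'
#' Gradient-weighted class-activation mapping on the final convolution layer
#' of each branch: channel weights `alpha[k] = (1/Z) * sum_i d(score)/dX[k, i]`
#' over the Z valid positions, heatmap `S_i = sum_k alpha[k] * X[k, i]`,
#' rectified (negative contributions clipped to 0) and normalized so the
#' maximum is 1. Branch maps are aggregated by elementwise mean and
#' renormalized. Because every convolution is 'same'-padded, latent position
#' i is residue i, so `S` aligns one-to-one with the valid residues of the
#' tensor (chains concatenated in slot order).
#'
#' @inheritParams ssnet_score
#' @param negate_gradient Use the negated gradient in `alpha` (the sign variant
#'   sometimes printed for this method); default `FALSE`, the standard
#'   positive-gradient convention under which binding regions score highest.
#' @param rectify Clip negative raw heatmap values to zero before
#'   normalization (default `TRUE`).
#' @return An object of class `"residue_heatmap"`: list with `S` (length =
#'   number of valid residues, max 1 unless identically 0), `per_branch`
#'   (list of normalized per-branch maps), `alpha` (per-branch channel
#'   weights), `chain_lengths`, and `score` (the forward-pass prediction).
#' @seealso [write_heatmap_pdb()], [proximity_hit_rate()]
#' @export
residue_heatmap <- function(tensor, fp, weights, config, negate_gradient = FALSE,
                            rectify = TRUE) {
  stopifnot(inherits(tensor, "protein_tensor"))
  bits <- if (inherits(fp, "ligand_fp")) as.numeric(fp$bits) else as.numeric(fp)
  segs <- .tensor_segments(tensor)
  cache <- .forward(segs, bits, weights, config, keep = TRUE)
  # d(score)/d(logit) seeds the backward pass so dX is d(score)/dX
  bw <- .backward(cache, weights, config,
                  dout = cache$score * (1 - cache$score), want_dX = TRUE)
  nb <- length(config$window_sizes)
  maps <- vector("list", nb)
  alphas <- vector("list", nb)
  for (bi in seq_len(nb)) {
    X <- cache$branches[[bi]]$X
    Z <- ncol(X)
    alpha <- rowSums(bw$dX[[bi]]) / Z
    if (negate_gradient) alpha <- -alpha
    raw <- as.vector(alpha %*% X)
    if (rectify) raw <- pmax(raw, 0)
    mx <- max(abs(raw))
    maps[[bi]] <- if (mx > 0) raw / mx else raw
    alphas[[bi]] <- alpha
  }
  S <- Reduce(`+`, maps) / nb
  mx <- max(S)
  if (mx > 0) {
    S <- S / mx
  } else if (all(vapply(bw$dX, function(m) all(m == 0), TRUE))) {
    warning("all-zero Grad-CAM gradients; returning an all-zero heatmap")
  }
  structure(list(S = S, per_branch = maps, alpha = alphas,
                 chain_lengths = tensor$chain_lengths,
                 score = cache$score),
            class = "residue_heatmap")
}

#' @export
print.residue_heatmap <- function(x, ...) {
  cat(sprintf("residue heatmap: %d residues, score %.3f, %d residues with S > 0.5\n",
              length(x$S), x$score, sum(x$S > 0.5)))
  invisible(x)
}

#' Per-residue heatmap table
#'
#' @param heatmap A `"residue_heatmap"`.
#' @return Data frame with `chain` (index), `residue` (position within
#'   chain) and `S`.
#' @export
heatmap_table <- function(heatmap) {
  stopifnot(inherits(heatmap, "residue_heatmap"))
  data.frame(chain = rep(seq_along(heatmap$chain_lengths), heatmap$chain_lengths),
             residue = unlist(lapply(heatmap$chain_lengths, seq_len)),
             S = heatmap$S)
}

#' Write a heatmap-colored CA PDB
#'
#' Writes the structure's CA trace with the B-factor column set to
#' `100 * S` (fixed 2-decimal PDB field), so any molecular viewer's
#' B-factor rainbow (violet lowest, red highest) renders the attribution.
#'
#' @param structure The `"ca_structure"` the heatmap was computed for.
#' @param heatmap A `"residue_heatmap"` whose residues align with the
#'   structure's chains (first chains in file order, as featurized).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_heatmap_pdb <- function(structure, heatmap, path) {
  stopifnot(inherits(structure, "ca_structure"),
            inherits(heatmap, "residue_heatmap"))
  chains <- structure$chains[seq_along(heatmap$chain_lengths)]
  lens <- vapply(chains, function(ch) nrow(ch$xyz), 0L)
  if (!identical(as.integer(lens), as.integer(heatmap$chain_lengths))) {
    stop("heatmap does not align with structure: chain lengths ",
         paste(lens, collapse = "/"), " vs ",
         paste(heatmap$chain_lengths, collapse = "/"))
  }
  b <- split(100 * heatmap$S,
             rep(seq_along(heatmap$chain_lengths), heatmap$chain_lengths))
  write_ca_pdb(lapply(chains, `[[`, "xyz"), path, b = b)
}

#' Proximity hit rate of highlighted residues against a reference set
#'
#' For each distance cutoff, the fraction of reference residues whose CA
#' atom lies within that distance of any highlighted CA atom (cutoff 0
#' counts only coincident, i.e. identical, residues). The fraction is
#' non-decreasing in the cutoff.
#'
#' @param highlighted n x 3 matrix of highlighted CA coordinates (e.g. the
#'   residues in the top decile of a heatmap's `S`).
#' @param reference m x 3 matrix of annotated reference CA coordinates
#'   (same frame). Must be nonempty.
#' @param cutoffs Distance cutoffs in Angstrom.
#' @return Named numeric vector of detected fractions, one per cutoff.
#' @export
proximity_hit_rate <- function(highlighted, reference, cutoffs = c(0, 4, 6, 8)) {
  reference <- as.matrix(reference)
  if (nrow(reference) == 0) stop("empty reference residue set")
  out <- setNames(numeric(length(cutoffs)), paste0(cutoffs, "A"))
  if (is.null(highlighted) || nrow(as.matrix(highlighted)) == 0) {
    warning("empty highlighted set; hit rate is 0 at all cutoffs")
    return(out)
  }
  highlighted <- as.matrix(highlighted)
  dmin <- apply(reference, 1, function(p) {
    sqrt(min(colSums((t(highlighted) - p)^2)))
  })
  for (i in seq_along(cutoffs)) {
    out[i] <- mean(dmin <= cutoffs[i] + 1e-6)
  }
  out
}
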