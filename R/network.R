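# --- model configuration and weights -----------------------------------------

#' Model configuration
#'
#' Architecture and training hyperparameters for the branch-convolution
#' scorer. The defaults follow the full-scale architecture (four branch
#' window sizes 5/10/15/20 residues, three convolution layers of 128 filters
#' per branch); `preset = "small"` is a reduced configuration (16 filters,
#' two layers, 32-unit embeddings) sized for desk-scale experiments and the
#' synthetic benchmark.
#'
#' @param window_sizes Convolution window sizes K, in residues, one branch
#'   per size. Distinct, each <= 1500.
#' @param n_conv Convolution layers per branch (N).
#' @param channels Filters per convolution layer (R).
#' @param protein_embed_dim,ligand_embed_dim,final_hidden_dim Dense layer
#'   widths of the protein embedding, ligand embedding and final hidden
#'   layer.
#' @param n_bits Expected ligand fingerprint length.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch negative resampling.
#' @param preset `"full"` (the defaults) or `"small"`.
#' @return An object of class `"ssnet_config"`.
#' @export
ssnet_config <- function(window_sizes = c(5L, 10L, 15L, 20L),
                         n_conv = 3L, channels = 128L,
                         protein_embed_dim = 128L, ligand_embed_dim = 128L,
                         final_hidden_dim = 64L, n_bits = 1024L,
                         learning_rate = 1e-4, epochs = 20L, batch_size = 32L,
                         seed = 1L, preset = c("full", "small")) {
  preset <- match.arg(preset)
  if (preset == "small") {
    if (missing(channels)) channels <- 16L
    if (missing(n_conv)) n_conv <- 2L
    if (missing(protein_embed_dim)) protein_embed_dim <- 32L
    if (missing(ligand_embed_dim)) ligand_embed_dim <- 32L
    if (missing(final_hidden_dim)) final_hidden_dim <- 32L
    if (missing(learning_rate)) learning_rate <- 1e-3
  }
  window_sizes <- as.integer(window_sizes)
  stopifnot(length(window_sizes) >= 1, !anyDuplicated(window_sizes),
            all(window_sizes >= 1), all(window_sizes <= 1500),
            n_conv >= 1, channels >= 1, protein_embed_dim >= 1,
            ligand_embed_dim >= 1, final_hidden_dim >= 1, n_bits >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(window_sizes = window_sizes, n_conv = as.integer(n_conv),
                 channels = as.integer(channels),
                 protein_embed_dim = as.integer(protein_embed_dim),
                 ligand_embed_dim = as.integer(ligand_embed_dim),
                 final_hidden_dim = as.integer(final_hidden_dim),
                 n_bits = as.integer(n_bits),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 preset = preset),
            class = "ssnet_config")
}

#' @export
print.ssnet_config <- function(x, ...) {
  cat(sprintf("ssnet config (%s): branches K = {%s}, %d conv layers x %d filters\n",
              x$preset, paste(x$window_sizes, collapse = ","), x$n_conv, x$channels))
  cat(sprintf("  embeddings: protein %d, ligand %d (from %d bits), hidden %d\n",
              x$protein_embed_dim, x$ligand_embed_dim, x$n_bits, x$final_hidden_dim))
  cat(sprintf("  training: lr %g, %d epochs, batch %d, seed %d\n",
              x$learning_rate, x$epochs, x$batch_size, x$seed))
  invisible(x)
}

# He-initialized weights; conv W layout is (out_ch x in_ch*K), K blocks of
# in_ch columns, matching the C++ kernels
.init_weights <- function(cfg) {
  he <- function(nout, nin) {
    matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
  }
  R <- cfg$channels
  conv <- lapply(cfg$window_sizes, function(K) {
    lapply(seq_len(cfg$n_conv), function(l) {
      in_ch <- if (l == 1) 2L else R
      list(W = he(R, in_ch * K), b = numeric(R))
    })
  })
  nb <- length(cfg$window_sizes)
  list(conv = conv,
       prot = list(W = he(cfg$protein_embed_dim, 2 * R * nb),
                   b = numeric(cfg$protein_embed_dim)),
       lig = list(W = he(cfg$ligand_embed_dim, cfg$n_bits),
                  b = numeric(cfg$ligand_embed_dim)),
       f1 = list(W = he(cfg$final_hidden_dim,
                        cfg$protein_embed_dim + cfg$ligand_embed_dim),
                 b = numeric(cfg$final_hidden_dim)),
       f2 = list(W = he(1L, cfg$final_hidden_dim), b = numeric(1)))
}

# --- forward pass -------------------------------------------------------------

# segments: list of 2 x n_i matrices (valid columns per chain); fp: 0/1 vector
# Returns score and, with keep = TRUE, every intermediate needed by .backward.
.forward <- function(segments, fp, w, cfg, keep = FALSE) {
  stopifnot(length(fp) == cfg$n_bits)
  if (length(segments) == 0 || sum(vapply(segments, ncol, 0L)) == 0) {
    stop("all-masked protein tensor: no valid residues")
  }
  nb <- length(cfg$window_sizes)
  R <- cfg$channels
  pooled <- numeric(0)
  cache <- if (keep) list(branches = vector("list", nb)) else NULL
  for (bi in seq_len(nb)) {
    K <- cfg$window_sizes[bi]
    acts <- vector("list", length(segments))
    pre <- vector("list", length(segments))
    for (si in seq_along(segments)) {
      A <- segments[[si]]
      if (keep) { pre[[si]] <- vector("list", cfg$n_conv); acts[[si]] <- vector("list", cfg$n_conv + 1); acts[[si]][[1]] <- A }
      for (l in seq_len(cfg$n_conv)) {
        Z <- conv1d_fwd(A, w$conv[[bi]][[l]]$W, w$conv[[bi]][[l]]$b, K)
        A <- Z * (Z > 0)
        if (keep) { pre[[si]][[l]] <- Z; acts[[si]][[l + 1]] <- A }
      }
      if (!keep) acts[[si]] <- A
    }
    X <- do.call(cbind, if (keep) lapply(acts, function(a) a[[cfg$n_conv + 1]]) else acts)
    imax <- max.col(X, ties.method = "first")
    imin <- max.col(-X, ties.method = "first")
    d <- X[cbind(seq_len(R), imax)]
    v <- d - X[cbind(seq_len(R), imin)]
    pooled <- c(pooled, d, v)
    if (keep) {
      cache$branches[[bi]] <- list(pre = pre, acts = acts, X = X,
                                   imax = imax, imin = imin)
    }
  }
  yp_pre <- drop(w$prot$W %*% pooled) + w$prot$b
  yp <- pmax(yp_pre, 0)
  yl_pre <- drop(w$lig$W %*% fp) + w$lig$b
  yl <- pmax(yl_pre, 0)
  e <- c(yp, yl)
  h_pre <- drop(w$f1$W %*% e) + w$f1$b
  h <- pmax(h_pre, 0)
  o <- drop(w$f2$W %*% h) + w$f2$b
  score <- 1 / (1 + exp(-o))
  if (!keep) return(score)
  cache$pooled <- pooled; cache$yp_pre <- yp_pre; cache$yp <- yp
  cache$yl_pre <- yl_pre; cache$yl <- yl; cache$h_pre <- h_pre; cache$h <- h
  cache$o <- o; cache$score <- score; cache$fp <- fp
  cache$segments <- segments
  cache
}

# Backprop from d(loss)/d(o) = dout (pre-sigmoid gradient).
# Returns parameter gradients and, when want_dX, the gradient of the sigmoid
# output w.r.t. each branch's final conv activation (for Grad-CAM).
.backward <- function(cache, w, cfg, dout, want_dX = FALSE) {
  nb <- length(cfg$window_sizes)
  R <- cfg$channels
  g <- list(conv = vector("list", nb))
  dh <- drop(t(w$f2$W) * dout)
  g$f2 <- list(W = matrix(cache$h * dout, nrow = 1), b = dout)
  dh_pre <- dh * (cache$h_pre > 0)
  g$f1 <- list(W = outer(dh_pre, c(cache$yp, cache$yl)), b = dh_pre)
  de <- drop(t(w$f1$W) %*% dh_pre)
  pe <- cfg$protein_embed_dim
  dyp_pre <- de[seq_len(pe)] * (cache$yp_pre > 0)
  dyl_pre <- de[-seq_len(pe)] * (cache$yl_pre > 0)
  g$prot <- list(W = outer(dyp_pre, cache$pooled), b = dyp_pre)
  g$lig <- list(W = outer(dyl_pre, cache$fp), b = dyl_pre)
  dpool <- drop(t(w$prot$W) %*% dyp_pre)
  dX_branches <- if (want_dX) vector("list", nb) else NULL
  for (bi in seq_len(nb)) {
    K <- cfg$window_sizes[bi]
    br <- cache$branches[[bi]]
    off <- (bi - 1) * 2 * R
    dd <- dpool[off + seq_len(R)]
    dv <- dpool[off + R + seq_len(R)]
    dX <- matrix(0, nrow = R, ncol = ncol(br$X))
    dX[cbind(seq_len(R), br$imax)] <- dX[cbind(seq_len(R), br$imax)] + dd + dv
    dX[cbind(seq_len(R), br$imin)] <- dX[cbind(seq_len(R), br$imin)] - dv
    if (want_dX) dX_branches[[bi]] <- dX
    g$conv[[bi]] <- lapply(seq_len(cfg$n_conv), function(l) {
      in_ch <- if (l == 1) 2L else R
      list(W = matrix(0, R, in_ch * K), b = numeric(R))
    })
    col0 <- 0L
    for (si in seq_along(br$acts)) {
      nc <- ncol(br$acts[[si]][[1]])
      dA <- dX[, col0 + seq_len(nc), drop = FALSE]
      col0 <- col0 + nc
      for (l in rev(seq_len(cfg$n_conv))) {
        dZ <- dA * (br$pre[[si]][[l]] > 0)
        gw <- conv1d_bwd_w(dZ, br$acts[[si]][[l]], K)
        g$conv[[bi]][[l]]$W <- g$conv[[bi]][[l]]$W + gw$dW
        g$conv[[bi]][[l]]$b <- g$conv[[bi]][[l]]$b + drop(gw$db)
        if (l > 1) {
          dA <- conv1d_bwd_x(dZ, w$conv[[bi]][[l]]$W,
                             if (l == 2) cfg$channels else cfg$channels, K)
        }
      }
    }
  }
  list(grads = g, dX = dX_branches)
}

# --- exported network operations ---------------------------------------------

#' Score one protein-ligand pair
#'
#' Runs the branch-convolution forward pass: per-branch stacks of
#' 'same'-padded 1D convolutions with ReLU over the curvature/torsion rows,
#' masked global-max and total-variation pooling over valid residues only,
#' dense protein and ligand embeddings, and a final sigmoid score.
#'
#' @param tensor A `"protein_tensor"`.
#' @param fp A `"ligand_fp"` or 0/1 vector of length `config$n_bits`.
#' @param weights Network weights (from [ssnet()] fits use `coef(fit)`).
#' @param config The `"ssnet_config"` the weights were built for.
#' @return Binding score in `[0, 1]`.
#' @export
ssnet_score <- function(tensor, fp, weights, config) {
  stopifnot(inherits(tensor, "protein_tensor"))
  bits <- if (inherits(fp, "ligand_fp")) as.numeric(fp$bits) else as.numeric(fp)
  .forward(.tensor_segments(tensor), bits, weights, config)
}

#' Global-max and total-variation pooling
#'
#' Collapses a latent activation matrix over its valid columns: `d[r]` is the
#' row maximum and `v[r]` the row range (max - min), so `v` is always
#' nonnegative.
#'
#' @param latent R x L activation matrix.
#' @param mask Logical vector over columns; only `TRUE` columns are pooled
#'   (default all).
#' @return List with vectors `d` and `v`, each of length `nrow(latent)`.
#' @examples
#' pool_latent(matrix(c(1, 3, 2), nrow = 1))  # d = 3, v = 2
#' @export
pool_latent <- function(latent, mask = NULL) {
  latent <- as.matrix(latent)
  if (is.null(mask)) mask <- rep(TRUE, ncol(latent))
  stopifnot(length(mask) == ncol(latent))
  if (!any(mask)) stop("no valid columns to pool")
  X <- latent[, mask, drop = FALSE]
  d <- apply(X, 1, max)
  v <- d - apply(X, 1, min)
  list(d = d, v = v)
}

#' Mean binary cross-entropy loss
#'
#' `-(1/M) * sum(y log s + (1 - y) log(1 - s))` in nats, with scores clipped
#' to `[eps, 1 - eps]`.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels (0/1), same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Mean loss (nats).
#' @examples
#' bce_loss(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
bce_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) == 0) stop("empty prediction list")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' Label activity records by binding affinity
#'
#' Applies the two-threshold rule used to binarize measured affinities
#' (IC50-style, nM): below `active_below` is active, above `inactive_above`
#' inactive, and records in between are discarded as ambiguous.
#'
#' @param affinity_nM Positive affinities in nM.
#' @param active_below Active threshold x (default 100 nM).
#' @param inactive_above Inactive threshold y (default 10000 nM).
#' @return Factor with levels `active`, `inactive`, `discard`.
#' @examples
#' label_by_affinity(c(50, 20000, 5000))
#' @export
label_by_affinity <- function(affinity_nM, active_below = 100,
                              inactive_above = 10000) {
  stopifnot(active_below <= inactive_above)
  if (any(!is.finite(affinity_nM)) || any(affinity_nM <= 0)) {
    stop("affinities must be positive and finite")
  }
  out <- ifelse(affinity_nM < active_below, "active",
                ifelse(affinity_nM > inactive_above, "inactive", "discard"))
  factor(out, levels = c("active", "inactive", "discard"))
}
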