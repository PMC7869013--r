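# --- model fitting ------------------------------------------------------------

# recursive Adam update over the nested weight list
.adam_step <- function(w, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(w)) {
    keys <- if (is.null(names(w))) seq_along(w) else names(w)
    for (nm in keys) {
      r <- .adam_step(w[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      w[[nm]] <- r$w; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(w = w, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

.zeros_like <- function(w) {
  if (is.list(w)) lapply(w, .zeros_like) else w * 0
}

.add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- .add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

.as_bits <- function(fp, n_bits) {
  v <- if (inherits(fp, "ligand_fp")) fp$bits else fp
  v <- as.numeric(v)
  if (length(v) != n_bits) {
    stop("fingerprint length ", length(v), " does not match config n_bits ", n_bits)
  }
  v
}

#' Fit the protein-ligand interaction scorer
#'
#' Trains the multi-branch 1D convolutional network on labeled
#' protein-ligand pairs by minimizing binary cross-entropy with Adam and
#' class-balanced sampling: every epoch uses all positive pairs plus an
#' equal-sized fresh random resample of the negatives, so an excess of
#' decoys never swamps the loss. Training is bit-reproducible for a fixed
#' `config$seed`.
#'
#' @param pairs Data frame with columns `protein_id`, `ligand_id` and either
#'   `label` (0/1) or `affinity_nM` (binarized via [label_by_affinity()];
#'   in-between records are dropped).
#' @param tensors Named list of `"protein_tensor"` objects keyed by
#'   `protein_id`.
#' @param fingerprints Ligand fingerprints keyed by `ligand_id`: a logical/
#'   0-1 matrix with one named row per ligand, or a named list of
#'   `"ligand_fp"` objects.
#' @param config An [ssnet_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `"ssnet"`: list with `weights`, `config`,
#'   `training` (per-epoch data frame: epoch, loss, n_pos, n_neg), and the
#'   training pair table with fitted scores. Supports `predict`, `print`,
#'   `summary`, `coef`, `plot`, `residuals` and `simulate`.
#' @seealso [predict.ssnet()], [residue_heatmap()], [save_ssnet()]
#' @export
ssnet <- function(pairs, tensors, fingerprints, config = ssnet_config(),
                  verbose = FALSE) {
  stopifnot(inherits(config, "ssnet_config"),
            is.data.frame(pairs),
            all(c("protein_id", "ligand_id") %in% names(pairs)))
  if (!"label" %in% names(pairs)) {
    if (!"affinity_nM" %in% names(pairs)) {
      stop("pairs needs a 'label' or 'affinity_nM' column")
    }
    lab <- label_by_affinity(pairs$affinity_nM)
    pairs <- pairs[lab != "discard", , drop = FALSE]
    pairs$label <- as.integer(lab[lab != "discard"] == "active")
  }
  stopifnot(all(pairs$label %in% c(0, 1)))
  if (length(unique(pairs$label)) < 2) {
    stop("training needs at least one positive and one negative pair")
  }
  if (is.matrix(fingerprints)) {
    fm <- fingerprints
    fingerprints <- lapply(seq_len(nrow(fm)), function(i) as.numeric(fm[i, ]))
    names(fingerprints) <- rownames(fm)
  }
  miss <- setdiff(unique(pairs$protein_id), names(tensors))
  if (length(miss)) stop("missing tensors for proteins: ", paste(head(miss), collapse = ", "))
  miss <- setdiff(unique(pairs$ligand_id), names(fingerprints))
  if (length(miss)) stop("missing fingerprints for ligands: ", paste(head(miss), collapse = ", "))

  segs <- lapply(tensors, .tensor_segments)
  bits <- lapply(fingerprints, .as_bits, n_bits = config$n_bits)

  set.seed(config$seed)
  w <- .init_weights(config)
  m <- .zeros_like(w); v <- .zeros_like(w)
  pos <- which(pairs$label == 1)
  neg <- which(pairs$label == 0)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    n_pos = integer(), n_neg = integer())
  t_adam <- 0L
  for (ep in seq_len(config$epochs)) {
    idx <- c(pos, sample(neg, length(pos), replace = length(neg) < length(pos)))
    idx <- sample(idx)
    ep_loss <- 0
    i0 <- 1L
    while (i0 <= length(idx)) {
      batch <- idx[i0:min(i0 + config$batch_size - 1L, length(idx))]
      i0 <- i0 + config$batch_size
      gacc <- NULL
      for (j in batch) {
        cache <- .forward(segs[[pairs$protein_id[j]]], bits[[pairs$ligand_id[j]]],
                          w, config, keep = TRUE)
        y <- pairs$label[j]
        s <- min(max(cache$score, 1e-7), 1 - 1e-7)
        ep_loss <- ep_loss - (y * log(s) + (1 - y) * log(1 - s))
        bw <- .backward(cache, w, config, dout = cache$score - y)
        gacc <- if (is.null(gacc)) bw$grads else .add_grads(gacc, bw$grads)
      }
      gacc <- rapply(gacc, function(x) x / length(batch), how = "replace")
      t_adam <- t_adam + 1L
      r <- .adam_step(w, gacc, m, v, config$learning_rate, t_adam)
      w <- r$w; m <- r$m; v <- r$v
    }
    ep_loss <- ep_loss / length(idx)
    if (!is.finite(ep_loss)) stop("non-finite training loss at epoch ", ep)
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss,
                                 n_pos = length(pos), n_neg = length(pos)))
    if (verbose) cat(sprintf("epoch %2d  loss %.4f  (%d pairs)\n", ep, ep_loss, length(idx)))
  }
  scores <- vapply(seq_len(nrow(pairs)), function(j) {
    .forward(segs[[pairs$protein_id[j]]], bits[[pairs$ligand_id[j]]], w, config)
  }, numeric(1))
  fit <- structure(list(weights = w, config = config, training = log,
                        pairs = transform(pairs, score = scores),
                        n_proteins = length(unique(pairs$protein_id)),
                        n_ligands = length(unique(pairs$ligand_id)),
                        threshold = 0.5,
                        format_version = 1L,
                        call = match.call()),
                   class = "ssnet")
  fit
}

#' Predict binding scores from a fitted model
#'
#' @param object An `"ssnet"` fit.
#' @param pairs Data frame with `protein_id` and `ligand_id` columns; omit it
#'   (with `tensor`/`fp` set) to score a single pair.
#' @param tensors,fingerprints Containers as in [ssnet()].
#' @param tensor,fp A single `"protein_tensor"` and fingerprint, scored when
#'   `pairs` is missing.
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict.ssnet <- function(object, pairs = NULL, tensors = NULL,
                          fingerprints = NULL, tensor = NULL, fp = NULL, ...) {
  if (is.null(pairs)) {
    stopifnot(!is.null(tensor), !is.null(fp))
    return(ssnet_score(tensor, fp, object$weights, object$config))
  }
  if (is.matrix(fingerprints)) {
    fm <- fingerprints
    fingerprints <- lapply(seq_len(nrow(fm)), function(i) as.numeric(fm[i, ]))
    names(fingerprints) <- rownames(fm)
  }
  segs <- lapply(tensors, .tensor_segments)
  bits <- lapply(fingerprints, .as_bits, n_bits = object$config$n_bits)
  vapply(seq_len(nrow(pairs)), function(j) {
    .forward(segs[[pairs$protein_id[j]]], bits[[pairs$ligand_id[j]]],
             object$weights, object$config)
  }, numeric(1))
}

#' @export
print.ssnet <- function(x, ...) {
  cat("ssnet fit: branch-CNN protein-ligand interaction scorer\n")
  cat(sprintf("  %d pairs (%d proteins x %d ligands), %d epochs, final loss %.4f\n",
              nrow(x$pairs), x$n_proteins, x$n_ligands,
              nrow(x$training), x$training$loss[nrow(x$training)]))
  print(x$config)
  invisible(x)
}

#' @export
summary.ssnet <- function(object, ...) {
  s <- object$pairs$score
  y <- object$pairs$label
  out <- list(config = object$config, training = object$training,
              auroc = if (length(unique(y)) == 2) auroc(s, y) else NA_real_,
              loss = bce_loss(s, y),
              accuracy = mean((s >= object$threshold) == (y == 1)),
              n_pairs = nrow(object$pairs))
  class(out) <- "summary.ssnet"
  out
}

#' @export
print.summary.ssnet <- function(x, ...) {
  cat("ssnet training summary\n")
  cat(sprintf("  %d pairs; training AUROC %.3f, BCE %.4f, accuracy %.3f (threshold 0.5)\n",
              x$n_pairs, x$auroc, x$loss, x$accuracy))
  cat(sprintf("  loss: epoch 1 %.4f -> epoch %d %.4f\n",
              x$training$loss[1], nrow(x$training),
              x$training$loss[nrow(x$training)]))
  invisible(x)
}

#' @export
coef.ssnet <- function(object, ...) object$weights

#' @export
residuals.ssnet <- function(object, ...) object$pairs$label - object$pairs$score

#' @export
plot.ssnet <- function(x, ...) {
  graphics::plot(x$training$epoch, x$training$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean BCE loss (nats)",
                 main = "ssnet training loss", ...)
  invisible(x)
}

#' @export
simulate.ssnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$pairs$score
  out <- as.data.frame(replicate(nsim, rbinom(length(s), 1, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# --- checkpointing ------------------------------------------------------------

#' Save / load a fitted model checkpoint
#'
#' Single-file checkpoint (weights + configuration + format version) with a
#' bit-exact round trip: scores from a reloaded model match the original
#' exactly.
#'
#' @param object An `"ssnet"` fit.
#' @param path Checkpoint file path.
#' @return `save_ssnet` returns `path` invisibly; `load_ssnet` the restored
#'   `"ssnet"` object.
#' @export
save_ssnet <- function(object, path) {
  stopifnot(inherits(object, "ssnet"))
  saveRDS(object, path, version = 3)
  invisible(path)
}

#' @rdname save_ssnet
#' @export
load_ssnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ssnet") || is.null(obj$format_version)) {
    stop("not an ssnet checkpoint: ", path)
  }
  obj
}
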