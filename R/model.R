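#' Loss configuration for the correction model
#'
#' The training objective is a weighted sum of three terms,
#' `L_overall = L_correct + w_contrast * L_contrast +
#' w_consistency * L_consistency`: a reconstruction term (global L1 plus a
#' mask-weighted L1 over the pseudo-artifact region), a contrastive term
#' pulling the bottleneck embeddings of a map and its shifted/rotated version
#' together (normalized-temperature cross-entropy), and a consistency term
#' matching the first two moments of the prediction to the uncorrupted part
#' of the input.
#'
#' @param w_contrast,w_consistency non-negative weights of the contrastive
#'   and consistency terms.
#' @param lambda_mask extra weight on the L1 error inside the
#'   pseudo-artifact region.
#' @param temperature softmax temperature of the contrastive term.
#' @param max_shift,max_rot augmentation bounds: shift in px, rotation in
#'   degrees.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(w_contrast = 0.1, w_consistency = 0.1,
                        lambda_mask = 5, temperature = 0.5,
                        max_shift = 8, max_rot = 10) {
  stopifnot(w_contrast >= 0, w_consistency >= 0, lambda_mask >= 0,
            temperature > 0, max_shift >= 0, max_rot >= 0)
  structure(list(w_contrast = w_contrast, w_consistency = w_consistency,
                 lambda_mask = lambda_mask, temperature = temperature,
                 max_shift = max_shift, max_rot = max_rot),
            class = "loss_config")
}

# mirror-reflect continuous indices into [1, n]
reflect_index <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  y <- (x - 1) %% p
  1 + (n - 1) - abs(y - (n - 1))
}

#' Shift-and-rotate augmentation with reflection fill
#'
#' Applies a random integer shift and small rotation to a thickness grid,
#' filling pixels that fall outside the frame by mirror reflection. This is
#' the perturbation whose bottleneck embedding the contrastive loss ties to
#' the original's.
#'
#' @param values numeric matrix.
#' @param max_shift maximum |shift| per axis, px (integer shifts are drawn).
#' @param max_rot maximum |rotation|, degrees.
#' @param seed integer seed.
#' @return Perturbed matrix of the same shape.
#' @export
augment_map <- function(values, max_shift = 8, max_rot = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shift <- round(stats::runif(2, -max_shift, max_shift))
  rot <- stats::runif(1, -max_rot, max_rot) * pi / 180
  if (all(shift == 0) && rot == 0) return(values)
  warp_map(values, shift, rot)
}

# inverse-map each output pixel to a source location (rotate about the grid
# center, then shift), sample bilinearly with reflected indices
warp_map <- function(values, shift, rot) {
  d <- dim(values)
  ctr <- (d + 1) / 2
  rr <- rep(seq_len(d[1L]), times = d[2L]) - ctr[1L] - shift[1L]
  cc <- rep(seq_len(d[2L]), each = d[1L]) - ctr[2L] - shift[2L]
  sr <- ctr[1L] + rr * cos(rot) + cc * sin(rot)
  sc <- ctr[2L] - rr * sin(rot) + cc * cos(rot)
  sr <- reflect_index(sr, d[1L])
  sc <- reflect_index(sc, d[2L])
  matrix(bilinear_sample(values, sr, sc), d[1L], d[2L])
}

#' Reconstruction loss
#'
#' Mean absolute deviation between prediction and target over the whole grid,
#' plus `lambda_mask` times the mean absolute deviation over the
#' pseudo-artifact region (0 when the mask is empty).
#'
#' @param pred,target numeric arrays of equal shape.
#' @param mask logical array (pseudo-artifact region), same shape.
#' @param lambda_mask region-emphasis weight.
#' @return Scalar loss.
#' @export
correction_loss <- function(pred, target, mask, lambda_mask = 5) {
  stopifnot(all(dim(pred) == dim(target)))
  d <- abs(pred - target)
  m <- if (any(mask)) mean(d[mask]) else 0
  mean(d) + lambda_mask * m
}

correction_loss_grad <- function(pred, target, mask, lambda_mask = 5) {
  s <- sign(pred - target)
  g <- s / length(pred)
  if (any(mask)) g[mask] <- g[mask] + lambda_mask * s[mask] / sum(mask)
  g
}

#' Contrastive (NT-Xent) loss over paired embeddings
#'
#' Normalized-temperature cross-entropy over cosine similarities: rows
#' `1..B` of `emb` are the embeddings of `B` maps, rows `B+1..2B` those of
#' their perturbed versions; row `i` and row `i+B` are positives, all other
#' rows are negatives.
#'
#' @param emb numeric matrix, `2B x d`, rows L2-normalized.
#' @param temperature softmax temperature (> 0).
#' @param grad if `TRUE`, also return the gradient with respect to `emb`.
#' @return Scalar loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
contrastive_loss <- function(emb, temperature = 0.5, grad = FALSE) {
  n <- nrow(emb)
  if (n < 4L || n %% 2L != 0L)
    stop("need at least 2 original/perturbed pairs (4 embeddings)",
         call. = FALSE)
  B <- n %/% 2L
  partner <- c(seq_len(B) + B, seq_len(B))
  s <- emb %*% t(emb) / temperature
  diag(s) <- -Inf                       # anchor never its own candidate
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  Z <- rowSums(e)
  logp <- s[cbind(seq_len(n), partner)] - m - log(Z)
  loss <- -mean(logp)
  if (!grad) return(loss)
  P <- e / Z
  G <- P
  G[cbind(seq_len(n), partner)] <- G[cbind(seq_len(n), partner)] - 1
  G <- G / (n * temperature)
  g_emb <- G %*% emb + t(G) %*% emb
  list(loss = loss, grad = g_emb)
}

#' Distribution-consistency loss
#'
#' Encourages the corrected map to keep the statistical profile of the
#' uncorrupted measurements: absolute difference of means plus absolute
#' difference of standard deviations, computed over the pixels in
#' `keep` (typically non-disc, non-artifact pixels of the input).
#'
#' @param pred,input_map numeric arrays of equal shape.
#' @param keep logical array selecting the comparison region.
#' @return Scalar loss.
#' @export
consistency_loss <- function(pred, input_map, keep) {
  stopifnot(all(dim(pred) == dim(input_map)))
  if (!any(keep)) return(0)
  p <- pred[keep]; q <- input_map[keep]
  sdp <- function(v) sqrt(mean((v - mean(v))^2))
  abs(mean(p) - mean(q)) + abs(sdp(p) - sdp(q))
}

consistency_loss_grad <- function(pred, input_map, keep) {
  g <- array(0, dim(pred))
  if (!any(keep)) return(g)
  p <- pred[keep]; q <- input_map[keep]
  n <- length(p)
  mp <- mean(p)
  sp <- sqrt(mean((p - mp)^2))
  gk <- sign(mp - mean(q)) / n
  sq <- sqrt(mean((q - mean(q))^2))
  if (sp > 1e-12) gk <- gk + sign(sp - sq) * (p - mp) / (n * sp)
  g[keep] <- gk
  g
}

#' Overall training loss
#'
#' @param parts list (or numeric vector) with elements `correct`, `contrast`,
#'   `consistency`.
#' @param config a [loss_config()].
#' @return `correct + w_contrast * contrast + w_consistency * consistency`.
#' @export
total_loss <- function(parts, config = loss_config()) {
  parts <- as.list(parts)
  stopifnot(is.finite(parts$correct), is.finite(parts$contrast),
            is.finite(parts$consistency))
  parts$correct + config$w_contrast * parts$contrast +
    config$w_consistency * parts$consistency
}

# assemble the (H, W, 2, N) input tensor: scaled thickness + sub-floor
# indicator channel
stack_inputs <- function(maps, floor_um, scale = 100) {
  d <- dim(maps[[1L]])
  x <- array(0, c(d[1L], d[2L], 2L, length(maps)))
  for (i in seq_along(maps)) {
    m <- unclass(maps[[i]])
    x[, , 1L, i] <- m / scale
    x[, , 2L, i] <- (m < floor_um) * 1
  }
  x
}

#' Fit the artifact-correction model
#'
#' Trains a compact convolutional encoder-decoder with skip connections
#' (four resolution levels, an embedding head on the bottleneck) to restore
#' thickness values in artifact regions, from pseudo-artifact training pairs.
#' The objective is the three-term loss of [loss_config()]; optimization is
#' Adam on minibatches, fully deterministic for a given `seed`. Inputs enter
#' as two channels: thickness / 100 and a binary sub-floor indicator.
#'
#' @param pairs list of `training_pair` objects (see
#'   [superimpose_pattern()], [build_pseudo_corpus()]); each element must
#'   also carry `$disc`.
#' @param config a [loss_config()].
#' @param epochs number of passes over the training pairs.
#' @param batch_size minibatch size (>= 2 for the contrastive term).
#' @param lr Adam learning rate.
#' @param widths channel widths of the four levels.
#' @param emb_dim embedding dimension of the contrastive head.
#' @param floor_um measurement floor, um.
#' @param seed integer seed controlling initialization, batching and
#'   augmentation.
#' @param verbose print per-epoch losses.
#' @return Object of class `rnflt_correction`: list with `params` (network
#'   weights), `config`, `history` (per-epoch data frame of `l_correct`,
#'   `l_contrast`, `l_consistency`, `l_overall`), `size`, `floor_um`.
#' @seealso [predict.rnflt_correction()] to correct maps.
#' @export
train_correction_model <- function(pairs, config = loss_config(),
                                   epochs = 10L, batch_size = 8L,
                                   lr = 3e-3, widths = c(8L, 16L, 32L, 32L),
                                   emb_dim = 16L, floor_um = 50,
                                   seed = 1L, verbose = FALSE) {
  stopifnot(length(pairs) >= 1L, epochs >= 1L, batch_size >= 2L)
  set.seed(seed)
  d <- dim(pairs[[1L]]$input)
  if (d[1L] %% 8L != 0L || d[2L] %% 8L != 0L)
    stop("map side must be divisible by 8 for the 4-level network",
         call. = FALSE)
  params <- net_init(in_ch = 2L, widths = widths, emb_dim = emb_dim)
  opt <- adam_init(params)
  n <- length(pairs)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_parts <- c(correct = 0, contrast = 0, consistency = 0, overall = 0)
    nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      if (length(idx) < 2L) next       # contrastive term needs >= 2 pairs
      bp <- pairs[idx]
      x <- stack_inputs(lapply(bp, `[[`, "input"), floor_um)
      tgt <- stack_inputs(lapply(bp, `[[`, "target"), floor_um)[, , 1L, ,
                                                                drop = FALSE]
      msk <- array(FALSE, dim(tgt))
      keep <- array(FALSE, dim(tgt))
      for (i in seq_along(bp)) {
        msk[, , 1L, i] <- bp[[i]]$pseudo_mask
        keep[, , 1L, i] <- !bp[[i]]$pseudo_mask & !unclass(bp[[i]]$disc) &
          !(unclass(bp[[i]]$input) < floor_um)
      }
      xa <- x
      for (i in seq_along(bp)) {
        sh <- round(stats::runif(2, -config$max_shift, config$max_shift))
        ro <- stats::runif(1, -config$max_rot, config$max_rot) * pi / 180
        xa[, , 1L, i] <- warp_map(x[, , 1L, i], sh, ro)
        xa[, , 2L, i] <- warp_map(x[, , 2L, i], sh, ro)
      }
      cache <- net_fwd(params, x, decoder = TRUE)
      cache_a <- net_fwd(params, xa, decoder = FALSE)
      emb <- rbind(cache$emb, cache_a$emb)
      l_cor <- correction_loss(cache$pred, tgt, msk, config$lambda_mask)
      cl <- contrastive_loss(emb, config$temperature, grad = TRUE)
      l_con <- 0
      g_con <- array(0, dim(cache$pred))
      for (i in seq_along(bp)) {
        k <- keep[, , 1L, i]
        l_con <- l_con + consistency_loss(cache$pred[, , 1L, i],
                                          x[, , 1L, i], k) / length(bp)
        g_con[, , 1L, i] <- consistency_loss_grad(cache$pred[, , 1L, i],
                                                  x[, , 1L, i], k) / length(bp)
      }
      l_all <- total_loss(list(correct = l_cor, contrast = cl$loss,
                               consistency = l_con), config)
      if (!is.finite(l_all))
        stop(sprintf(
          "non-finite loss at epoch %d (correct=%g contrast=%g consistency=%g); aborting",
          ep, l_cor, cl$loss, l_con), call. = FALSE)
      g_pred <- correction_loss_grad(cache$pred, tgt, msk,
                                     config$lambda_mask) +
        config$w_consistency * g_con
      B <- length(bp)
      g_emb <- config$w_contrast * cl$grad
      g1 <- net_bwd(params, cache, g_pred = g_pred,
                    g_emb = g_emb[seq_len(B), , drop = FALSE])
      g2 <- net_bwd(params, cache_a, g_pred = NULL,
                    g_emb = g_emb[B + seq_len(B), , drop = FALSE])
      st <- adam_step(params, grad_add(g1, g2), opt, lr = lr)
      params <- st$p
      opt$m <- st$state$m; opt$v <- st$state$v; opt$t <- st$state$t
      ep_parts <- ep_parts + c(l_cor, cl$loss, l_con, l_all)
      nb <- nb + 1L
    }
    hist[[ep]] <- ep_parts / nb
    if (verbose)
      cat(sprintf("epoch %d: L_overall %.4f (correct %.4f contrast %.4f consistency %.4f)\n",
                  ep, hist[[ep]][4L], hist[[ep]][1L], hist[[ep]][2L],
                  hist[[ep]][3L]))
  }
  hist <- as.data.frame(do.call(rbind, hist))
  names(hist) <- c("l_correct", "l_contrast", "l_consistency", "l_overall")
  hist$epoch <- seq_len(epochs)
  structure(list(params = params, config = config, history = hist,
                 size = d, floor_um = floor_um, scale = 100,
                 seed = seed, lr = lr, batch_size = batch_size,
                 epochs = epochs),
            class = "rnflt_correction")
}

#' @export
print.rnflt_correction <- function(x, ...) {
  w <- attr(x$params, "widths")
  cat(sprintf("RNFLT artifact-correction model (%dx%d input, widths %s)\n",
              x$size[1L], x$size[2L], paste(w, collapse = "-")))
  h <- x$history
  cat(sprintf("  trained %d epochs; L_overall %.4f -> %.4f\n",
              nrow(h), h$l_overall[1L], h$l_overall[nrow(h)]))
  cat(sprintf("  loss weights: w_contrast %.3g, w_consistency %.3g, lambda_mask %.3g\n",
              x$config$w_contrast, x$config$w_consistency,
              x$config$lambda_mask))
  invisible(x)
}

#' @export
summary.rnflt_correction <- function(object, ...) {
  print(object)
  cat("\ntraining history:\n")
  print(object$history, row.names = FALSE, digits = 4)
  invisible(object$history)
}

#' @export
plot.rnflt_correction <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$l_overall, h$l_correct),
                    type = "l", lty = 1, lwd = 2,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L_overall", "L_correct"),
                   col = 1:2, lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Correct the artifacts in an RNFLT map
#'
#' Detects the artifact region (sub-floor, non-disc pixels), runs the map
#' through the trained network, and blends: measured values are kept
#' everywhere off the artifact mask, network predictions (clipped to at least
#' the floor) replace values on it. A map with no artifacts is returned
#' unchanged. Maps whose resolution differs from the training resolution are
#' resampled through the network and the prediction is resampled back.
#'
#' @param object an [train_correction_model()] fit.
#' @param map the [rnflt_map()] to correct.
#' @param disc its [disc_mask()] (default: standard central disc).
#' @param regenerate_all if `TRUE`, return the raw network output everywhere
#'   instead of blending (diagnostic mode).
#' @param ... unused.
#' @return List with `map` (corrected [rnflt_map()]) and `mask` (the
#'   [artifact_mask()] that was filled in).
#' @export
predict.rnflt_correction <- function(object, map, disc = disc_mask(map),
                                     regenerate_all = FALSE, ...) {
  am <- artifact_mask(map, disc, object$floor_um)
  if (!any(am) && !regenerate_all)
    return(list(map = map, mask = am))
  vals <- unclass(map)
  net_in <- resize_matrix(vals, object$size)
  x <- array(0, c(object$size[1L], object$size[2L], 2L, 1L))
  x[, , 1L, 1L] <- net_in / object$scale
  x[, , 2L, 1L] <- (net_in < object$floor_um) * 1
  cache <- net_fwd(object$params, x, decoder = TRUE)
  pred <- resize_matrix(matrix(cache$pred[, , 1L, 1L],
                               object$size[1L], object$size[2L]),
                        dim(vals)) * object$scale
  pred <- pmin(pmax(pred, object$floor_um), 500)
  out_vals <- if (regenerate_all) pred else vals
  if (!regenerate_all) out_vals[am] <- pred[am]
  out <- map
  out[] <- out_vals
  list(map = out, mask = am)
}
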