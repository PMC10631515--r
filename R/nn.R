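# Internal building blocks for the correction network. Activations are R
# arrays of dim (H, W, C, N); convolutions run through the compiled
# primitives in src/convnet.cpp (stride 1, zero 'same' padding).

relu <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(g, act) { g[act <= 0] <- 0; g }

avgpool2 <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1L], by = 2L); jo <- seq(1L, d[2L], by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
     x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(g) {
  d <- dim(g)
  out <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], d[4L]))
  io <- seq(1L, 2L * d[1L], by = 2L); jo <- seq(1L, 2L * d[2L], by = 2L)
  g4 <- g / 4
  out[io, jo, , ] <- g4; out[io + 1L, jo, , ] <- g4
  out[io, jo + 1L, , ] <- g4; out[io + 1L, jo + 1L, , ] <- g4
  out
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(g) {
  d <- dim(g)
  io <- seq(1L, d[1L], by = 2L); jo <- seq(1L, d[2L], by = 2L)
  g[io, jo, , , drop = FALSE] + g[io + 1L, jo, , , drop = FALSE] +
    g[io, jo + 1L, , , drop = FALSE] + g[io + 1L, jo + 1L, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

conv_init <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

#' @keywords internal
net_init <- function(in_ch = 2L, widths = c(8L, 16L, 32L, 32L),
                     emb_dim = 16L, out_bias = 0.8) {
  p <- list(
    enc1 = conv_init(3, 3, in_ch, widths[1L]),
    enc2 = conv_init(3, 3, widths[1L], widths[2L]),
    enc3 = conv_init(3, 3, widths[2L], widths[3L]),
    bott = conv_init(3, 3, widths[3L], widths[4L]),
    dec3 = conv_init(3, 3, widths[4L] + widths[3L], widths[2L]),
    dec2 = conv_init(3, 3, widths[2L] + widths[2L], widths[1L]),
    dec1 = conv_init(3, 3, widths[1L] + widths[1L], widths[1L]),
    outc = conv_init(3, 3, widths[1L], 1L, gain = 0.3),
    emb = list(w = matrix(stats::rnorm(widths[4L] * emb_dim,
                                       sd = 1 / sqrt(widths[4L])),
                          widths[4L], emb_dim),
               b = numeric(emb_dim)))
  p$outc$b[] <- out_bias
  attr(p, "widths") <- widths
  attr(p, "in_ch") <- in_ch
  p
}

# forward pass; caches every intermediate needed by net_bwd.
# decoder = FALSE runs the encoder + embedding head only (contrastive branch).
net_fwd <- function(p, x, decoder = TRUE) {
  e1 <- relu(conv2d_fwd(x, p$enc1$w, p$enc1$b)); p1 <- avgpool2(e1)
  e2 <- relu(conv2d_fwd(p1, p$enc2$w, p$enc2$b)); p2 <- avgpool2(e2)
  e3 <- relu(conv2d_fwd(p2, p$enc3$w, p$enc3$b)); p3 <- avgpool2(e3)
  bt <- relu(conv2d_fwd(p3, p$bott$w, p$bott$b))
  db <- dim(bt)
  gap <- apply(bt, c(3L, 4L), mean)              # C x N
  emb_raw <- t(gap) %*% p$emb$w +
    matrix(p$emb$b, db[4L], length(p$emb$b), byrow = TRUE)
  nrm <- sqrt(rowSums(emb_raw^2)) + 1e-12
  emb <- emb_raw / nrm
  cache <- list(x = x, e1 = e1, p1 = p1, e2 = e2, p2 = p2, e3 = e3, p3 = p3,
                bt = bt, gap = gap, emb_raw = emb_raw, nrm = nrm, emb = emb)
  if (decoder) {
    u3 <- upsample2(bt); c3 <- concat_ch(u3, e3)
    d3 <- relu(conv2d_fwd(c3, p$dec3$w, p$dec3$b))
    u2 <- upsample2(d3); c2 <- concat_ch(u2, e2)
    d2 <- relu(conv2d_fwd(c2, p$dec2$w, p$dec2$b))
    u1 <- upsample2(d2); c1 <- concat_ch(u1, e1)
    d1 <- relu(conv2d_fwd(c1, p$dec1$w, p$dec1$b))
    pred <- conv2d_fwd(d1, p$outc$w, p$outc$b)
    cache <- c(cache, list(c3 = c3, d3 = d3, c2 = c2, d2 = d2,
                           c1 = c1, d1 = d1, pred = pred))
  }
  cache
}

zero_like <- function(p) rapply(p, function(a) a * 0, how = "replace")

grad_add <- function(a, b) {
  if (is.list(a)) return(mapply(grad_add, a, b, SIMPLIFY = FALSE))
  a + b
}

# backward pass. g_pred: gradient at the predicted map (or NULL);
# g_emb: gradient at the *normalized* embedding rows (or NULL).
net_bwd <- function(p, cache, g_pred = NULL, g_emb = NULL) {
  g <- zero_like(p)
  split_ch <- function(gc, n1) {
    list(gc[, , seq_len(n1), , drop = FALSE],
         gc[, , -seq_len(n1), , drop = FALSE])
  }
  g_e1s <- g_e2s <- g_e3s <- NULL
  g_bt <- array(0, dim(cache$bt))
  if (!is.null(g_pred)) {
    pp <- conv2d_bwd_params(cache$d1, g_pred, dim(p$outc$w)[1:2])
    g$outc$w <- g$outc$w + pp$gw; g$outc$b <- g$outc$b + pp$gb
    g_d1 <- relu_bwd(conv2d_bwd_input(g_pred, p$outc$w), cache$d1)
    pp <- conv2d_bwd_params(cache$c1, g_d1, dim(p$dec1$w)[1:2])
    g$dec1$w <- g$dec1$w + pp$gw; g$dec1$b <- g$dec1$b + pp$gb
    s <- split_ch(conv2d_bwd_input(g_d1, p$dec1$w), dim(cache$d2)[3L])
    g_e1s <- s[[2L]]
    g_d2 <- relu_bwd(upsample2_bwd(s[[1L]]), cache$d2)
    pp <- conv2d_bwd_params(cache$c2, g_d2, dim(p$dec2$w)[1:2])
    g$dec2$w <- g$dec2$w + pp$gw; g$dec2$b <- g$dec2$b + pp$gb
    s <- split_ch(conv2d_bwd_input(g_d2, p$dec2$w), dim(cache$d3)[3L])
    g_e2s <- s[[2L]]
    g_d3 <- relu_bwd(upsample2_bwd(s[[1L]]), cache$d3)
    pp <- conv2d_bwd_params(cache$c3, g_d3, dim(p$dec3$w)[1:2])
    g$dec3$w <- g$dec3$w + pp$gw; g$dec3$b <- g$dec3$b + pp$gb
    s <- split_ch(conv2d_bwd_input(g_d3, p$dec3$w), dim(cache$bt)[3L])
    g_e3s <- s[[2L]]
    g_bt <- g_bt + upsample2_bwd(s[[1L]])
  }
  if (!is.null(g_emb)) {
    # through L2 normalization: d(e/|e|) , then the linear head, then GAP
    z <- cache$emb
    g_raw <- (g_emb - z * rowSums(g_emb * z)) / cache$nrm
    g$emb$w <- g$emb$w + cache$gap %*% g_raw
    g$emb$b <- g$emb$b + colSums(g_raw)
    g_gap <- p$emb$w %*% t(g_raw)                 # C x N
    db <- dim(cache$bt)
    spatial <- db[1L] * db[2L]
    g_bt <- g_bt + aperm(array(rep(t(g_gap) / spatial, each = spatial),
                               c(db[1L], db[2L], db[4L], db[3L])),
                         c(1L, 2L, 4L, 3L))
  }
  g_bt <- relu_bwd(g_bt, cache$bt)
  pp <- conv2d_bwd_params(cache$p3, g_bt, dim(p$bott$w)[1:2])
  g$bott$w <- g$bott$w + pp$gw; g$bott$b <- g$bott$b + pp$gb
  g_e3 <- avgpool2_bwd(conv2d_bwd_input(g_bt, p$bott$w))
  if (!is.null(g_e3s)) g_e3 <- g_e3 + g_e3s
  g_e3 <- relu_bwd(g_e3, cache$e3)
  pp <- conv2d_bwd_params(cache$p2, g_e3, dim(p$enc3$w)[1:2])
  g$enc3$w <- g$enc3$w + pp$gw; g$enc3$b <- g$enc3$b + pp$gb
  g_e2 <- avgpool2_bwd(conv2d_bwd_input(g_e3, p$enc3$w))
  if (!is.null(g_e2s)) g_e2 <- g_e2 + g_e2s
  g_e2 <- relu_bwd(g_e2, cache$e2)
  pp <- conv2d_bwd_params(cache$p1, g_e2, dim(p$enc2$w)[1:2])
  g$enc2$w <- g$enc2$w + pp$gw; g$enc2$b <- g$enc2$b + pp$gb
  g_e1 <- avgpool2_bwd(conv2d_bwd_input(g_e2, p$enc2$w))
  if (!is.null(g_e1s)) g_e1 <- g_e1 + g_e1s
  g_e1 <- relu_bwd(g_e1, cache$e1)
  pp <- conv2d_bwd_params(cache$x, g_e1, dim(p$enc1$w)[1:2])
  g$enc1$w <- g$enc1$w + pp$gw; g$enc1$b <- g$enc1$b + pp$gb
  g
}

adam_init <- function(p) list(m = zero_like(p), v = zero_like(p), t = 0L)

adam_step <- function(p, g, st, lr = 3e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- function(pp, gg, mm, vv) {
    if (is.list(pp)) {
      out <- mapply(upd, pp, gg, mm, vv, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m2 <- beta1 * mm + (1 - beta1) * gg
    v2 <- beta2 * vv + (1 - beta2) * gg * gg
    mh <- m2 / (1 - beta1^st$t)
    vh <- v2 / (1 - beta2^st$t)
    list(p = pp - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
  out <- upd(p, g, st$m, st$v)
  attributes(out$p) <- attributes(p)
  list(p = out$p, state = list(m = out$m, v = out$v, t = st$t))
}

# bilinear resize of a matrix to new dimensions (used to run maps of a
# different resolution through a trained model)
resize_matrix <- function(m, new_dim) {
  if (identical(dim(m), as.integer(new_dim))) return(m)
  r <- seq(1, nrow(m), length.out = new_dim[1L])
  c <- seq(1, ncol(m), length.out = new_dim[2L])
  g <- expand.grid(r = r, c = c)
  matrix(bilinear_sample(m, g$r, g$c), new_dim[1L], new_dim[2L])
}
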