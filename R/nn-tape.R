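# A minimal define-by-run autodiff tape for channel-first 4D tensors.
#
# Every op computes its output eagerly and records what backward needs.
# tape_backward() walks the recorded nodes in reverse, accumulating
# gradients per node and per named parameter.  This is deliberately small:
# only the ops the U-Net, the ensemble head and Grad-CAM require.

tape_new <- function(train = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$train <- isTRUE(train)
  tp$named <- list()
  tp
}

.tape_add <- function(tp, value, op, parents = integer(), cache = list(),
                      param = NULL, name = NULL) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, op = op, parents = parents,
                         cache = cache, param = param, name = name)
  if (!is.null(name)) tp$named[[name]] <- id
  id
}

tape_value <- function(tp, id) {
  force(id)  # ids are often nested op calls that must append first
  tp$nodes[[id]]$value
}

tape_named_id <- function(tp, name) {
  id <- tp$named[[name]]
  if (is.null(id)) .stopf("no layer named '%s' in this model", name)
  id
}

op_input <- function(tp, x, name = NULL) .tape_add(tp, x, "input", name = name)

op_conv3d <- function(tp, id, w, b, k, param = NULL, name = NULL) {
  x <- tape_value(tp, id)
  y <- .conv3d_forward(x, dim(x), w, b, as.integer(k))
  .tape_add(tp, y, "conv3d", id,
            cache = list(w = w, k = as.integer(k), co = length(b),
                         xdim = dim(x)),
            param = param, name = name)
}

op_convt3d <- function(tp, id, w, b, param = NULL, name = NULL) {
  x <- tape_value(tp, id)
  y <- .convt3d_forward(x, dim(x), w, b)
  .tape_add(tp, y, "convt3d", id,
            cache = list(w = w, co = length(b), xdim = dim(x)),
            param = param, name = name)
}

op_relu <- function(tp, id, name = NULL) {
  x <- tape_value(tp, id)
  y <- x
  y[y < 0] <- 0
  .tape_add(tp, y, "relu", id, cache = list(pos = x > 0), name = name)
}

op_maxpool3d <- function(tp, id, name = NULL) {
  x <- tape_value(tp, id)
  sp <- dim(x)[-1L]
  if (any(sp %% 2L != 0L))
    .stopf("max pooling requires even spatial dims, got (%s)",
           paste(sp, collapse = ", "))
  r <- .maxpool3d_forward(x, dim(x))
  .tape_add(tp, r$y, "maxpool3d", id,
            cache = list(argmax = r$argmax, xdim = dim(x)), name = name)
}

op_concat <- function(tp, id1, id2, name = NULL) {
  a <- tape_value(tp, id1); b <- tape_value(tp, id2)
  da <- dim(a); db <- dim(b)
  if (!identical(da[-1L], db[-1L]))
    .stopf("concat: spatial dims differ")
  y <- array(0, c(da[1L] + db[1L], da[-1L]))
  y[seq_len(da[1L]), , , ] <- a
  y[da[1L] + seq_len(db[1L]), , , ] <- b
  .tape_add(tp, y, "concat", c(id1, id2),
            cache = list(c1 = da[1L], c2 = db[1L]), name = name)
}

# channel subset (used for modality routing); channels may repeat
op_select <- function(tp, id, channels, name = NULL) {
  x <- tape_value(tp, id)
  y <- x[channels, , , , drop = FALSE]
  dim(y) <- c(length(channels), dim(x)[-1L])
  .tape_add(tp, y, "select", id,
            cache = list(channels = channels, xdim = dim(x)), name = name)
}

op_dropout <- function(tp, id, rate, name = NULL) {
  x <- tape_value(tp, id)
  if (!tp$train || rate <= 0)
    return(.tape_add(tp, x, "identity", id, name = name))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  .tape_add(tp, x * keep, "dropout", id, cache = list(keep = keep),
            name = name)
}

# channel-wise softmax over dim 1
op_softmax <- function(tp, id, name = NULL) {
  x <- tape_value(tp, id)
  d <- dim(x)
  p <- array(.softmax_mat(matrix(x, nrow = d[1L])), d)
  .tape_add(tp, p, "softmax", id, cache = list(), name = name)
}

.softmax_mat <- function(m) {
  mx <- m[1L, ]
  if (nrow(m) > 1L) for (c in 2:nrow(m)) mx <- pmax(mx, m[c, ])
  e <- exp(m - rep(mx, each = nrow(m)))
  e / rep(colSums(e), each = nrow(m))
}

# Reverse-mode sweep from node `id` with gradient `seed`.
# Returns per-parameter gradients and (optionally) all node gradients.
tape_backward <- function(tp, id, seed, keep_node_grads = FALSE) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  grads[[id]] <- seed
  pgrads <- list()
  acc <- function(cur, add) if (is.null(cur)) add else cur + add

  for (i in seq(id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    switch(nd$op,
      input = NULL,
      identity = {
        grads[[nd$parents]] <- acc(grads[[nd$parents]], g)
      },
      relu = {
        grads[[nd$parents]] <- acc(grads[[nd$parents]], g * nd$cache$pos)
      },
      dropout = {
        grads[[nd$parents]] <- acc(grads[[nd$parents]], g * nd$cache$keep)
      },
      conv3d = {
        cc <- nd$cache
        gx <- .conv3d_backward_x(g, cc$xdim, cc$w, cc$k, cc$co)
        grads[[nd$parents]] <- acc(grads[[nd$parents]], gx)
        if (!is.null(nd$param)) {
          x <- tape_value(tp, nd$parents)
          gwb <- .conv3d_backward_w(x, cc$xdim, g, cc$k, cc$co)
          pgrads[[nd$param]] <-
            if (is.null(pgrads[[nd$param]])) gwb
            else list(gw = pgrads[[nd$param]]$gw + gwb$gw,
                      gb = pgrads[[nd$param]]$gb + gwb$gb)
        }
      },
      convt3d = {
        cc <- nd$cache
        gx <- .convt3d_backward_x(g, cc$xdim, cc$w, cc$co)
        grads[[nd$parents]] <- acc(grads[[nd$parents]], gx)
        if (!is.null(nd$param)) {
          x <- tape_value(tp, nd$parents)
          gwb <- .convt3d_backward_w(x, cc$xdim, g, cc$co)
          pgrads[[nd$param]] <-
            if (is.null(pgrads[[nd$param]])) gwb
            else list(gw = pgrads[[nd$param]]$gw + gwb$gw,
                      gb = pgrads[[nd$param]]$gb + gwb$gb)
        }
      },
      maxpool3d = {
        cc <- nd$cache
        gx <- .maxpool3d_backward(g, cc$argmax, cc$xdim)
        grads[[nd$parents]] <- acc(grads[[nd$parents]], gx)
      },
      select = {
        cc <- nd$cache
        gx <- array(0, cc$xdim)
        for (ci in seq_along(cc$channels)) {
          gslice <- g[ci, , , , drop = FALSE]
          dim(gslice) <- c(1L, dim(g)[-1L])
          gx[cc$channels[ci], , , ] <-
            gx[cc$channels[ci], , , ] + gslice[1L, , , ]
        }
        grads[[nd$parents]] <- acc(grads[[nd$parents]], gx)
      },
      concat = {
        cc <- nd$cache
        g1 <- g[seq_len(cc$c1), , , , drop = FALSE]
        g2 <- g[cc$c1 + seq_len(cc$c2), , , , drop = FALSE]
        dim(g1) <- c(cc$c1, dim(g)[-1L]); dim(g2) <- c(cc$c2, dim(g)[-1L])
        grads[[nd$parents[1L]]] <- acc(grads[[nd$parents[1L]]], g1)
        grads[[nd$parents[2L]]] <- acc(grads[[nd$parents[2L]]], g2)
      },
      softmax = {
        p <- nd$value
        d <- dim(p)
        pm <- matrix(p, nrow = d[1L]); gm <- matrix(g, nrow = d[1L])
        s <- colSums(gm * pm)
        gx <- array(pm * (gm - rep(s, each = d[1L])), d)
        grads[[nd$parents]] <- acc(grads[[nd$parents]], gx)
      },
      .stopf("tape: unknown op '%s'", nd$op)
    )
  }
  list(params = pgrads, nodes = if (keep_node_grads) grads else NULL)
}
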