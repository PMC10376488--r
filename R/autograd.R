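# Reverse-mode automatic differentiation on a dynamic tape.
#
# Values are plain R arrays with dim = c(N, H, W, C) (or matrices for the
# channel-vector paths such as squeeze-and-excitation).  Each differentiable
# op wraps its result in a node environment holding the value, a gradient
# slot and a backward closure; nodes are recorded on the active tape in
# creation order, which is a valid topological order of the DAG, so
# backpropagation is a single reverse sweep.

.af_env <- new.env(parent = emptyenv())
.af_env$tape <- NULL
.af_env$grad_enabled <- FALSE

ag_grad_enabled <- function() isTRUE(.af_env$grad_enabled)

#' @keywords internal
ag_tape_begin <- function() {
  .af_env$tape <- new.env(parent = emptyenv())
  .af_env$tape$nodes <- vector("list", 256L)
  .af_env$tape$n <- 0L
  .af_env$grad_enabled <- TRUE
  invisible(.af_env$tape)
}

ag_tape_end <- function() {
  .af_env$tape <- NULL
  .af_env$grad_enabled <- FALSE
  invisible(NULL)
}

ag_record <- function(node) {
  tp <- .af_env$tape
  if (is.null(tp)) return(invisible(node))
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- node
  invisible(node)
}

# A node: value + grad accumulator + backward closure over cached inputs.
ag_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  class(nd) <- "ag_node"
  if (!is.null(backward)) ag_record(nd)
  nd
}

# A parameter: a leaf node that persists across tape lifetimes.
ag_param <- function(value, name = "", trainable = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd$name <- name
  nd$trainable <- trainable
  class(nd) <- c("ag_param", "ag_node")
  nd
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x
as_node <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"))
  tp <- .af_env$tape
  if (is.null(tp)) stop("no active tape; call ag_tape_begin() first")
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- differentiable ops ----------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else as.numeric(ag_value(b))
  out <- nn_conv2d(xv, wv, bv, as.integer(stride), as.integer(dilation))
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    gr <- nn_conv2d_backward(xv, wv, g, as.integer(stride),
                             as.integer(dilation), !is.null(b))
    if (inherits(x, "ag_node")) ag_accum(x, gr$gx)
    if (inherits(w, "ag_node")) ag_accum(w, gr$gw)
    if (!is.null(b) && inherits(b, "ag_node")) ag_accum(b, gr$gb)
  })
}

ag_conv2d_transpose <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else as.numeric(ag_value(b))
  out <- nn_conv2d_transpose2(xv, wv, bv)
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    gr <- nn_conv2d_transpose2_backward(xv, wv, g, !is.null(b))
    if (inherits(x, "ag_node")) ag_accum(x, gr$gx)
    if (inherits(w, "ag_node")) ag_accum(w, gr$gw)
    if (!is.null(b) && inherits(b, "ag_node")) ag_accum(b, gr$gb)
  })
}

ag_maxpool2 <- function(x) {
  xv <- ag_value(x)
  mp <- nn_maxpool2(xv)
  if (!ag_grad_enabled()) return(ag_node(mp$out))
  xd <- dim(xv)
  ag_node(mp$out, backward = function(g) {
    if (inherits(x, "ag_node"))
      ag_accum(x, nn_maxpool2_backward(mp$idx, g, as.integer(xd)))
  })
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  out <- pmax(xv, 0)
  dim(out) <- dim(xv)
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) ag_accum(x, g * (xv > 0))
  })
}

ag_sigmoid <- function(x) {
  xv <- ag_value(x)
  s <- 1 / (1 + exp(-xv))
  dim(s) <- dim(xv)
  if (!ag_grad_enabled()) return(ag_node(s))
  ag_node(s, backward = function(g) {
    if (inherits(x, "ag_node")) ag_accum(x, g * s * (1 - s))
  })
}

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  out <- av + bv
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(a, "ag_node")) ag_accum(a, g)
    if (inherits(b, "ag_node")) ag_accum(b, g)
  })
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  out <- av * bv
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(a, "ag_node")) ag_accum(a, g * bv)
    if (inherits(b, "ag_node")) ag_accum(b, g * av)
  })
}

# Multiply a feature map (N,H,W,C) by per-channel gates (N,C).
ag_scale_channels <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dim(xv); n <- d[1]; hw <- d[2] * d[3]; c <- d[4]
  expand <- function(g) {
    # (N,C) -> (N,H,W,C) by repeating over the spatial block
    out <- g[, rep(seq_len(c), each = hw), drop = FALSE]
    dim(out) <- d
    out
  }
  ge <- expand(gv)
  out <- xv * ge
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) ag_accum(x, g * ge)
    if (inherits(gate, "ag_node")) {
      gg <- g * xv
      dim(gg) <- c(n, hw, c)
      ag_accum(gate, apply(gg, c(1, 3), sum))
    }
  })
}

# Global average pool (N,H,W,C) -> (N,C).
ag_global_avg_pool <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); n <- d[1]; hw <- d[2] * d[3]; c <- d[4]
  xm <- xv
  dim(xm) <- c(n, hw, c)
  out <- apply(xm, c(1, 3), mean)
  dim(out) <- c(n, c)
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) {
      ge <- g[, rep(seq_len(c), each = hw), drop = FALSE] / hw
      dim(ge) <- d
      ag_accum(x, ge)
    }
  })
}

# Broadcast per-channel vectors (N,C) back to (N,H,W,C); the "resize back"
# step of the pooled pyramid path.
ag_broadcast_spatial <- function(x, h, w) {
  xv <- ag_value(x)
  n <- dim(xv)[1]; c <- dim(xv)[2]; hw <- h * w
  out <- xv[, rep(seq_len(c), each = hw), drop = FALSE]
  dim(out) <- c(n, h, w, c)
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) {
      dim(g) <- c(n, hw, c)
      ag_accum(x, apply(g, c(1, 3), sum))
    }
  })
}

# Dense layer on (N,C) matrices.
ag_dense <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  out <- xv %*% wv
  if (!is.null(b)) out <- sweep(out, 2, as.numeric(ag_value(b)), "+")
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) ag_accum(x, g %*% t(wv))
    if (inherits(w, "ag_node")) ag_accum(w, t(xv) %*% g)
    if (!is.null(b) && inherits(b, "ag_node")) ag_accum(b, colSums(g))
  })
}

# Channel concatenation of (N,H,W,Ca) and (N,H,W,Cb).
ag_concat_channels <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- c(av, bv)
  dim(out) <- c(da[1:3], da[4] + db[4])
  if (!ag_grad_enabled()) return(ag_node(out))
  na <- length(av)
  ag_node(out, backward = function(g) {
    if (inherits(a, "ag_node")) {
      ga <- g[seq_len(na)]; dim(ga) <- da; ag_accum(a, ga)
    }
    if (inherits(b, "ag_node")) {
      gb <- g[-seq_len(na)]; dim(gb) <- db; ag_accum(b, gb)
    }
  })
}

# Nearest-neighbour x2 upsampling.
ag_upsample_nearest2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  ih <- rep(seq_len(d[2]), each = 2); iw <- rep(seq_len(d[3]), each = 2)
  out <- xv[, ih, iw, , drop = FALSE]
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(x, "ag_node")) {
      # sum the 2x2 blocks back
      gs <- g[, seq(1, 2 * d[2], 2), seq(1, 2 * d[3], 2), , drop = FALSE] +
            g[, seq(2, 2 * d[2], 2), seq(1, 2 * d[3], 2), , drop = FALSE] +
            g[, seq(1, 2 * d[2], 2), seq(2, 2 * d[3], 2), , drop = FALSE] +
            g[, seq(2, 2 * d[2], 2), seq(2, 2 * d[3], 2), , drop = FALSE]
      ag_accum(x, gs)
    }
  })
}

# Batch normalization over (N,H,W) per channel.  In training mode uses batch
# statistics and updates the layer's running estimates in place; in
# evaluation mode uses the running estimates (no gradient flows then).
ag_batchnorm <- function(x, gamma, beta, layer, training) {
  xv <- ag_value(x)
  d <- dim(xv); c <- d[4]; m <- prod(d[1:3])
  xm <- xv
  dim(xm) <- c(m, c)
  gv <- as.numeric(ag_value(gamma)); bv <- as.numeric(ag_value(beta))
  eps <- layer$eps
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    layer$params$running_mean$value <- layer$momentum * layer$params$running_mean$value +
      (1 - layer$momentum) * mu
    layer$params$running_var$value <- layer$momentum * layer$params$running_var$value +
      (1 - layer$momentum) * va
  } else {
    mu <- as.numeric(layer$params$running_mean$value)
    va <- as.numeric(layer$params$running_var$value)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  dim(out) <- d
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    dim(g) <- c(m, c)
    if (inherits(gamma, "ag_node")) ag_accum(gamma, colSums(g * xhat))
    if (inherits(beta, "ag_node")) ag_accum(beta, colSums(g))
    if (inherits(x, "ag_node")) {
      if (training) {
        gxh <- sweep(g, 2, gv, "*")
        s1 <- colMeans(gxh)
        s2 <- colMeans(gxh * xhat)
        gx <- sweep(gxh, 2, s1, "-") - sweep(xhat, 2, s2, "*")
        gx <- sweep(gx, 2, inv, "*")
      } else {
        gx <- sweep(sweep(g, 2, gv, "*"), 2, inv, "*")
      }
      dim(gx) <- d
      ag_accum(x, gx)
    }
  })
}

# Soft dice loss between predicted probabilities and a binary target.
ag_dice_loss <- function(p, target, smooth = 1e-6) {
  pv <- ag_value(p)
  tv <- as.numeric(target)
  num <- 2 * sum(pv * tv) + smooth
  den <- sum(pv) + sum(tv) + smooth
  out <- 1 - num / den
  if (!ag_grad_enabled()) return(ag_node(out))
  ag_node(out, backward = function(g) {
    if (inherits(p, "ag_node")) {
      gp <- g * (num / den^2 - 2 * tv / den)
      dim(gp) <- dim(pv)
      ag_accum(p, gp)
    }
  })
}
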