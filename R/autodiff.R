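#' @name autodiff
#' @title Reverse-mode automatic differentiation core
#'
#' @description
#' A compact tape-based reverse-mode autodiff engine used by every layer of
#' the network. Tensors are environments holding a dense numeric array, an
#' accumulated gradient, and a backward closure; operations build the graph
#' implicitly. Feature maps are stored as `[H, W, C, N]` arrays (height,
#' width, channel, batch) throughout the package.
#'
#' The engine is deliberately minimal: dense arrays only, no broadcasting
#' beyond the explicit gate/bias ops the network needs, and a single
#' synchronous tape. All heavy kernels reduce to BLAS matrix products.
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L
.ag$macs <- 0
.ag$count_macs <- FALSE

#' Create a tensor node
#'
#' @param value numeric array (any shape; scalars allowed).
#' @param requires_grad should gradients be accumulated into this node?
#' @return an object of class `agTensor`.
#' @keywords internal
agTensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- NULL
  e$bwd <- NULL
  e$rg <- isTRUE(requires_grad)
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  class(e) <- "agTensor"
  e
}

agIs <- function(x) inherits(x, "agTensor")
agValue <- function(x) if (agIs(x)) x$value else x

# Wrap the result of an operation. `bwd` receives the output gradient and
# returns a list of gradients aligned with `parents` (NULL entries allowed).
# The backward closure is only retained when some parent needs gradients, so
# inference-mode graphs carry no tape.
agOp <- function(value, parents, bwd) {
  rg <- FALSE
  for (p in parents) if (p$rg) { rg <- TRUE; break }
  t <- agTensor(value, requires_grad = rg)
  if (rg) {
    t$parents <- parents
    t$bwd <- bwd
  }
  t
}

asAg <- function(x) if (agIs(x)) x else agTensor(x, requires_grad = FALSE)

#' Run backpropagation from a root node
#'
#' Accumulates gradients into every reachable node with `requires_grad`.
#' Creation order doubles as a topological order because parents always
#' precede children on the tape.
#' @param root the output node (typically a scalar loss).
#' @param grad seed gradient; defaults to 1 (or an array of ones).
#' @keywords internal
agBackward <- function(root, grad = NULL) {
  if (!root$rg) stop("root does not require gradients")
  if (is.null(grad)) {
    grad <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  }
  nodes <- vector("list", 512L)
  n <- 0L
  seen <- new.env(parent = emptyenv(), size = 1024L)
  stack <- vector("list", 512L)
  sp <- 1L
  stack[[1L]] <- root
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    n <- n + 1L
    if (n > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n]] <- nd
    nd$grad <- NULL
    if (!is.null(nd$parents)) {
      for (p in nd$parents) {
        if (p$rg) {
          sp <- sp + 1L
          if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[sp]] <- p
        }
      }
    }
  }
  nodes <- nodes[seq_len(n)]
  ord <- order(vapply(nodes, function(x) x$id, integer(1)), decreasing = TRUE)
  root$grad <- grad
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$bwd) || is.null(nd$grad)) next
    gs <- nd$bwd(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      g <- gs[[k]]
      if (p$rg && !is.null(g)) {
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    # release the tape as we consume it
    nd$bwd <- NULL
    nd$parents <- NULL
    if (!identical(nd, root)) nd$grad <- NULL
  }
  invisible(root)
}

## ---- elementwise and scalar ops ------------------------------------------

agAdd <- function(a, b) {
  a <- asAg(a); b <- asAg(b)
  agOp(a$value + b$value, list(a, b), function(g) list(g, g))
}

agMul <- function(a, b) {
  a <- asAg(a); b <- asAg(b)
  av <- a$value; bv <- b$value
  agOp(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

agScale <- function(a, s) {
  agOp(a$value * s, list(a), function(g) list(g * s))
}

agAddScalar <- function(a, s) agOp(a$value + s, list(a), function(g) list(g))

agSum <- function(a) {
  d <- dim(a$value)
  agOp(sum(a$value), list(a), function(g) {
    list(if (is.null(d)) rep(g, length(a$value)) else array(g, d))
  })
}

agMean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  agOp(mean(a$value), list(a), function(g) {
    list(if (is.null(d)) rep(g / n, n) else array(g / n, d))
  })
}

agRelu <- function(a) {
  v <- a$value
  m <- v > 0
  agOp(v * m, list(a), function(g) list(g * m))
}

agSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  agOp(s, list(a), function(g) list(g * s * (1 - s)))
}

## ---- linear algebra ------------------------------------------------------

# counted matrix product: every call adds m*k*n multiply-accumulates to the
# global counter when counting is switched on (used by the complexity probes)
mmCounted <- function(a, b) {
  if (.ag$count_macs) {
    .ag$macs <- .ag$macs + as.numeric(nrow(a)) * ncol(a) * ncol(b)
  }
  a %*% b
}

macCounterReset <- function() {
  .ag$macs <- 0
  .ag$count_macs <- TRUE
  invisible(NULL)
}

macCounterRead <- function() {
  .ag$count_macs <- FALSE
  .ag$macs
}

agMatmul <- function(a, b) {
  a <- asAg(a); b <- asAg(b)
  av <- a$value; bv <- b$value
  agOp(mmCounted(av, bv), list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# x: [rows, Cin]; W: [Cin, Cout]; b: length Cout or NULL
agLinear <- function(x, W, b = NULL) {
  y <- agMatmul(x, W)
  if (is.null(b)) return(y)
  b <- asAg(b)
  bv <- b$value
  agOp(sweep(y$value, 2L, bv, "+"), list(y, b), function(g) {
    list(g, colSums(g))
  })
}

## ---- shape ops -----------------------------------------------------------

agReshape <- function(a, newdim) {
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  agOp(v, list(a), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

agAperm <- function(a, perm) {
  inv <- order(perm)
  agOp(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# concatenate two [H,W,C,N] maps along the channel axis
agConcatC <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 4L, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- av
  out[, , da[3] + seq_len(db[3]), ] <- bv
  agOp(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# column subset of a matrix (used to split attention heads)
agCols <- function(a, idx) {
  v <- a$value
  d <- dim(v)
  agOp(v[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, d[1], d[2])
    out[, idx] <- g
    list(out)
  })
}

# row-wise softmax of a matrix (softmax over the key axis of attention)
agSoftmaxRows <- function(a) {
  v <- a$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  agOp(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

## ---- gradient checking helper -------------------------------------------

# central finite differences against an arbitrary scalar-valued builder;
# used by the test suite to validate every layer's backward pass
agGradCheck <- function(f, xs, eps = 1e-5) {
  ts <- lapply(xs, agTensor, requires_grad = TRUE)
  out <- f(ts)
  agBackward(out)
  ana <- lapply(ts, function(t) t$grad)
  num <- lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    g <- x
    g[] <- 0
    for (k in seq_along(x)) {
      xp <- x; xp[k] <- xp[k] + eps
      xm <- x; xm[k] <- xm[k] - eps
      xsp <- xs; xsp[[i]] <- xp
      xsm <- xs; xsm[[i]] <- xm
      fp <- f(lapply(xsp, agTensor, requires_grad = FALSE))
      fm <- f(lapply(xsm, agTensor, requires_grad = FALSE))
      g[k] <- (agValue(fp) - agValue(fm)) / (2 * eps)
    }
    g
  })
  list(analytic = ana, numeric = num)
}
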