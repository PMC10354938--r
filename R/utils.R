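#' @name utils
#' @title Parameter-tree helpers
#' @description
#' Network parameters are nested named lists whose numeric leaves are the
#' trainable arrays; batch-norm running statistics live in environments at
#' the same tree positions and are not trainable. These helpers wrap a tree
#' into autodiff tensors, read gradients back out, and serialize state.
#' @keywords internal
NULL

# wrap numeric leaves as agTensors; environments (BN state) and scalars of
# bookkeeping (configs, integers named 'stride' etc.) pass through untouched
wrapParamTree <- function(p, requires_grad = FALSE) {
  if (is.list(p) && !inherits(p, "attentionConfig") && !inherits(p, "resStageConfig")) {
    return(lapply(p, wrapParamTree, requires_grad = requires_grad))
  }
  if (is.numeric(p) && length(p) > 0L && is.null(attr(p, "noTrain"))) {
    if (is.integer(p)) return(p)   # structural integers are not parameters
    return(agTensor(p, requires_grad = requires_grad))
  }
  p
}

# walk a wrapped tree and a visitor over its agTensor leaves; path is the
# dotted name chain, used as optimizer-state key
walkAgLeaves <- function(p, fn, path = "") {
  if (agIs(p)) {
    fn(p, path)
    return(invisible(NULL))
  }
  if (is.list(p) && !inherits(p, "attentionConfig") && !inherits(p, "resStageConfig")) {
    nm <- names(p)
    for (i in seq_along(p)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      walkAgLeaves(p[[i]], fn, paste0(path, ".", key))
    }
  }
  invisible(NULL)
}

# deep-copy a parameter tree, materializing BN state environments as lists
# (used by checkpointing) and back
paramTreeToList <- function(p) {
  if (is.environment(p)) {
    return(structure(list(running_mean = p$running_mean,
                          running_var = p$running_var),
                     class = "bnStateList"))
  }
  if (is.list(p) && !inherits(p, c("attentionConfig", "resStageConfig", "bnStateList"))) {
    return(lapply(p, paramTreeToList))
  }
  p
}

paramTreeFromList <- function(p) {
  if (inherits(p, "bnStateList")) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- p$running_mean
    e$running_var <- p$running_var
    return(e)
  }
  if (is.list(p) && !inherits(p, c("attentionConfig", "resStageConfig"))) {
    return(lapply(p, paramTreeFromList))
  }
  p
}

# derive a child RNG seed from (seed, index) that stays inside 32-bit range
deriveSeed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
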