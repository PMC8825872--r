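# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
# All randomness in the package flows through this, so a single config seed
# determines every draw without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  force(expr)
}

# Recursively apply f over the numeric leaves of parallel nested lists.
# Used for optimizer updates and gradient accumulation over parameter trees.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# Sum of f applied to every numeric leaf (e.g. for global gradient norms)
tree_reduce_sum <- function(f, tree) {
  if (is.list(tree)) {
    sum(vapply(tree, function(x) tree_reduce_sum(f, x), numeric(1)))
  } else {
    f(tree)
  }
}

relu <- function(x) pmax(x, 0)
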