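# Utilities over nested parameter trees: plain nested lists whose numeric
# leaves are the trainable arrays. Environments (batch-norm running stats)
# live in the same trees but are never treated as leaves. Gradient trees
# mirror the parameter tree but may hold NULL where a branch received no
# gradient; all helpers treat NULL as "absent".

nl_is_leaf <- function(x) is.numeric(x)

# Combine matching numeric leaves of a and b with f. Unnamed list branches
# are matched by position (they always have equal lengths, with NULL
# padding); named branches by name. A NULL on either side yields the other.
nl_map2 <- function(a, b, f) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (nl_is_leaf(a)) return(f(a, b))
  if (is.environment(a)) return(a)
  out <- a
  keys <- if (!is.null(names(a)) || !is.null(names(b))) {
    union(names(a), names(b))
  } else {
    seq_len(max(length(a), length(b)))
  }
  for (k in keys) {
    bk <- if (is.character(k) && !k %in% names(b)) NULL else b[[k]]
    ak <- if (is.character(k) && !k %in% names(a)) NULL else a[[k]]
    r <- nl_map2(ak, bk, f)
    if (!is.null(r)) out[[k]] <- r
  }
  out
}

nl_map <- function(a, f) {
  if (is.null(a)) return(NULL)
  if (nl_is_leaf(a)) return(f(a))
  if (is.environment(a)) return(a)
  out <- a
  keys <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (k in keys) {
    r <- nl_map(a[[k]], f)
    if (!is.null(r)) out[[k]] <- r
  }
  out
}

nl_add <- function(a, b) nl_map2(a, b, `+`)

nl_zero_like <- function(a) nl_map(a, function(x) x * 0)

# Named flat list of numeric leaves, names are /-separated paths.
nl_leaves <- function(a, path = character()) {
  if (is.null(a)) return(list())
  if (nl_is_leaf(a)) return(setNames(list(a), paste(path, collapse = "/")))
  if (is.environment(a)) return(list())
  out <- list()
  keys <- if (!is.null(names(a))) names(a) else as.character(seq_along(a))
  for (i in seq_along(keys)) {
    out <- c(out, nl_leaves(a[[i]], c(path, keys[i])))
  }
  out
}

nl_sumsq <- function(a) sum(vapply(nl_leaves(a), function(x) sum(x^2), numeric(1)))

# Shape fingerprint used to guard checkpoint loading.
nl_shapes <- function(a) lapply(nl_leaves(a), function(x) dim(x) %||% length(x))

`%||%` <- function(x, y) if (is.null(x)) y else x
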