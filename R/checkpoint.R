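#' Save a model checkpoint
#'
#' Serializes parameters (including batch-norm running statistics), the
#' model description, the run configuration snapshot, epoch, RNG state and
#' metric history. The round trip is bit-exact.
#'
#' @param model A `narm_teacher` or `narm_student`.
#' @param path Destination file (RDS).
#' @param config Optional `run_config` snapshot.
#' @param epoch Optional epoch counter.
#' @param history Optional metric history (e.g. a training log).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, config = NULL, epoch = NULL,
                            history = NULL) {
  # materialize batch-norm environments so the file is self-contained
  freeze <- function(x) {
    if (is.environment(x)) return(list(.bn_rs = as.list(x)))
    if (is.list(x)) return(lapply(x, freeze))
    x
  }
  obj <- list(class = class(model)[1],
              model = model[setdiff(names(model), c("params", "audit"))],
              params = freeze(model$params),
              shapes = nl_shapes(model$params),
              config = config, epoch = epoch,
              rng = if (exists(".Random.seed", globalenv())) {
                get(".Random.seed", globalenv())
              },
              history = history)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Restores a model saved with [save_checkpoint()]. If `into` is given,
#' its architecture fingerprint (the full set of parameter shapes) must
#' match; mismatches are refused with a shape diff.
#'
#' @param path Checkpoint file.
#' @param into Optional existing model to load the parameters into.
#' @param restore_rng Restore the RNG state stored in the checkpoint.
#' @return The restored model, with `config`, `epoch` and `history`
#'   attached as attributes.
#' @export
load_checkpoint <- function(path, into = NULL, restore_rng = FALSE) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  thaw <- function(x) {
    if (is.list(x) && identical(names(x), ".bn_rs")) {
      e <- new.env(parent = emptyenv())
      for (nm in names(x$.bn_rs)) assign(nm, x$.bn_rs[[nm]], e)
      return(e)
    }
    if (is.list(x)) return(lapply(x, thaw))
    x
  }
  params <- thaw(obj$params)
  if (!is.null(into)) {
    want <- nl_shapes(into$params)
    have <- obj$shapes
    if (!identical(want, have)) {
      only_w <- setdiff(names(want), names(have))
      only_h <- setdiff(names(have), names(want))
      both <- intersect(names(want), names(have))
      diff <- both[!mapply(identical, want[both], have[both])]
      stop("architecture fingerprint mismatch; differing leaves: ",
           paste(c(diff, only_w, only_h), collapse = ", "))
    }
    model <- into
    model$params <- params
  } else {
    model <- c(obj$model, list(params = params))
    class(model) <- obj$class
    if (obj$class == "narm_teacher") {
      audit <- new.env(parent = emptyenv())
      audit$backwards <- character(0)
      model$audit <- audit
    }
  }
  if (restore_rng && !is.null(obj$rng)) {
    assign(".Random.seed", obj$rng, globalenv())
  }
  attr(model, "config") <- obj$config
  attr(model, "epoch") <- obj$epoch
  attr(model, "history") <- obj$history
  model
}
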