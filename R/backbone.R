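#' Backbone specification
#'
#' Describes a stage-wise convolutional backbone: an ordered list of stages
#' (output channels, dyadic downsampling factor) and the suffix of stages
#' tapped by NARMs. Two presets are provided: `"tiny"` (3 stages, for desk
#' scale work and the test-suite) and `"resnet50-like"` (5 stages with the
#' channel/stride layout of a ResNet-50, exposed as the same stage
#' template).
#'
#' @param preset `"tiny"` or `"resnet50-like"`.
#' @param n_taps How many trailing stages feed NARMs; defaults to 2 for
#'   `"tiny"` and 3 for `"resnet50-like"` (the last-three-stages setting).
#' @param channels Optional integer vector overriding per-stage channels.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(preset = c("tiny", "resnet50-like"),
                          n_taps = NULL, channels = NULL) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    channels <- channels %||% c(8L, 16L, 32L)
    n_taps <- n_taps %||% 2L
  } else {
    channels <- channels %||% c(64L, 256L, 512L, 1024L, 2048L)
    n_taps <- n_taps %||% 3L
  }
  n <- length(channels)
  if (n_taps < 1 || n_taps > n) stop("n_taps must be in 1..", n)
  structure(list(preset = preset, channels = as.integer(channels),
                 factors = rep(2L, n),
                 taps = seq.int(n - n_taps + 1L, n)),
            class = "backbone_spec")
}

#' Build a stage-tapped backbone
#'
#' Instantiates backbone parameters for a [backbone_spec()] and returns a
#' callable that maps an image batch to the ordered list of all stage
#' feature maps. Each stage is conv 3x3 -> BatchNorm -> ReLU -> 2x2 average
#' pooling. Initialisation is fully determined by the R random seed in
#' effect.
#'
#' @param spec A [backbone_spec()], or a preset name.
#' @return List with `params`, `spec`, and `forward(x, training)`.
#' @export
build_backbone <- function(spec = backbone_spec("tiny")) {
  if (is.character(spec)) spec <- backbone_spec(spec)
  stopifnot(inherits(spec, "backbone_spec"))
  params <- init_backbone(spec)
  list(params = params, spec = spec,
       forward = function(x, training = FALSE) {
         backbone_forward(params, spec, x, training)$stages
       })
}

init_backbone <- function(spec) {
  cin <- 3L
  stages <- list()
  for (s in seq_along(spec$channels)) {
    stages[[paste0("stage", s)]] <-
      list(conv = nn_conv_init(3, 3, cin, spec$channels[s]),
           bn = nn_bn_init(spec$channels[s]))
    cin <- spec$channels[s]
  }
  stages
}

backbone_forward <- function(params, spec, x, training = FALSE) {
  x <- as_batch(x)
  stages <- list()
  caches <- list()
  h <- x
  for (s in seq_along(spec$channels)) {
    p <- params[[paste0("stage", s)]]
    cv <- nn_conv_fwd(p$conv, h, 1, 1)
    bn <- nn_bn_fwd(p$bn, cv$out, training)
    rl <- nn_relu_fwd(bn$out)
    pl <- nn_pool_fwd(rl$out, spec$factors[s])
    caches[[s]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                        pl = pl$cache)
    h <- pl$out
    stages[[s]] <- h
  }
  list(stages = stages, cache = caches)
}

# stage_grads: list over stages (NULL entries allowed). Gradients are
# propagated from the deepest non-NULL stage down to the input, adding each
# stage's external gradient where present. Parameter grads are accumulated.
backbone_backward <- function(params, spec, cache, stage_grads) {
  n <- length(spec$channels)
  grads <- list()
  g <- NULL
  for (s in rev(seq_len(n))) {
    ext <- if (s <= length(stage_grads)) stage_grads[[s]] else NULL
    if (is.null(g) && is.null(ext)) next
    g <- if (is.null(g)) ext else if (is.null(ext)) g else g + ext
    p <- params[[paste0("stage", s)]]
    cc <- cache[[s]]
    gpool <- nn_pool_bwd(cc$pl, g)
    grl <- nn_relu_bwd(cc$rl, gpool)
    bbn <- nn_bn_bwd(p$bn, cc$bn, grl)
    bcv <- nn_conv_bwd(p$conv, cc$cv, bbn$gx)
    grads[[paste0("stage", s)]] <- list(conv = bcv$grads, bn = bbn$grads)
    g <- bcv$gx
  }
  list(gx = g, grads = grads)
}

# spatial side of stage s for a square input of side `input_size`
stage_side <- function(spec, s, input_size) {
  as.integer(input_size / prod(spec$factors[seq_len(s)]))
}
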