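default_run_config <- function() {
  list(
    data = list(dir = NULL, n_classes = 3L, per_class = 50L,
                image_size = 64L, split = c(0.6, 0.1, 0.3)),
    model = list(backbone = "tiny", n_taps = 2L,
                 feature_channels = 16L, head_hidden = 256L,
                 restore_channels = 64L, epsilon = 1e-5),
    training = list(lr0 = 0.002, epochs = 200L, batch_size = 32L,
                    momentum = 0.9, alpha = 0.6, beta = 0.4, seed = 1L),
    fusion = list(betas = c(0.2, 0.35, 0.45), projection_channels = NULL),
    distill = list(alpha = 0.5, T_start = 0.5, T_end = 2.0,
                   phase_1_epochs = 8L, phase_2_epochs = 2L,
                   feature_align_weight = 0.1),
    noise = list(sigma = 0.10, clip = TRUE, apply_to = "train"),
    eval = list(top_k = c(1L, 5L), n_seeds = 5L)
  )
}

validate_run_config <- function(cfg) {
  checks <- list(
    c("training", "lr0"), c("training", "epochs"),
    c("training", "batch_size"), c("noise", "sigma"),
    c("model", "epsilon")
  )
  pos <- function(path, strict = TRUE) {
    v <- cfg[[path[1]]][[path[2]]]
    ok <- is.numeric(v) && length(v) == 1 &&
      (if (strict) v > 0 else v >= 0)
    if (!ok) stop(sprintf("invalid value for key %s.%s",
                          path[1], path[2]))
  }
  pos(c("training", "lr0")); pos(c("training", "epochs"))
  pos(c("training", "batch_size")); pos(c("model", "epsilon"))
  pos(c("noise", "sigma"), strict = FALSE)
  if (any(cfg$fusion$betas < 0)) stop("invalid value for key fusion.betas")
  if (cfg$distill$alpha < 0 || cfg$distill$alpha > 1) {
    stop("invalid value for key distill.alpha")
  }
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the package defaults (the standard
#' training recipe: D = 1024 / D' = 256 / D'' = 64 at full scale, fusion
#' betas 0.2/0.35/0.45, loss weights 0.6/0.4, distillation alpha 0.5,
#' sigma = 0.10, lr 0.002, batch size 32). Unknown keys are rejected with
#' the offending key named.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated nested configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        stop("unknown config section: ", section)
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          stop(sprintf("unknown config key: %s.%s", section, key))
        }
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    }
    attr(cfg, "source") <- normalizePath(path)
  }
  cfg <- validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
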