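#' Default pipeline configuration
#'
#' All tunable keys of the pipeline in one nested list:
#' `preprocess$first$N/wn`, `preprocess$second$N/wn`,
#' `preprocess$normalize`, `preprocess$peak_prominence_frac`, `crests$*`,
#' `capsnet$*`, `training$*`, `split$*`.
#'
#' @return nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(preprocess = list(first = list(N = 2L, wn = 0.002),
                         second = list(N = 2L, wn = 0.03),
                         normalize = TRUE,
                         peak_prominence_frac = 0.05),
       crests = list(shifts = c(480, 865, 941, 1129, 1339, 1461, 2910),
                     points_before = 56L, points_after = 55L,
                     segment_length = 28L),
       capsnet = list(conv1_channels = 256L, primary_channels = 256L,
                      primary_caps_dim = 8L, n_classes = 3L,
                      class_caps_dim = 16L, routing_iterations = 3L,
                      m_plus = 0.9, m_minus = 0.1, lambda = 0.5),
       training = list(epochs = 160L, batch_size = 16L,
                       learning_rate = 1e-3, eval_every = 1L,
                       screen_outliers = FALSE, z_threshold = 3),
       split = list(per_variety_test = 8L))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML document and merges it (recursively) over
#' [default_pipeline_config()], so a file needs to mention only the keys it
#' changes.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_rec(cfg, user)
}

#' Build typed objects from a pipeline configuration
#'
#' @param cfg nested list as returned by [load_config()].
#' @return list with `first`/`second` [filter_spec()]s, `crests`
#'   [crest_config()], `capsnet` [capsnet_config()], `training`
#'   [train_config()], plus the raw list.
#' @export
resolve_config <- function(cfg = default_pipeline_config()) {
  list(first = filter_spec(cfg$preprocess$first$N, cfg$preprocess$first$wn),
       second = filter_spec(cfg$preprocess$second$N,
                            cfg$preprocess$second$wn),
       normalize = isTRUE(cfg$preprocess$normalize),
       crests = crest_config(
         reference_shifts = cfg$crests$shifts,
         points_before = cfg$crests$points_before,
         points_after = cfg$crests$points_after,
         segment_length = cfg$crests$segment_length,
         segments_per_window = (cfg$crests$points_before +
                                  cfg$crests$points_after + 1L) %/%
           cfg$crests$segment_length),
       capsnet = capsnet_config(
         conv1_channels = cfg$capsnet$conv1_channels,
         primary_channels = cfg$capsnet$primary_channels,
         primary_caps_dim = cfg$capsnet$primary_caps_dim,
         n_classes = cfg$capsnet$n_classes,
         class_caps_dim = cfg$capsnet$class_caps_dim,
         routing_iterations = cfg$capsnet$routing_iterations,
         m_plus = cfg$capsnet$m_plus, m_minus = cfg$capsnet$m_minus,
         lambda = cfg$capsnet$lambda),
       training = train_config(
         epochs = cfg$training$epochs, batch_size = cfg$training$batch_size,
         learning_rate = cfg$training$learning_rate,
         eval_every = cfg$training$eval_every),
       raw = cfg)
}
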