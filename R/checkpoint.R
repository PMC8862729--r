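#' Save model parameters to a JSON checkpoint
#'
#' The checkpoint is a plain-text archive holding the configuration block
#' and all weights as one flat numeric array; loading validates the value
#' count against the configuration.
#'
#' @param params A \code{"model_params"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_model <- function(params, path) {
  cfg <- unclass(params$config)
  flat <- as.numeric(unlist(numeric_part(params), use.names = FALSE))
  jsonlite::write_json(list(config = cfg, n_values = length(flat),
                            values = flat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load model parameters from a JSON checkpoint
#'
#' @param path Checkpoint path written by \code{save_model}.
#' @return A \code{"model_params"}.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  j <- jsonlite::fromJSON(path)
  cfg <- do.call(model_config, j$config)
  # build a shape skeleton without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(0)
  skeleton <- init_params(cfg)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  num <- numeric_part(skeleton)
  n_expected <- length(unlist(num, use.names = FALSE))
  if (length(j$values) != n_expected)
    stop("checkpoint holds ", length(j$values), " values but the config ",
         "requires ", n_expected)
  restored <- utils::relist(j$values, skeleton = num)
  skeleton[names(restored)] <- restored
  skeleton
}
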