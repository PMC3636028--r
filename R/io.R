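#' Save / load a mixture model as JSON
#'
#' Human-readable serialization: priors plus one conditional table per
#' group.
#'
#' @param model A [mixture_model()].
#' @param path File path.
#' @return `read_model_json` returns a [mixture_model()];
#'   `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(priors = model$priors,
              conditionals = lapply(model$conditionals, function(m) {
                lapply(seq_len(nrow(m)), function(k) m[k, ])
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conds <- lapply(obj$conditionals, function(g) {
    if (is.matrix(g)) g else do.call(rbind, g)
  })
  mixture_model(obj$priors, conds)
}

#' Save / load a WTA network as JSON
#'
#' @param network A [wta_network()].
#' @param path File path.
#' @return `read_network_json` returns a [wta_network()];
#'   `write_network_json` returns `path` invisibly.
#' @export
write_network_json <- function(network, path) {
  obj <- list(K = network$K, n_inputs = network$n_inputs,
              offset_c = network$offset_c,
              weights = lapply(seq_len(network$K), function(k) {
                network$weights[k, ]
              }),
              excitabilities = network$excitabilities)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(obj$weights)) obj$weights else
    do.call(rbind, obj$weights)
  wta_network(obj$K, obj$n_inputs, offset_c = obj$offset_c,
              weights = W, excitabilities = obj$excitabilities)
}

#' Build configuration objects from a YAML file
#'
#' Reads a YAML file with optional blocks `simulation`, `plasticity`,
#' `inhibition` and `kernel`, each holding arguments for the matching
#' constructor ([sim_config()], [plasticity_config()],
#' [inhibition_config()], [kernel_spec()]).
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration objects (missing blocks get the
#'   constructor defaults).
#' @export
load_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, fn) {
    args <- y[[block]]
    if (is.null(args)) args <- list()
    do.call(fn, args)
  }
  list(simulation = build("simulation", sim_config),
       plasticity = build("plasticity", plasticity_config),
       inhibition = build("inhibition", inhibition_config),
       kernel = build("kernel", kernel_spec),
       raw = y)
}
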