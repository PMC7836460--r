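# JSON persistence for trained models (weights + scaler + config + seed).

scaler_to_list <- function(s) {
  list(lo = as.numeric(s$lo), hi = as.numeric(s$hi),
       target = if (is.null(s$target)) NULL else as.numeric(s$target),
       p = s$p, names = s$names)
}

scaler_from_list <- function(l) {
  tgt <- if (is.null(l$target)) NULL else c(lo = l$target[1], hi = l$target[2])
  structure(list(lo = stats::setNames(as.numeric(l$lo), l$names),
                 hi = stats::setNames(as.numeric(l$hi), l$names),
                 target = tgt, p = as.integer(l$p),
                 names = unlist(l$names)),
            class = "hyp_scaler")
}

#' Save a trained model to JSON
#'
#' Persists the learned parameters, the fitted scaler, the configuration
#' and the seed of any of the three model types; [load_model()] restores
#' an object whose predictions equal the original's.
#'
#' @param model A `hyp_mlp`, `hyp_rbf` or `hyp_svr`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hyp_model"))
  obj <- list(type = class(model)[1L], model_id = model$model_id,
              seed = model$seed, scaler = scaler_to_list(model$scaler))
  p <- model$params
  obj$params <- switch(class(model)[1L],
    hyp_mlp = list(W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
                   hidden_size = p$hidden_size, n_inputs = p$n_inputs,
                   activation = p$activation),
    hyp_rbf = list(centers = p$centers, sigma = p$sigma, w = p$w, b = p$b,
                   m = p$m, strategy = p$strategy),
    hyp_svr = list(beta = p$beta, sv = p$sv, b = p$b, gamma = p$gamma,
                   cost = p$cost, epsilon = p$epsilon, n_sv = p$n_sv),
    stop("unknown model type", call. = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a trained model from JSON
#' @param path File written by [save_model()].
#' @return A trained model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- scaler_from_list(obj$scaler)
  p <- obj$params
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  model <- switch(obj$type,
    hyp_mlp = list(params = structure(
      list(W1 = as_mat(p$W1), b1 = as.numeric(p$b1),
           w2 = as.numeric(p$w2), b2 = as.numeric(p$b2),
           hidden_size = as.integer(p$hidden_size),
           n_inputs = as.integer(p$n_inputs), activation = p$activation),
      class = "mlp_params")),
    hyp_rbf = list(params = structure(
      list(centers = as_mat(p$centers), sigma = as.numeric(p$sigma),
           w = as.numeric(p$w), b = as.numeric(p$b), m = as.integer(p$m),
           strategy = p$strategy), class = "rbf_params")),
    hyp_svr = list(params = list(
      beta = as.numeric(p$beta), sv = as_mat(p$sv), b = as.numeric(p$b),
      gamma = as.numeric(p$gamma), cost = as.numeric(p$cost),
      epsilon = as.numeric(p$epsilon), n_sv = as.integer(p$n_sv))),
    stop("unknown model type in file: ", obj$type, call. = FALSE)
  )
  model$scaler <- scaler
  model$seed <- as.integer(obj$seed)
  model$model_id <- obj$model_id
  structure(model, class = c(obj$type, "hyp_model"))
}
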