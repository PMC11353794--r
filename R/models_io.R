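#' Read and write process models as JSON
#'
#' Markov models are stored as `{type: "dtmc"|"ctmc", alphabet, matrix, pi}`
#' with the matrix row-major (rows index the next state) at full double
#' precision; Gaussian-process models as `{type: "dtgp"|"ctgp", mean, gamma}`
#' where `gamma` is either the vector of lag values (dtgp) or
#' `{coeffs, t_max}` for the fitted polynomial (ctgp; coefficients are in the
#' lag-scaled basis `u = t / t_max`).
#'
#' @param model A [dtmc_model()], [ctmc_model()] or [stationary_gp()].
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   reconstructed model object.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "dtmc_model")) {
    list(type = "dtmc", alphabet = model$alphabet,
         matrix = asplit(model$P, 1), pi = unname(model$pi))
  } else if (inherits(model, "ctmc_model")) {
    list(type = "ctmc", alphabet = model$alphabet,
         matrix = asplit(model$Q, 1), pi = unname(model$pi))
  } else if (inherits(model, "stationary_gp")) {
    if (model$mode == "discrete") {
      list(type = "dtgp", mean = model$mean, gamma = model$gamma)
    } else {
      list(type = "ctgp", mean = model$mean,
           gamma = list(coeffs = model$gamma$coeffs, t_max = model$gamma$t_max))
    }
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    "dtmc" = {
      P <- do.call(rbind, lapply(seq_len(length(obj$alphabet)), function(i) {
        as.numeric(if (is.matrix(obj$matrix)) obj$matrix[i, ] else obj$matrix[[i]])
      }))
      dtmc_model(P, obj$alphabet, obj$pi)
    },
    "ctmc" = {
      Q <- do.call(rbind, lapply(seq_len(length(obj$alphabet)), function(i) {
        as.numeric(if (is.matrix(obj$matrix)) obj$matrix[i, ] else obj$matrix[[i]])
      }))
      ctmc_model(Q, obj$alphabet, obj$pi)
    },
    "dtgp" = stationary_gp(obj$mean, as.numeric(obj$gamma)),
    "ctgp" = stationary_gp(obj$mean, structure(
      list(coeffs = as.numeric(obj$gamma$coeffs), t_max = obj$gamma$t_max,
           max_residual = NA_real_, indefinite_lags = integer(0)),
      class = "continuous_autocov"
    )),
    stop(sprintf("unknown model type '%s'", obj$type))
  )
}
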