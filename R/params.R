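#' @useDynLib medmtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.medmtl_env <- new.env(parent = emptyenv())
.medmtl_env$param_counter <- 0L

#' Create a trainable parameter
#'
#' Parameters are stored in environments so that every module holding a
#' reference sees the same values and gradient buffer. This is what makes the
#' shared blocks genuinely shared across tasks: a backward pass initiated by
#' one task accumulates into the buffer that all other tasks reference.
#'
#' @param value numeric array (or vector) of initial values.
#' @param name human-readable parameter name.
#' @param trainable logical; frozen parameters are skipped by optimizers.
#' @return an environment of class `mtl_param` with fields `value`, `grad`,
#'   `name`, `trainable` and a unique integer `id`.
#' @export
new_param <- function(value, name = "", trainable = TRUE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- if (is.null(dim(value))) numeric(length(value)) else array(0, dim = dim(value))
  e$name <- name
  e$trainable <- trainable
  .medmtl_env$param_counter <- .medmtl_env$param_counter + 1L
  e$id <- .medmtl_env$param_counter
  class(e) <- "mtl_param"
  e
}

#' @export
print.mtl_param <- function(x, ...) {
  cat(sprintf("<mtl_param '%s' [%s]%s>\n", x$name,
              paste(dim(x$value) %||% length(x$value), collapse = "x"),
              if (x$trainable) "" else " frozen"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

accum_grad <- function(p, g) {
  p$grad <- p$grad + g
  invisible(p)
}

#' Collect all parameters in a module tree
#'
#' Walks a nested list of modules/layers and returns every `mtl_param`
#' exactly once (deduplicated by identity), in a stable order.
#'
#' @param x a layer, module (nested list) or list of them.
#' @param trainable_only drop frozen parameters.
#' @return list of `mtl_param` environments.
#' @export
collect_params <- function(x, trainable_only = FALSE) {
  out <- list()
  walk <- function(node) {
    if (inherits(node, "mtl_param")) {
      out[[length(out) + 1L]] <<- node
    } else if (is.list(node)) {
      for (el in node) walk(el)
    }
  }
  walk(x)
  ids <- vapply(out, function(p) p$id, integer(1))
  out <- out[!duplicated(ids)]
  if (trainable_only) out <- Filter(function(p) isTRUE(p$trainable), out)
  out
}

#' Total number of scalar parameters in a module tree
#' @inheritParams collect_params
#' @export
n_params <- function(x, trainable_only = TRUE) {
  ps <- collect_params(x, trainable_only = trainable_only)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(params)
}

#' Snapshot parameter values (deep copy) for frozen-contract checks
#' @inheritParams collect_params
#' @return named list of numeric arrays.
#' @export
param_snapshot <- function(x) {
  ps <- collect_params(x)
  vals <- lapply(ps, function(p) p$value)
  names(vals) <- vapply(ps, function(p) sprintf("%d:%s", p$id, p$name), character(1))
  vals
}

#' Checksum of all parameter values
#'
#' A simple deterministic digest (sum, sum of squares and element count of
#' every parameter) used to verify that frozen shared blocks are untouched by
#' linear probing.
#' @inheritParams collect_params
#' @export
param_checksum <- function(x) {
  ps <- collect_params(x)
  v <- unlist(lapply(ps, function(p) c(sum(p$value), sum(p$value^2), length(p$value))))
  paste(format(sum(v), digits = 17), format(sum(v * seq_along(v)), digits = 17))
}

set_trainable <- function(x, trainable) {
  for (p in collect_params(x)) p$trainable <- trainable
  invisible(x)
}

## deterministic gaussian init helpers --------------------------------------

he_init <- function(dim, fan_in) {
  array(stats::rnorm(prod(dim), sd = sqrt(2 / fan_in)), dim = dim)
}
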