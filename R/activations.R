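SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Evaluate an activation function
#'
#' Registry of the activations compared in the reconstruction study:
#' `relu(x) = max(0, x)`; `elu(x) = x` for `x > 0`, else `exp(x) - 1`;
#' `selu(x) = lambda * x` for `x > 0`, else `lambda * alpha * (exp(x) - 1)`
#' with the self-normalizing constants `lambda = 1.0507009873554805`,
#' `alpha = 1.6732632423543772`; `swish(x) = x * sigmoid(x)`.
#'
#' @param name one of `"relu"`, `"elu"`, `"selu"`, `"swish"`.
#' @param x numeric vector/array.
#' @return the activation applied elementwise, same shape as `x`.
#' @export
activation_value <- function(name, x) {
  f <- activation_registry[[name]]
  if (is.null(f))
    stop(sprintf("unknown activation '%s'; available: %s", name,
                 paste(names(activation_registry), collapse = ", ")))
  f$fn(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# fn and the derivative expressed in terms of x (and optionally y = fn(x));
# branch-free forms (note exp(pmin(x, 0)) is 1 exactly where x > 0).
activation_registry <- list(
  relu = list(
    fn = function(x) pmax(x, 0),
    grad = function(x, y) (x > 0) * 1
  ),
  elu = list(
    fn = function(x) pmax(x, 0) + exp(pmin(x, 0)) - 1,
    grad = function(x, y) pmin(y + 1, 1)
  ),
  selu = list(
    fn = function(x) SELU_LAMBDA * (pmax(x, 0) + SELU_ALPHA * (exp(pmin(x, 0)) - 1)),
    grad = function(x, y) {
      g <- y + SELU_LAMBDA * SELU_ALPHA      # lambda*alpha*exp(x) where x <= 0
      g[x > 0] <- SELU_LAMBDA
      g
    }
  ),
  swish = list(
    fn = function(x) x * sigmoid(x),
    grad = function(x, y) {
      s <- sigmoid(x)
      s * (1 + x * (1 - s))
    }
  )
)

activation_grad <- function(name, x, y) activation_registry[[name]]$grad(x, y)
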