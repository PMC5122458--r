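#' Gradient-response functional for the Keller-Segel model
#'
#' Defines how the population drift velocity V(y) depends on the local
#' oxygen field. Supported kinds:
#' \describe{
#'   \item{constant}{\eqn{V = v_{drift} \, sign(c_y)}: fixed-magnitude drift
#'     up the gradient.}
#'   \item{linear}{\eqn{V = \beta c_y}: classical linear taxis with
#'     coefficient \eqn{\beta} (um^2 s^-1 \%^-1).}
#'   \item{tanh_abs}{\eqn{V = v_{drift} \tanh(\alpha |c_y|)\, sign(c_y)}:
#'     absolute-gradient sensing, saturating at \eqn{v_{drift}};
#'     \eqn{\alpha} in um \%^-1.}
#'   \item{tanh_linear}{identical functional form to \code{tanh_abs} (the
#'     1D reduction of both is \eqn{v_{drift}\tanh(\alpha c_y)}); kept as a
#'     distinct kind so fits against each label can be compared.}
#'   \item{tanh_log}{\eqn{V = v_{drift} \tanh(\alpha c_y / c)}:
#'     relative-gradient (logarithmic / Weber-law) sensing; \eqn{\alpha} in
#'     um. The division by \eqn{c} is floored at \code{c_min} because
#'     log-sensing cannot hold at arbitrarily small concentrations.}
#' }
#'
#' @param kind one of \code{"constant"}, \code{"linear"}, \code{"tanh_abs"},
#'   \code{"tanh_log"}, \code{"tanh_linear"}.
#' @param vdrift maximal drift speed (um/s), >= 0.
#' @param alpha saturation scale (units depend on kind, see above), >= 0.
#' @param beta taxis coefficient for \code{kind = "linear"}.
#' @param c_min concentration floor (\% oxygen) used inside \eqn{c_y/c}.
#' @return object of class \code{response_model}.
#' @export
response_model <- function(kind = c("tanh_log", "tanh_abs", "tanh_linear",
                                    "linear", "constant"),
                           vdrift = 5.2, alpha = 1850, beta = 0,
                           c_min = 1e-3) {
  kind <- match.arg(kind)
  stopifnot(vdrift >= 0, alpha >= 0, c_min > 0)
  structure(list(kind = kind, vdrift = vdrift, alpha = alpha, beta = beta,
                 c_min = c_min), class = "response_model")
}

#' Evaluate the drift velocity V(y) of a response model
#'
#' @param model a \code{response_model}.
#' @param c concentration profile (\%), same length as \code{dc_dy}; must be
#'   nonnegative up to a small tolerance.
#' @param dc_dy lateral concentration gradient (\%/um).
#' @return signed drift velocity (um/s), \eqn{|V| \le v_{drift}} for the
#'   saturating kinds, with \eqn{sign(V) = sign(c_y)}.
#' @export
response_velocity <- function(model, c, dc_dy) {
  stopifnot(inherits(model, "response_model"), length(c) == length(dc_dy))
  if (any(c < -1e-6)) stop("negative concentrations in response_velocity")
  c <- pmax(c, model$c_min)
  switch(model$kind,
    constant = model$vdrift * sign(dc_dy),
    linear = model$beta * dc_dy,
    tanh_abs = model$vdrift * tanh(model$alpha * abs(dc_dy)) * sign(dc_dy),
    tanh_linear = model$vdrift * tanh(model$alpha * dc_dy),
    tanh_log = model$vdrift * tanh(model$alpha * dc_dy / c)
  )
}

#' Keller-Segel population parameters
#'
#' @param D colony diffusion constant (um^2/s), > 0.
#' @param v ensemble-average swimming speed (um/s), used only to derive the
#'   effective rotational diffusion \eqn{D_r = v^2 / 2D}.
#' @return object of class \code{ks_params} with fields \code{D}, \code{v},
#'   and derived \code{Dr} (never stored independently).
#' @export
ks_params <- function(D = 865, v = 16.5) {
  stopifnot(D > 0, v > 0)
  structure(list(D = D, v = v, Dr = v^2 / (2 * D)), class = "ks_params")
}
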