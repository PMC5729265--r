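#' Convert beta values to M-values (logit2 transform)
#'
#' M-values, \code{log2(beta / (1 - beta))}, put methylation proportions on
#' an unbounded, approximately Gaussian scale on which linear modelling is
#' appropriate. Beta values are clipped to \code{[epsilon, 1 - epsilon]}
#' first so the result is always finite.
#'
#' @param beta numeric vector or matrix of methylation proportions
#' @param epsilon clipping bound in (0, 0.5); default \code{1e-6}
#' @return object of the same shape with M-values (log2 units)
#' @examples
#' betaToM(c(0.5, 0.8))       # 0, 2
#' mToBeta(betaToM(0.123))    # round-trips
#' @seealso \code{\link{mToBeta}}
#' @export
betaToM <- function(beta, epsilon = 1e-6) {
    if (!is.numeric(beta))
        stop("'beta' must be numeric")
    if (!is.numeric(epsilon) || length(epsilon) != 1L ||
        epsilon <= 0 || epsilon >= 0.5)
        stop("'epsilon' must be a single number in (0, 0.5)")
    b <- pmin(pmax(beta, epsilon), 1 - epsilon)
    m <- log2(b / (1 - b))
    if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
    m
}

#' Convert M-values back to beta values
#'
#' Inverse of \code{\link{betaToM}}: \code{beta = 2^M / (1 + 2^M)}.
#'
#' @param m numeric vector or matrix of M-values
#' @return object of the same shape with beta values in (0, 1)
#' @export
mToBeta <- function(m) {
    if (!is.numeric(m))
        stop("'m' must be numeric")
    b <- 1 / (1 + 2^(-m))
    if (is.matrix(m)) dimnames(b) <- dimnames(m)
    b
}
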