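#' Permutation test of the region-by-design association
#'
#' Tests whether the RDA of the region is significant by permuting the
#' pairing between samples and the predictor rows: in each of \code{nperm}
#' permutations the predictor block is re-assigned to samples at random
#' (jointly across all predictor columns), conditioning covariates stay
#' attached to their samples, the permuted predictors are re-residualised
#' on the covariates, and the pseudo-F is recomputed. The p-value uses the
#' add-one formula \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (nperm + 1)},
#' so the smallest attainable p is \code{1/(nperm + 1)} (with the default
#' 10,000 permutations, 1/10001 < 1e-4). Ties count as exceedances.
#'
#' @param y numeric matrix of M-values, k CpGs by n samples
#' @param design a \linkS4class{DesignMatrix}
#' @param nperm number of permutations (default 10000)
#' @param seed integer RNG seed for reproducibility; \code{NULL} uses the
#'   current RNG state
#' @param scale,r2Denominator passed to \code{\link{fitRDA}}
#' @return an \linkS4class{RDAPermutation}
#' @examples
#' ph <- data.frame(group = rep(c("A", "B"), each = 5),
#'                  row.names = paste0("S", 1:10))
#' d <- encodeDesign(ph, "group")
#' y <- matrix(rnorm(50), 5, 10,
#'             dimnames = list(paste0("cg", 1:5), rownames(ph)))
#' pt <- rdaPermTest(y, d, nperm = 199, seed = 1)
#' pValue(pt)
#' @export
rdaPermTest <- function(y, design, nperm = 10000L, seed = NULL,
                        scale = FALSE,
                        r2Denominator = c("total", "conditioned")) {
    r2Denominator <- match.arg(r2Denominator)
    nperm <- as.integer(nperm)
    if (nperm < 1L) stop("'nperm' must be at least 1")
    fit <- fitRDA(y, design, scale = scale, r2Denominator = r2Denominator)
    fObs <- pseudoF(fit)
    if (fit@m == 0L) stop("permutation test needs at least one predictor")
    if (!is.null(seed)) set.seed(as.integer(seed))

    X <- design@predictors
    Z <- design@conditioning
    n <- fit@n; m <- fit@m; q <- fit@q
    df2 <- n - m - q - 1L

    Yc <- scale(t(y), center = TRUE, scale = FALSE)
    if (scale) {
        sds <- apply(Yc, 2, stats::sd)
        sds[sds < 1e-12] <- 1
        Yc <- sweep(Yc, 2, sds, "/")
    }
    qz <- NULL
    if (q > 0) {
        qz <- qr(Z)
        Yc <- Yc - qr.fitted(qz, Yc)
    }
    ssAfter <- sum(Yc^2)

    fNull <- vapply(seq_len(nperm), function(b) {
        Xp <- X[sample.int(n), , drop = FALSE]
        if (q > 0) Xp <- Xp - qr.fitted(qz, Xp)
        qx <- qr(Xp)
        Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
        ssFit <- sum(crossprod(Q, Yc)^2)
        ssRes <- ssAfter - ssFit
        if (ssRes <= 0) return(Inf)
        (ssFit / m) / (ssRes / df2)
    }, numeric(1))

    p <- (1 + sum(fNull >= fObs)) / (nperm + 1)
    new("RDAPermutation", fObs = fObs, fNull = fNull, pValue = p,
        nperm = nperm,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        fit = fit)
}

setMethod("pValue", "RDAPermutation", function(object, ...) object@pValue)
setMethod("nullDraws", "RDAPermutation", function(object, ...) object@fNull)
setMethod("observedStat", "RDAPermutation", function(object, ...) object@fObs)
setMethod("explainedR2", "RDAPermutation", function(object, ...)
    object@fit@r2)

setMethod("show", "RDAPermutation", function(object) {
    cat("RDAPermutation:", object@nperm, "permutations\n")
    cat(sprintf("  pseudo-F = %.4g, p = %.4g (min attainable %.3g)\n",
                object@fObs, object@pValue, 1 / (object@nperm + 1)))
    cat(sprintf("  region R2 = %.4f\n", object@fit@r2))
})
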