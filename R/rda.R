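#' Fit a redundancy analysis of a region's M-values on a design
#'
#' Redundancy analysis (RDA) proceeds in two steps: a multiple linear
#' regression of every CpG (column of the sample-by-CpG outcome matrix) on
#' all predictor columns, followed by a principal components analysis of
#' the fitted matrix; the PCA axes of the fitted matrix are the RDA
#' components. The R-squared is the fraction of the total centered
#' variance of the region captured by the fitted matrix. When conditioning
#' covariates are present, both outcome and predictors are residualised on
#' them first (partial RDA); by default the R-squared is still referred to
#' the total variance before conditioning (see \code{r2Denominator}).
#'
#' @param y numeric matrix of M-values, k CpGs (rows) by n samples
#'   (columns)
#' @param design a \linkS4class{DesignMatrix} with n rows in the same
#'   sample order
#' @param scale logical; scale each CpG to unit variance before the fit
#'   (correlation-based RDA). Default \code{FALSE}: centering only.
#' @param r2Denominator \code{"total"} (default) refers the R-squared to
#'   the full centered variance including the conditioned part;
#'   \code{"conditioned"} refers it to the variance remaining after the
#'   covariates are partialled out
#' @param components logical; compute RDA components (SVD of the fitted
#'   matrix). Can be turned off when only the R-squared is needed.
#' @return an \linkS4class{RDAFit}
#' @examples
#' ph <- data.frame(group = rep(c("A", "B"), each = 5),
#'                  row.names = paste0("S", 1:10))
#' d <- encodeDesign(ph, "group")
#' y <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("cg", 1:4), rownames(ph)))
#' fit <- fitRDA(y, d)
#' explainedR2(fit)
#' @export
fitRDA <- function(y, design, scale = FALSE,
                   r2Denominator = c("total", "conditioned"),
                   components = TRUE) {
    r2Denominator <- match.arg(r2Denominator)
    stopifnot(is(design, "DesignMatrix"))
    if (!is.matrix(y) || !is.numeric(y))
        stop("'y' must be a numeric matrix (CpGs x samples)")
    if (!all(is.finite(y))) stop("'y' must be finite")
    X <- design@predictors
    Z <- design@conditioning
    n <- ncol(y); k <- nrow(y)
    m <- ncol(X); q <- ncol(Z)
    if (nrow(X) != n)
        stop("design has ", nrow(X), " rows but 'y' has ", n, " samples")
    if (m > 0 && n <= m + q + 1)
        stop("insufficient samples: need n > m + q + 1 (n = ", n,
             ", m = ", m, ", q = ", q, ")")

    Yc <- t(y)                               # samples x CpGs
    Yc <- scale(Yc, center = TRUE, scale = FALSE)
    if (scale) {
        sds <- apply(Yc, 2, stats::sd)
        sds[sds < 1e-12] <- 1
        Yc <- sweep(Yc, 2, sds, "/")
    }
    ssTotal <- sum(Yc^2)

    ssCond <- 0
    if (q > 0) {
        qz <- qr(Z)
        condFit <- qr.fitted(qz, Yc)
        ssCond <- sum(condFit^2)
        Yc <- Yc - condFit
        X <- X - qr.fitted(qz, X)
    }

    if (m == 0) {
        ssFit <- 0
        ssRes <- sum(Yc^2)
        Yhat <- matrix(0, n, k)
    } else {
        qx <- qr(X)
        if (qx$rank < m)
            stop("rank-deficient design: predictors are collinear",
                 if (q > 0) " (possibly with the conditioning covariates)")
        Yhat <- qr.fitted(qx, Yc)
        ssFit <- sum(Yhat^2)
        ssRes <- sum((Yc - Yhat)^2)
    }

    denom <- if (r2Denominator == "total") ssTotal else ssFit + ssRes
    r2 <- if (denom > 0) ssFit / denom else 0

    scores <- matrix(numeric(0), n, 0)
    loadings <- matrix(numeric(0), k, 0)
    eig <- numeric(0)
    if (components && m > 0 && ssFit > 0) {
        cmax <- min(m, k, n - 1L)
        sv <- svd(Yhat, nu = cmax, nv = cmax)
        d <- sv$d[seq_len(cmax)]
        keep <- which(d > max(d[1], 0) * 1e-10)
        d <- d[keep]
        U <- sv$u[, keep, drop = FALSE]
        V <- sv$v[, keep, drop = FALSE]
        # fix component signs: largest-magnitude loading positive
        for (j in seq_along(d)) {
            i <- which.max(abs(V[, j]))
            if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
        }
        scores <- U %*% diag(d, nrow = length(d))
        loadings <- V
        eig <- d^2 / (n - 1)
        cn <- paste0("RDA", seq_along(d))
        dimnames(scores) <- list(colnames(y), cn)
        dimnames(loadings) <- list(rownames(y), cn)
        names(eig) <- cn
    }

    new("RDAFit", r2 = r2, ssTotal = ssTotal, ssFitted = ssFit,
        ssResidual = ssRes, ssConditioned = ssCond,
        sampleScores = scores, cpgLoadings = loadings, eigenvalues = eig,
        n = as.integer(n), k = as.integer(k), m = as.integer(m),
        q = as.integer(q), r2Denominator = r2Denominator)
}

#' Pseudo-F statistic of a fitted RDA
#'
#' The ratio of the constrained mean square to the residual mean square,
#' \eqn{F = (SS_{fit}/m) / (SS_{res}/(n - m - q - 1))}, the usual
#' permutation-test statistic of constrained ordination. Strictly
#' increasing in the R-squared at fixed n, m, q.
#'
#' @param fit an \linkS4class{RDAFit}
#' @return numeric scalar; \code{+Inf} (with a warning) when the residual
#'   sum of squares is zero, 0 when there are no predictors
#' @export
pseudoF <- function(fit) {
    stopifnot(is(fit, "RDAFit"))
    if (fit@m == 0L) return(0)
    df2 <- fit@n - fit@m - fit@q - 1L
    if (df2 < 1L) stop("no residual degrees of freedom")
    if (fit@ssResidual <= 0) {
        warning("zero residual sum of squares; pseudo-F is infinite")
        return(Inf)
    }
    (fit@ssFitted / fit@m) / (fit@ssResidual / df2)
}

setMethod("explainedR2", "RDAFit", function(object, ...) object@r2)
setMethod("ssDecomposition", "RDAFit", function(object, ...)
    c(total = object@ssTotal, conditioned = object@ssConditioned,
      fitted = object@ssFitted, residual = object@ssResidual))
setMethod("sampleScores", "RDAFit", function(object, ...)
    object@sampleScores)
setMethod("cpgLoadings", "RDAFit", function(object, ...)
    object@cpgLoadings)
setMethod("eigenvalues", "RDAFit", function(object, ...)
    object@eigenvalues)

setMethod("show", "RDAFit", function(object) {
    cat("RDAFit:", object@k, "CpGs,", object@n, "samples,", object@m,
        "predictor(s)")
    if (object@q > 0) cat(",", object@q, "conditioning covariate(s)")
    cat("\n")
    cat(sprintf("  R2 = %.4f (%s variance)\n", object@r2,
                object@r2Denominator))
    ss <- ssDecomposition(object)
    cat(sprintf("  SS: total %.3g = conditioned %.3g + fitted %.3g + residual %.3g\n",
                ss["total"], ss["conditioned"], ss["fitted"],
                ss["residual"]))
    cat("  components:", length(object@eigenvalues), "\n")
})

#' Biplot coordinates of a fitted RDA
#'
#' Returns the pieces needed for an RDA biplot: sample scores on the
#' retained components, per-group centroids (when a grouping factor is
#' supplied), and the CpGs with the largest loading magnitude across the
#' retained components.
#'
#' @param fit an \linkS4class{RDAFit}
#' @param nComponents number of leading components to keep
#' @param nLabeledCpgs number of top-loading CpGs to return (0 for none)
#' @param groups optional factor (or coercible) of length n giving a group
#'   per sample; centroids are the mean sample scores per level
#' @return list with data.frames \code{samples}, \code{centroids}
#'   (possibly empty), \code{cpgs}
#' @export
biplotCoordinates <- function(fit, nComponents = 2L, nLabeledCpgs = 5L,
                              groups = NULL) {
    stopifnot(is(fit, "RDAFit"))
    c <- length(fit@eigenvalues)
    if (nComponents > c)
        stop("nComponents = ", nComponents, " but only ", c,
             " component(s) are available")
    comps <- seq_len(nComponents)
    sc <- fit@sampleScores[, comps, drop = FALSE]
    samples <- data.frame(sample = rownames(sc), sc, check.names = FALSE,
                          row.names = NULL)

    centroids <- data.frame()
    if (!is.null(groups)) {
        g <- factor(groups)
        if (length(g) != fit@n)
            stop("'groups' must have one entry per sample")
        centroids <- do.call(rbind, lapply(levels(g), function(l) {
            data.frame(group = l,
                       t(colMeans(sc[g == l, , drop = FALSE])),
                       check.names = FALSE)
        }))
        rownames(centroids) <- NULL
    }

    cpgs <- data.frame()
    if (nLabeledCpgs > 0L) {
        ld <- fit@cpgLoadings[, comps, drop = FALSE]
        mag <- sqrt(rowSums(ld^2))
        top <- order(mag, decreasing = TRUE)[seq_len(min(nLabeledCpgs,
                                                         nrow(ld)))]
        cpgs <- data.frame(cpg = rownames(ld)[top],
                           ld[top, , drop = FALSE],
                           magnitude = mag[top], check.names = FALSE,
                           row.names = NULL)
    }
    list(samples = samples, centroids = centroids, cpgs = cpgs)
}
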