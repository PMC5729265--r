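#' Encode outcome and covariate columns into a centered design matrix
#'
#' Builds the predictor block (the variables whose association with
#' regional methylation is tested) and the conditioning block (covariates
#' partialled out before the test) from a phenotype table. Categorical
#' variables are dummy-coded with the first lexicographic level as the
#' reference (k levels give k - 1 columns); numeric variables enter as is.
#' All columns are mean-centered.
#'
#' @param phenotypes data.frame (or DataFrame) with sample IDs as rownames
#' @param outcome character vector of outcome column names (tested)
#' @param covariates character vector of covariate column names
#'   (conditioned on); default none
#' @return a \linkS4class{DesignMatrix}
#' @examples
#' ph <- data.frame(group = c("A", "A", "B", "B"),
#'                  row.names = paste0("S", 1:4))
#' encodeDesign(ph, "group")   # one centered column: -0.5 -0.5 0.5 0.5
#' @export
encodeDesign <- function(phenotypes, outcome, covariates = character()) {
    ph <- as.data.frame(phenotypes)
    unknown <- setdiff(c(outcome, covariates), colnames(ph))
    if (length(unknown) > 0)
        stop("unknown phenotype column(s): ", paste(unknown, collapse = ", "))
    if (length(outcome) == 0) stop("at least one outcome column is required")

    X <- .encodeBlock(ph, outcome)
    Z <- .encodeBlock(ph, covariates)
    rownames(X) <- rownames(ph)
    rownames(Z) <- rownames(ph)
    new("DesignMatrix", predictors = X, conditioning = Z)
}

.encodeBlock <- function(ph, cols) {
    n <- nrow(ph)
    if (length(cols) == 0)
        return(matrix(numeric(0), nrow = n, ncol = 0))
    parts <- lapply(cols, function(cn) {
        v <- ph[[cn]]
        if (anyNA(v))
            stop("column '", cn, "' contains missing values")
        if (is.numeric(v)) {
            m <- matrix(as.numeric(v), ncol = 1,
                        dimnames = list(NULL, cn))
        } else {
            f <- factor(v, levels = sort(unique(as.character(v))))
            if (nlevels(f) < 2)
                stop("column '", cn, "' has fewer than 2 observed levels")
            m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
            colnames(m) <- paste0(cn, levels(f)[-1])
        }
        m
    })
    M <- do.call(cbind, parts)
    M <- scale(M, center = TRUE, scale = FALSE)
    attr(M, "scaled:center") <- NULL
    sds <- apply(M, 2, function(z) max(abs(z)))
    if (any(sds < 1e-12))
        stop("column(s) constant after centering: ",
             paste(colnames(M)[sds < 1e-12], collapse = ", "))
    if (ncol(M) > 0 && qr(M)$rank < ncol(M))
        stop("design block is rank deficient after centering")
    M
}

#' @describeIn DesignMatrix-class number of predictor columns (m)
#' @param x a \linkS4class{DesignMatrix}
#' @export
nPredictors <- function(x) {
    stopifnot(is(x, "DesignMatrix"))
    ncol(x@predictors)
}

#' @describeIn DesignMatrix-class number of conditioning columns (q)
#' @export
nConditioning <- function(x) {
    stopifnot(is(x, "DesignMatrix"))
    ncol(x@conditioning)
}

#' @describeIn DesignMatrix-class the centered predictor block
#' @export
predictorMatrix <- function(x) {
    stopifnot(is(x, "DesignMatrix"))
    x@predictors
}

#' @describeIn DesignMatrix-class the centered conditioning block
#' @export
conditioningMatrix <- function(x) {
    stopifnot(is(x, "DesignMatrix"))
    x@conditioning
}

setMethod("show", "DesignMatrix", function(object) {
    cat("DesignMatrix:", nrow(object@predictors), "samples,",
        ncol(object@predictors), "predictor column(s)")
    if (ncol(object@conditioning) > 0)
        cat(",", ncol(object@conditioning), "conditioning column(s)")
    cat("\n")
    if (ncol(object@predictors) > 0)
        cat("  predictors:",
            paste(colnames(object@predictors), collapse = ", "), "\n")
})
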