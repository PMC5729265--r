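#' @title Generics for methylRDA result objects
#' @name methylRDA-generics
#' @description Accessor generics shared by the result classes
#' (\linkS4class{RDAFit}, \linkS4class{RDAPermutation},
#' \linkS4class{RegionalNull}).
NULL

#' Proportion of variance explained by the constrained axes
#'
#' @param object a fitted object
#' @param ... further arguments for methods
#' @return numeric scalar in \[0, 1\]
#' @export
setGeneric("explainedR2", function(object, ...) standardGeneric("explainedR2"))

#' Sum-of-squares decomposition of a fit
#'
#' @param object a fitted object
#' @param ... further arguments for methods
#' @return named numeric vector (total, conditioned, fitted, residual)
#' @export
setGeneric("ssDecomposition",
           function(object, ...) standardGeneric("ssDecomposition"))

#' Sample coordinates on the RDA components
#'
#' @param object a fitted object
#' @param ... further arguments for methods
#' @return numeric matrix, samples by components
#' @export
setGeneric("sampleScores", function(object, ...) standardGeneric("sampleScores"))

#' CpG loadings on the RDA components
#'
#' @param object a fitted object
#' @param ... further arguments for methods
#' @return numeric matrix, CpGs by components
#' @export
setGeneric("cpgLoadings", function(object, ...) standardGeneric("cpgLoadings"))

#' Component eigenvalues
#'
#' @param object a fitted object
#' @param ... further arguments for methods
#' @return numeric vector, nonincreasing
#' @export
setGeneric("eigenvalues", function(object, ...) standardGeneric("eigenvalues"))

#' P-value of a test result
#'
#' @param object a test result object
#' @param ... further arguments for methods
#' @return numeric scalar in (0, 1\]
#' @export
setGeneric("pValue", function(object, ...) standardGeneric("pValue"))

#' Null draws underlying an empirical p-value
#'
#' @param object a test result object
#' @param ... further arguments for methods
#' @return numeric vector of null statistics
#' @export
setGeneric("nullDraws", function(object, ...) standardGeneric("nullDraws"))

#' Observed test statistic
#'
#' @param object a test result object
#' @param ... further arguments for methods
#' @return numeric scalar
#' @export
setGeneric("observedStat", function(object, ...) standardGeneric("observedStat"))
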