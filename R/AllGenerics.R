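#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' `features()` and `targets()` return the sensor feature and GRF target
#' matrices; `stepMeta()` the per-row metadata of a dataset; `nSteps()` the
#' number of 101-row steps; `bodyMass()` the participant mass in kg;
#' `hyperparams()` a GP fit's kernel hyperparameters.
#'
#' @param object a \linkS4class{TrialRecording}, \linkS4class{AlignedStep},
#'   \linkS4class{StepDataset}, \linkS4class{GPRFit} or
#'   \linkS4class{GPRModel}.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("targets", function(object) standardGeneric("targets"))
#' @rdname accessors
#' @export
setGeneric("stepMeta", function(object) standardGeneric("stepMeta"))
#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setGeneric("bodyMass", function(object) standardGeneric("bodyMass"))
#' @rdname accessors
#' @export
setGeneric("hyperparams", function(object) standardGeneric("hyperparams"))

#' @rdname accessors
#' @export
setMethod("features", "AlignedStep", function(object) object@features)
#' @rdname accessors
#' @export
setMethod("features", "StepDataset", function(object) object@features)
#' @rdname accessors
#' @export
setMethod("targets", "AlignedStep", function(object) object@targets)
#' @rdname accessors
#' @export
setMethod("targets", "StepDataset", function(object) object@targets)
#' @rdname accessors
#' @export
setMethod("stepMeta", "StepDataset", function(object) object@meta)
#' @rdname accessors
#' @export
setMethod("nSteps", "StepDataset", function(object) nrow(object@features) %/% 101L)
#' @rdname accessors
#' @export
setMethod("bodyMass", "AlignedStep", function(object) object@bodyMass)
#' @rdname accessors
#' @export
setMethod("bodyMass", "TrialRecording", function(object) object@bodyMass)
#' @rdname accessors
#' @export
setMethod("hyperparams", "GPRFit", function(object) object@hyp)
#' @rdname accessors
#' @export
setMethod("hyperparams", "GPRModel", function(object)
  lapply(object@fits, function(f) f@hyp))
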