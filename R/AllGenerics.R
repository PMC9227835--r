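#' @rdname SimulatedDataset-class
#' @param x a SimulatedDataset or FeatureTable.
#' @export
setGeneric("metabMatrix", function(x) standardGeneric("metabMatrix"))

#' @describeIn SimulatedDataset-class subjects-by-metabolites level matrix.
setMethod("metabMatrix", "SimulatedDataset", function(x) t(assay(x, "levels")))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @describeIn SimulatedDataset-class outcome vector (length N).
setMethod("outcome", "SimulatedDataset", function(x) colData(x)$outcome)

#' @rdname SimulatedDataset-class
#' @export
setGeneric("effectVector", function(x) standardGeneric("effectVector"))

#' @describeIn SimulatedDataset-class length-M planted effect vector.
setMethod("effectVector", "SimulatedDataset", function(x) rowData(x)$beta)

#' @rdname SimulatedDataset-class
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))

#' @describeIn SimulatedDataset-class indices of planted true positives.
setMethod("truthSet", "SimulatedDataset",
          function(x) which(rowData(x)$isTrue))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("scenarioConfig", function(x) standardGeneric("scenarioConfig"))

#' @describeIn SimulatedDataset-class the generating ScenarioConfig.
setMethod("scenarioConfig", "SimulatedDataset", function(x) x@config)

#' @rdname FeatureTable-class
#' @param x a FeatureTable.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @describeIn FeatureTable-class samples-by-metabolites raw intensities.
setMethod("intensityMatrix", "FeatureTable",
          function(x) t(assay(x, "intensity")))

#' @rdname FeatureTable-class
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))

#' @describeIn FeatureTable-class per-sample covariate data.frame
#'   (age, sex, batch).
setMethod("covariateData", "FeatureTable",
          function(x) as.data.frame(colData(x)))

#' Accessors for MethodOutput
#'
#' @param x a [MethodOutput-class].
#' @name MethodOutput-accessors
#' @export
setGeneric("methodScores", function(x) standardGeneric("methodScores"))

#' @rdname MethodOutput-accessors
setMethod("methodScores", "MethodOutput", function(x) x@scores)

#' @rdname MethodOutput-accessors
#' @export
setGeneric("selectedSet", function(x) standardGeneric("selectedSet"))

#' @rdname MethodOutput-accessors
setMethod("selectedSet", "MethodOutput", function(x) x@selected)

#' @rdname MethodOutput-accessors
#' @export
setGeneric("methodTuning", function(x) standardGeneric("methodTuning"))

#' @rdname MethodOutput-accessors
setMethod("methodTuning", "MethodOutput", function(x) x@tuning)

#' @rdname MethodOutput-accessors
#' @export
setGeneric("methodPvalues", function(x) standardGeneric("methodPvalues"))

#' @rdname MethodOutput-accessors
setMethod("methodPvalues", "MethodOutput", function(x) x@pvalues)
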