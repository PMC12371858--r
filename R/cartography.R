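#' Construct a multi-echo image
#'
#' @param data numeric array indexed (row, col, echo)
#' @param protocol acquisition protocol; `nEchoes` must match `dim(data)[3]`
#' @param mask optional logical matrix of voxels to analyze (default: all)
#' @return a [MultiEchoImage-class]
#' @export
multiEchoImage <- function(data, protocol, mask = NULL) {
  d <- dim(data)
  if (length(d) != 3L) stop("data must be a (row, col, echo) array")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  new("MultiEchoImage", data = data, protocol = protocol, mask = mask)
}

#' Construct an ROI label map
#'
#' @param labels integer matrix with values 0 (background), 1 (cortex),
#'   2 (outer medulla), 3 (inner medulla)
#' @return a [ROILabels-class]
#' @export
roiLabels <- function(labels) {
  storage.mode(labels) <- "integer"
  new("ROILabels", labels = labels)
}

#' Layer names used for renal label maps
#' @return named integer vector mapping layer name to label value
#' @export
renalLayers <- function() {
  c(cortex = 1L, outer_medulla = 2L, inner_medulla = 3L)
}

.newMap <- function(values, valid, units) {
  values[!valid] <- NA_real_
  values[valid & !is.finite(values)] <- NA_real_
  valid <- valid & is.finite(values)
  values[!valid] <- 0
  new("ParametricMap", values = values, valid = valid, units = units)
}

#' Voxel-wise parametric mapping
#'
#' Fits every in-mask voxel of a multi-echo image independently with a
#' mono-exponential (T2 or T2*) or constrained bi-exponential (TVF) model.
#' Invalid fits are marked in the validity mask and propagate as missing
#' values; there is no spatial coupling, so the result commutes with voxel
#' permutation.
#'
#' @param image a [MultiEchoImage-class]
#' @param model `"mono_t2"` (MESE), `"mono_t2star"` (MGE) or `"biexp_tvf"`
#'   (MESE)
#' @param constraints [FitConstraints-class] for the bi-exponential model
#' @param t2RangeMs search range for the mono-exponential decay constant
#' @return a named list of [ParametricMap-class] objects: `map` (the primary
#'   quantity: T2/T2* in ms or TVF in percent) plus companions (`t2short`
#'   and `residual` for the bi-exponential model; `s0` and `residual` for
#'   the mono-exponential models)
#' @export
mapVoxelwise <- function(image, model = c("mono_t2", "mono_t2star", "biexp_tvf"),
                         constraints = fitConstraints(),
                         t2RangeMs = c(1, 2000)) {
  model <- match.arg(model)
  stopifnot(is(image, "MultiEchoImage"))
  validObject(image)
  isMese <- is(image@protocol, "MESEProtocol")
  if (model %in% c("mono_t2", "biexp_tvf") && !isMese)
    stop(sprintf("model '%s' requires a MESEProtocol, got %s", model,
                 class(image@protocol)))
  if (model == "mono_t2star" && isMese)
    stop("model 'mono_t2star' requires an MGEProtocol, got MESEProtocol")

  d <- dim(image@data)
  te <- echoTimes(image@protocol)
  idx <- which(image@mask)
  flat <- matrix(image@data, d[1] * d[2], d[3])
  Y <- t(flat[idx, , drop = FALSE])
  blank <- matrix(0, d[1], d[2])
  fblank <- matrix(FALSE, d[1], d[2])
  fill <- function(v) { m <- blank; m[idx] <- v; m }
  fillL <- function(v) { m <- fblank; m[idx] <- v; m }

  if (model == "biexp_tvf") {
    f <- .biexpBatch(Y, te, constraints)
    valid <- fillL(f$valid)
    list(map = .newMap(fill(f$tvfPercent), valid, "percent"),
         t2short = .newMap(fill(f$t2ShortMs), valid, "ms"),
         residual = .newMap(fill(sqrt(f$rss)), valid, "au"))
  } else {
    f <- .monoexpBatch(Y, te, t2RangeMs)
    valid <- fillL(f$valid)
    list(map = .newMap(fill(f$t2Ms), valid, "ms"),
         s0 = .newMap(fill(f$s0), valid, "au"),
         residual = .newMap(fill(sqrt(f$rss)), valid, "au"))
  }
}

#' Voxel-wise T2' map
#'
#' Combines aligned T2 and T2* maps through `1/T2* = 1/T2 + 1/T2'`. Voxels
#' where either input is invalid, or where `T2* >= T2` (which would make
#' T2' infinite or negative), are marked invalid; their count is reported
#' in `attr(result, "nExcluded")`.
#'
#' @param t2Map,t2StarMap aligned [ParametricMap-class] objects in ms
#' @return a [ParametricMap-class] of T2' (ms)
#' @export
t2primeMap <- function(t2Map, t2StarMap) {
  stopifnot(is(t2Map, "ParametricMap"), is(t2StarMap, "ParametricMap"))
  if (!identical(dim(t2Map@values), dim(t2StarMap@values)))
    stop("map shapes differ")
  ok <- t2Map@valid & t2StarMap@valid & (t2StarMap@values < t2Map@values)
  nExcluded <- sum(t2Map@valid & t2StarMap@valid & !ok)
  vals <- matrix(0, nrow(t2Map@values), ncol(t2Map@values))
  vals[ok] <- 1 / (1 / t2StarMap@values[ok] - 1 / t2Map@values[ok])
  out <- .newMap(vals, ok, "ms")
  attr(out, "nExcluded") <- nExcluded
  out
}

#' Per-layer ROI medians
#'
#' Median of the valid voxels of a parametric map within each renal layer.
#' Layers with no valid voxel yield `NA`.
#'
#' @param map a [ParametricMap-class]
#' @param labels a [ROILabels-class] of matching shape
#' @return named numeric vector (cortex, outer_medulla, inner_medulla)
#' @export
roiMedian <- function(map, labels) {
  stopifnot(is(map, "ParametricMap"), is(labels, "ROILabels"))
  if (!identical(dim(map@values), dim(labels@labels)))
    stop("map and labels shapes differ")
  layers <- renalLayers()
  vapply(layers, function(l) {
    sel <- labels@labels == l & map@valid
    if (!any(sel)) NA_real_ else median(map@values[sel])
  }, numeric(1))
}

#' Construct a per-layer time course
#'
#' @param values matrix (layer x time point) of per-layer medians; rownames
#'   are taken as layer names when present
#' @param baselineIdx indices of baseline time points
#' @param interval1Idx,interval2Idx indices of the two post-intervention
#'   intervals (defaults follow the intervention design: four points in the
#'   first interval, three in the second)
#' @return a [LayerTimeCourse-class]
#' @export
layerTimeCourse <- function(values, baselineIdx,
                            interval1Idx, interval2Idx) {
  layers <- rownames(values)
  if (is.null(layers)) layers <- paste0("layer", seq_len(nrow(values)))
  new("LayerTimeCourse", values = as.matrix(values), layers = layers,
      baselineIdx = as.integer(baselineIdx),
      interval1Idx = as.integer(interval1Idx),
      interval2Idx = as.integer(interval2Idx))
}

#' Baseline and interval summary of a layer time course
#'
#' The reference is the mean of the baseline points per layer. Every
#' post-baseline point is expressed as a percent change against that
#' reference, and the changes are averaged within each interval.
#'
#' @param tc a [LayerTimeCourse-class]; baseline values must be positive
#' @return data.frame with one row per layer: `layer`, `baseline_mean`,
#'   `interval1_change_percent`, `interval2_change_percent`
#' @export
intervalSummary <- function(tc) {
  stopifnot(is(tc, "LayerTimeCourse"))
  validObject(tc)
  out <- lapply(seq_along(tc@layers), function(i) {
    v <- tc@values[i, ]
    base <- mean(v[tc@baselineIdx])
    if (!is.finite(base) || base <= 0)
      stop("baseline mean must be positive (layer ", tc@layers[i], ")")
    rel <- 100 * (v - base) / base
    data.frame(layer = tc@layers[i], baseline_mean = base,
               interval1_change_percent = mean(rel[tc@interval1Idx]),
               interval2_change_percent = mean(rel[tc@interval2Idx]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
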