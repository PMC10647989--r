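#' Read or write a dose grid in the plain text container format
#'
#' The container is a single self-describing JSON file holding the spatial
#' metadata (spacing, origin, isocenter, units, array dimensions) and the
#' flattened dose values in column-major order. It exists so synthetic and
#' test data round-trip without DICOM, and writes at full double precision.
#'
#' @param grid a [DoseGrid-class] or [PercentDoseGrid-class].
#' @param path file path (conventionally \code{.dose.json}).
#' @return \code{writeDoseGrid} returns \code{path} invisibly;
#'   \code{readDoseGrid} returns the grid.
#' @examples
#' g <- DoseGrid(array(runif(27), c(3, 3, 3)))
#' f <- tempfile(fileext = ".dose.json")
#' writeDoseGrid(g, f)
#' all.equal(doseValues(readDoseGrid(f)), doseValues(g))
#' @export
writeDoseGrid <- function(grid, path) {
  stopifnot(is(grid, "DoseGrid"))
  payload <- list(
    format = "isodiff-dose-grid",
    version = 1L,
    units = if (is(grid, "PercentDoseGrid")) "percent" else "Gy",
    dim = dim(grid@values),
    spacing = grid@spacing,
    origin = grid@origin,
    isocenter = grid@isocenter,
    values = as.vector(grid@values)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDoseGrid
#' @export
readDoseGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("unreadable dose container: ", conditionMessage(e)))
  need <- c("format", "dim", "spacing", "origin", "isocenter", "values")
  if (!is.list(payload) || !all(need %in% names(payload)) ||
      !identical(payload$format, "isodiff-dose-grid"))
    stop("not an isodiff dose container: ", path)
  values <- array(as.numeric(payload$values), dim = as.integer(payload$dim))
  cls <- if (identical(payload$units, "percent")) "PercentDoseGrid" else "DoseGrid"
  new(cls, values = values, spacing = as.numeric(payload$spacing),
      origin = as.numeric(payload$origin),
      isocenter = as.numeric(payload$isocenter))
}

#' Load a dose grid from DICOM RTDOSE or the plain container format
#'
#' File type is sniffed from content: a DICM magic number at byte offset 128
#' selects the DICOM RTDOSE reader, anything else is treated as the plain
#' JSON container. DICOM stored values are scaled by DoseGridScaling to Gy.
#' RTDOSE files carry no isocenter, so for DICOM input
#' \code{isocenterOverride} is required; for the container it takes
#' precedence over the stored isocenter when given.
#'
#' @param path input file.
#' @param isocenterOverride optional numeric(3) isocenter in mm.
#' @return a [DoseGrid-class] (dose in Gy).
#' @export
loadDoseGrid <- function(path, isocenterOverride = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(isocenterOverride) &&
      (!is.numeric(isocenterOverride) || length(isocenterOverride) != 3L))
    stop("'isocenterOverride' must be a numeric vector of length 3")
  grid <- if (.is_dicom(path)) {
    if (is.null(isocenterOverride))
      stop("DICOM RTDOSE carries no isocenter; supply 'isocenterOverride'")
    readDicomDose(path)
  } else {
    readDoseGrid(path)
  }
  if (!is.null(isocenterOverride)) {
    grid@isocenter <- as.numeric(isocenterOverride)
    validObject(grid)
    .warn_isocenter_outside(grid)
  }
  grid
}

.is_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}
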