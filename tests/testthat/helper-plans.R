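## Shared synthetic fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

## Small centered linear sphere: r0 = 20 mm on a 45^3 1 mm grid.
sphere20 <- function() memo("sphere20",
  makePlan(shape = "sphere", falloff = "linear", r0 = 20,
           gridDim = rep(45, 3)))
sphere20_pct <- function() memo("sphere20_pct", toPercent(sphere20()))

## Sphere with an off-center parametrization point: distance histograms get
## realistic nonzero width (a perfectly centered sphere collapses them to a
## single distance).
sphere25 <- function() memo("sphere25",
  makePlan(shape = "sphere", falloff = "linear", r0 = 25,
           isocenterOffset = c(8, 0, 0)))
sphere25_pct <- function() memo("sphere25_pct", toPercent(sphere25()))
sphere25_band <- function() memo("sphere25_band",
  suppressWarnings(buildToleranceBand(sphere25_pct(),
                                      levels = seq(10, 95, 5))))

## Anisotropic in-plane ellipsoids used by the rotation and ISOmr tests.
ellipsoid30 <- function() memo("ellipsoid30",
  makePlan(shape = "ellipsoid", falloff = "sigmoid", r0 = 30,
           axes = c(1, 0.65, 0.85)))
ellipsoid30_pct <- function() memo("ellipsoid30_pct", toPercent(ellipsoid30()))
ellipsoid50_pct <- function() memo("ellipsoid50_pct",
  toPercent(makePlan(shape = "ellipsoid", falloff = "sigmoid", r0 = 50,
                     axes = c(1, 0.6, 0.8))))

## Independent brute-force global gamma: exhaustive search over the integer
## voxel lattice (no interpolation, plain R). Deliberately a separate code
## path from the compiled engine; agreement is asserted on on-lattice shift
## cases where sub-voxel interpolation cannot change the optimum.
gamma_oracle_rate <- function(ref, ev, dose_pct = 3, dta = 2, cutoff = 10,
                              search_factor = 3) {
  v <- doseValues(ref)
  e <- doseValues(ev)
  stopifnot(all(dim(v) == dim(e)),
            all(gridSpacing(ref) == gridSpacing(ev)),
            all(gridOrigin(ref) == gridOrigin(ev)))
  sp <- gridSpacing(ref)
  d <- dim(v)
  dmax <- max(v)
  tol <- dose_pct / 100 * dmax
  cut <- cutoff / 100 * dmax
  rad <- search_factor * dta
  steps <- lapply(1:3, function(ax) seq(-floor(rad / sp[ax]),
                                        floor(rad / sp[ax])))
  offs <- as.matrix(expand.grid(steps))
  nrm <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
              (offs[, 3] * sp[3])^2)
  keep <- nrm <= rad
  offs <- offs[keep, , drop = FALSE]
  nrm <- nrm[keep]
  best <- array(Inf, d)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    idx <- vector("list", 3L)
    src <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      lo <- max(1L, 1L - o[ax])
      hi <- min(d[ax], d[ax] - o[ax])
      if (lo > hi) { ok <- FALSE; break }
      idx[[ax]] <- lo:hi
      src[[ax]] <- (lo + o[ax]):(hi + o[ax])
    }
    if (!ok) next
    dd <- (e[src[[1]], src[[2]], src[[3]]] -
           v[idx[[1]], idx[[2]], idx[[3]]]) / tol
    cand <- dd^2 + (nrm[k] / dta)^2
    cur <- best[idx[[1]], idx[[2]], idx[[3]]]
    best[idx[[1]], idx[[2]], idx[[3]]] <- pmin(cur, cand)
  }
  g <- sqrt(best)
  g[v < cut] <- NA
  100 * sum(g <= 1, na.rm = TRUE) / sum(!is.na(g))
}

## Write a synthetic DICOM RTDOSE with pydicom (the independent oracle for
## the hand-written reader). `values` are dose in Gy.
write_rtdose_py <- function(values, spacing, origin, scaling, path,
                            bits = 32L, implicit = FALSE,
                            modality = "DOSE") {
  stored <- round(values / scaling)
  cfg <- list(dim = dim(values), spacing = spacing, origin = origin,
              scaling = scaling, bits = bits, implicit = implicit,
              modality = modality, values = as.vector(stored))
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "from pydicom.uid import (ExplicitVRLittleEndian,",
    "                         ImplicitVRLittleEndian, generate_uid)",
    "cfg = json.load(open(sys.argv[1]))",
    "nx, ny, nz = cfg['dim']",
    "dtype = np.uint32 if cfg['bits'] == 32 else np.uint16",
    "arr = np.asarray(cfg['values'], dtype=dtype).reshape((nz, ny, nx))",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.481.2'",
    "meta.MediaStorageSOPInstanceUID = generate_uid()",
    "meta.TransferSyntaxUID = (ImplicitVRLittleEndian if cfg['implicit']",
    "                          else ExplicitVRLittleEndian)",
    "ds = FileDataset(sys.argv[2], {}, file_meta=meta, preamble=b'\\x00'*128)",
    "ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "ds.Modality = cfg['modality']",
    "ds.DoseUnits = 'GY'",
    "ds.DoseType = 'PHYSICAL'",
    "ds.DoseSummationType = 'PLAN'",
    "ds.Rows = ny",
    "ds.Columns = nx",
    "ds.NumberOfFrames = nz",
    "ds.SamplesPerPixel = 1",
    "ds.PhotometricInterpretation = 'MONOCHROME2'",
    "ds.BitsAllocated = cfg['bits']",
    "ds.BitsStored = cfg['bits']",
    "ds.HighBit = cfg['bits'] - 1",
    "ds.PixelRepresentation = 0",
    "ds.PixelSpacing = [str(cfg['spacing'][1]), str(cfg['spacing'][0])]",
    "ds.ImagePositionPatient = [str(v) for v in cfg['origin']]",
    "ds.ImageOrientationPatient = ['1', '0', '0', '0', '1', '0']",
    "ds.GridFrameOffsetVector = [str(k * cfg['spacing'][2])",
    "                            for k in range(nz)]",
    "ds.DoseGridScaling = repr(cfg['scaling'])",
    "ds.PixelData = arr.astype('<u4' if cfg['bits'] == 32",
    "                          else '<u2').tobytes()",
    "pydicom.dcmwrite(sys.argv[2], ds, enforce_file_format=True)"
  ), script)
  status <- system2("python", c(script, cfg_file, path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(path))
    stop("pydicom writer failed: ", paste(status, collapse = "\n"))
  invisible(path)
}
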