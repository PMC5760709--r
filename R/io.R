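## Plain-text and TIFF interchange for the analysis inputs and outputs.

#' Write / read a force curve as CSV
#'
#' Columns: \code{segment} ("extend"/"retract"), \code{separation_nm},
#' \code{force_pN}. The spring constant and velocity travel in commented
#' header lines.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param path CSV file path.
#' @return \code{readForceCurveCsv} returns a \linkS4class{ForceCurve}
#'   (without ground truth); \code{writeForceCurveCsv} returns \code{path}
#'   invisibly.
#' @export
writeForceCurveCsv <- function(curve, path) {
  stopifnot(is(curve, "ForceCurve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# spring_constant_N_per_m=%g", curve@springConstant),
               sprintf("# velocity_um_per_s=%g", curve@velocity)), con)
  df <- rbind(
    data.frame(segment = "extend", separation_nm = curve@sepExt,
               force_pN = curve@forceExt),
    data.frame(segment = "retract", separation_nm = curve@sepRet,
               force_pN = curve@forceRet))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeForceCurveCsv
#' @export
readForceCurveCsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getNum <- function(key, default) {
    m <- grep(key, hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*=", "", m[1])) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  ext <- df[df$segment == "extend", ]
  ret <- df[df$segment == "retract", ]
  new("ForceCurve",
      sepExt = ext$separation_nm, forceExt = ext$force_pN,
      sepRet = ret$separation_nm, forceRet = ret$force_pN,
      springConstant = getNum("spring_constant", NA_real_),
      velocity = getNum("velocity", NA_real_), truth = list())
}

#' Write / read a FRAP record as CSV
#'
#' Columns: \code{t}, \code{I}, \code{T}, \code{bg} and a 0/1
#' \code{post_bleach} flag.
#'
#' @param record a \linkS4class{FrapRecord}.
#' @param path CSV file path.
#' @export
writeFrapCsv <- function(record, path) {
  stopifnot(is(record, "FrapRecord"))
  post <- as.integer(seq_along(record@t) >= record@bleachIndex)
  utils::write.csv(data.frame(t = record@t, I = record@I, T = record@T,
                              bg = record@bg, post_bleach = post),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrapCsv
#' @export
readFrapCsv <- function(path) {
  df <- utils::read.csv(path)
  new("FrapRecord", t = df$t, I = df$I, T = df$T, bg = df$bg,
      bleachIndex = as.integer(which(df$post_bleach == 1)[1]),
      truth = list())
}

#' Write / read image stacks as multi-page 32-bit float TIFF
#'
#' @param x a matrix or list of matrices (pages).
#' @param path TIFF file path.
#' @return \code{readImageStack} returns a list of matrices.
#' @export
writeImageStack <- function(x, path) {
  if (is.matrix(x)) x <- list(x)
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(out)) out <- list(out)
  out
}

#' Write a simulation with its ground-truth JSON sidecar
#'
#' Saves a simulated object's data in an interchange format (multi-page
#' TIFF for images, CSV for force curves and FRAP records) next to a JSON
#' sidecar holding the preset name, seed and scalar ground truth.
#'
#' @param sim a simulated object.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir, name = "simulation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, name)
  truth <- groundTruth(sim)
  scalarTruth <- truth[vapply(truth, function(x)
    is.numeric(x) && length(x) < 1000 || is.character(x), logical(1))]
  paths <- character(0)
  if (is(sim, "SimulatedGpImage")) {
    p <- paste0(stem, ".tif")
    ## channel scaling: float TIFF expects [0,1]
    sc <- max(sim@blue, sim@red)
    writeImageStack(list(sim@blue / sc, sim@red / sc), p)
    scalarTruth$intensity_scale <- sc
    paths <- p
  } else if (is(sim, "SimulatedCellField")) {
    p <- paste0(stem, ".tif")
    sc <- max(sim@dapi, sim@membrane, sim@ligand)
    writeImageStack(list(sim@dapi / sc, sim@membrane / sc,
                         sim@ligand / sc), p)
    scalarTruth$intensity_scale <- sc
    paths <- p
  } else if (is(sim, "ForceCurve")) {
    p <- paste0(stem, ".csv")
    writeForceCurveCsv(sim, p)
    paths <- p
  } else if (is(sim, "FrapRecord")) {
    p <- paste0(stem, ".csv")
    writeFrapCsv(sim, p)
    paths <- p
  } else stop("unsupported simulation object")
  side <- paste0(stem, ".json")
  jsonlite::write_json(scalarTruth, side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}
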