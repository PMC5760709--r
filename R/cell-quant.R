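#' Detect nuclei by marker-controlled watershed
#'
#' A Wahlby-style pipeline: Gaussian smoothing, Otsu foreground
#' thresholding, h-maxima-seeded watershed on the smoothed intensity
#' (regions whose maxima differ by less than \code{h} are merged, removing
#' over-seeding across weak boundaries), small-object removal, and
#' optional shape-based splitting of remaining clusters by a
#' distance-transform watershed (applied when a component's area exceeds
#' what a single convex nucleus of its maximum inscribed radius could
#' cover).
#'
#' @param dapi single-channel nuclear image (matrix).
#' @param smoothing Gaussian sigma (px).
#' @param h h-maxima merge depth as a fraction of the image intensity
#'   range.
#' @param minArea minimum nucleus area (px^2).
#' @param shapeSplit split non-round clusters with a distance-transform
#'   watershed.
#' @return integer label matrix (0 = background); an image with no
#'   foreground yields an empty labeling, not an error.
#' @examples
#' fld <- simulateCellField(makePreset("control"), seed = 1, nCells = 4)
#' max(detectNuclei(fld@dapi))  # 4
#' @export
detectNuclei <- function(dapi, smoothing = 2, h = 0.2, minArea = 30L,
                         shapeSplit = TRUE) {
  stopifnot(is.matrix(dapi))
  if (smoothing <= 0 || h <= 0 || minArea < 1)
    stop("degenerate parameters: need smoothing > 0, h > 0, minArea >= 1")
  rng <- range(dapi)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(dapi), ncol(dapi)))
  norm <- (dapi - rng[1]) / (rng[2] - rng[1])
  sm <- gaussianBlur(norm, smoothing)
  fg <- sm > otsuThreshold(as.numeric(sm))
  if (!any(fg)) return(matrix(0L, nrow(dapi), ncol(dapi)))

  labels <- EBImage::watershed(EBImage::Image(sm * fg), tolerance = h,
                               ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(dapi), ncol(dapi))
  ## small-object removal
  sizes <- tabulate(labels)
  labels[labels > 0 & sizes[pmax(labels, 1L)] < minArea] <- 0L

  if (shapeSplit && any(labels > 0)) {
    out <- matrix(0L, nrow(dapi), ncol(dapi))
    nextId <- 0L
    for (id in sort(unique(labels[labels > 0]))) {
      idx <- which(labels == id, arr.ind = TRUE)
      pad <- 2L
      r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(dapi), max(idx[, 1]) + pad)
      c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(dapi), max(idx[, 2]) + pad)
      sub <- labels[r0:r1, c0:c1] == id
      dm <- EBImage::distmap(EBImage::Image(sub))
      rmax <- max(dm)
      area <- sum(sub)
      if (area > 1.35 * pi * rmax^2) {
        ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
        ws <- matrix(as.integer(EBImage::imageData(ws)), nrow(dm))
        ws[!sub] <- 0L
        for (sid in sort(unique(ws[ws > 0]))) {
          if (sum(ws == sid) < minArea) next
          nextId <- nextId + 1L
          tgt <- out[r0:r1, c0:c1]
          tgt[ws == sid] <- nextId
          out[r0:r1, c0:c1] <- tgt
        }
      } else {
        nextId <- nextId + 1L
        tgt <- out[r0:r1, c0:c1]
        tgt[sub] <- nextId
        out[r0:r1, c0:c1] <- tgt
      }
    }
    labels <- out
  } else if (any(labels > 0)) {
    ## relabel sequentially
    ids <- sort(unique(labels[labels > 0]))
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  labels
}

#' Segment cells by nucleus-seeded watershed on the membrane channel
#'
#' Nuclei are shrunk to single-pixel seeds (their centroids) and a seeded
#' watershed (region growing on the membrane-channel intensity) partitions
#' the thresholded, hole-filled cell foreground into one region per
#' nucleus. Each cell's boundary is thickened inward by \code{thickenPx}
#' pixels to form the membrane mask; the remaining interior is the
#' intracellular mask. Applying this per frame tracks moving membranes in
#' image stacks.
#'
#' @param membrane membrane-channel image (matrix).
#' @param nuclei integer nucleus label matrix, e.g. from [detectNuclei()].
#' @param thickenPx inward thickening of the boundary ring (px, >= 1).
#' @return a \linkS4class{CellSegmentation}.
#' @export
segmentCells <- function(membrane, nuclei, thickenPx = 5L) {
  stopifnot(is.matrix(membrane), is.matrix(nuclei),
            all(dim(membrane) == dim(nuclei)))
  if (thickenPx < 1L) stop("thickenPx must be >= 1")
  if (!any(nuclei > 0)) stop("zero seeds: no nuclei to segment from")
  nr <- nrow(membrane); nc <- ncol(membrane)

  cent <- labelCentroids(nuclei)
  seeds <- matrix(0L, nr, nc)
  ids <- as.integer(rownames(cent))
  seeds[cbind(pmin(pmax(round(cent[, "row"]), 1L), nr),
              pmin(pmax(round(cent[, "col"]), 1L), nc))] <- ids

  rng <- range(membrane)
  norm <- if (rng[1] == rng[2]) membrane * 0 else
    (membrane - rng[1]) / (rng[2] - rng[1])
  fg <- norm > otsuThreshold(as.numeric(norm))
  filled <- EBImage::fillHull(EBImage::Image(fg))
  mask <- (EBImage::imageData(filled) > 0) | seeds > 0

  cells <- EBImage::propagate(EBImage::Image(norm),
                              seeds = EBImage::Image(seeds),
                              mask = EBImage::Image(mask))
  cells <- matrix(as.integer(EBImage::imageData(cells)), nr, nc)

  brush <- EBImage::makeBrush(2L * as.integer(thickenPx) + 1L, "disc")
  memLab <- matrix(0L, nr, nc)
  intLab <- matrix(0L, nr, nc)
  present <- sort(unique(cells[cells > 0]))
  for (id in present) {
    idx <- which(cells == id, arr.ind = TRUE)
    pad <- as.integer(thickenPx) + 1L
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nr, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(nc, max(idx[, 2]) + pad)
    sub <- cells[r0:r1, c0:c1] == id
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(sub), brush)) > 0
    memT <- memLab[r0:r1, c0:c1]; intT <- intLab[r0:r1, c0:c1]
    memT[sub & !er] <- id
    intT[sub & er] <- id
    memLab[r0:r1, c0:c1] <- memT
    intLab[r0:r1, c0:c1] <- intT
  }
  border <- c(cells[1, ], cells[nr, ], cells[, 1], cells[, nc])
  new("CellSegmentation", nucleusLabels = nuclei, cellLabels = cells,
      membraneLabels = memLab, intracellularLabels = intLab,
      cellIds = present,
      edgeCells = sort(unique(border[border > 0])))
}

setMethod("show", "CellSegmentation", function(object) {
  cat(sprintf(
    "CellSegmentation: %d cells (%d touching the border), %d x %d px\n",
    length(object@cellIds), length(object@edgeCells),
    nrow(object@cellLabels), ncol(object@cellLabels)))
})

#' Per-cell endocytosed ligand fraction
#'
#' After scalar background subtraction (negative pixels clipped to 0), the
#' ligand intensity in each cell's intracellular mask is divided by the
#' total cellular intensity (membrane + intracellular) on a cell-by-cell
#' basis. Cells with zero total intensity are flagged and excluded, as are
#' cells touching the image border (truncated masks bias fractions) unless
#' \code{excludeEdges = FALSE}.
#'
#' @param ligand ligand-channel image (matrix).
#' @param seg a \linkS4class{CellSegmentation}.
#' @param background scalar background (a.u., >= 0).
#' @param excludeEdges exclude border-touching cells.
#' @return data.frame with columns \code{cellId}, \code{total},
#'   \code{compartment} (intracellular), \code{fraction} and
#'   \code{excluded}.
#' @export
endocytosedFraction <- function(ligand, seg, background = 0,
                                excludeEdges = TRUE) {
  stopifnot(is(seg, "CellSegmentation"), is.matrix(ligand),
            all(dim(ligand) == dim(seg@cellLabels)))
  if (background < 0) stop("background must be non-negative")
  corr <- pmax(ligand - background, 0)
  ids <- seg@cellIds
  intra <- vapply(ids, function(id)
    sum(corr[seg@intracellularLabels == id]), numeric(1))
  memb <- vapply(ids, function(id)
    sum(corr[seg@membraneLabels == id]), numeric(1))
  total <- intra + memb
  excluded <- total == 0
  if (excludeEdges) excluded <- excluded | ids %in% seg@edgeCells
  data.frame(cellId = ids, total = total, compartment = intra,
             fraction = ifelse(total > 0, intra / total, NA_real_),
             excluded = excluded)
}

#' Per-cell nuclear signal fraction
#'
#' Divides the background-corrected signal in each nucleus mask by the
#' total cellular intensity evaluated in the cell mask (area inside the
#' membrane mask including the membrane itself). Each nucleus is assigned
#' to the cell whose label covers its centroid; nuclei outside any cell
#' are flagged and excluded. Whole-cell and cytoplasmic (cell minus
#' nucleus) intensities are reported alongside.
#'
#' @param signal signal image (matrix), e.g. phospho-STAT1.
#' @param seg a \linkS4class{CellSegmentation}.
#' @param background scalar background (a.u., >= 0).
#' @param excludeEdges exclude border-touching cells.
#' @return data.frame with columns \code{cellId}, \code{nucleusId},
#'   \code{total}, \code{nuclear}, \code{cytoplasmic}, \code{fraction} and
#'   \code{excluded}.
#' @export
nuclearFraction <- function(signal, seg, background = 0,
                            excludeEdges = TRUE) {
  stopifnot(is(seg, "CellSegmentation"), is.matrix(signal),
            all(dim(signal) == dim(seg@cellLabels)))
  if (background < 0) stop("background must be non-negative")
  corr <- pmax(signal - background, 0)
  cent <- labelCentroids(seg@nucleusLabels)
  nucIds <- as.integer(rownames(cent))
  nr <- nrow(signal); nc <- ncol(signal)
  cellOf <- seg@cellLabels[cbind(pmin(pmax(round(cent[, "row"]), 1L), nr),
                                 pmin(pmax(round(cent[, "col"]), 1L), nc))]
  res <- lapply(seq_along(nucIds), function(j) {
    nid <- nucIds[j]; cid <- cellOf[j]
    if (cid == 0)
      return(data.frame(cellId = NA_integer_, nucleusId = nid,
                        total = NA_real_, nuclear = NA_real_,
                        cytoplasmic = NA_real_, fraction = NA_real_,
                        excluded = TRUE))
    cellMask <- seg@membraneLabels == cid | seg@intracellularLabels == cid
    total <- sum(corr[cellMask])
    nuclear <- sum(corr[seg@nucleusLabels == nid & cellMask])
    excl <- total == 0 || (excludeEdges && cid %in% seg@edgeCells)
    data.frame(cellId = cid, nucleusId = nid, total = total,
               nuclear = nuclear, cytoplasmic = total - nuclear,
               fraction = if (total > 0) nuclear / total else NA_real_,
               excluded = excl)
  })
  do.call(rbind, res)
}
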