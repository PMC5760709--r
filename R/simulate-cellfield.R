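# Paint a disk (or annulus when rInner > 0) into logical matrix `m`.
.paintDisk <- function(m, center, r, rInner = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(nr, ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(nc, ceiling(center[2] + r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  m[rows, cols] <- m[rows, cols] | (d2 <= r^2 & d2 > rInner^2)
  m
}

.paintLabelDisk <- function(m, center, r, id, rInner = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(nr, ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(nc, ceiling(center[2] + r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  sub <- m[rows, cols]
  sub[d2 <= r^2 & d2 > rInner^2] <- id
  m[rows, cols] <- sub
  m
}

#' Simulate a three-channel cell field with known endocytosed fractions
#'
#' Cells are laid out on a jittered grid without overlap. Channel 1 (DAPI)
#' contains nuclear disks; channel 2 a membrane annulus of the preset
#' thickness per cell; channel 3 the ligand, with a fraction
#' \code{f_endo} of each cell's total signal placed uniformly in an
#' interior disk (endosomal compartment, kept away from the membrane so
#' segmentation-boundary jitter cannot reassign it) and the remainder in
#' the membrane annulus. Additive background and Gaussian noise are applied
#' per channel. Ground truth records per-cell fractions and all masks.
#'
#' @param params a \linkS4class{MemPreset}; \code{endo$f_endo} reflects the
#'   ligand chosen in [makePreset()].
#' @param seed integer seed.
#' @param nCells number of cells; defaults to the preset.
#' @param shape optional image size (rows, cols); computed from the grid
#'   when NULL. An explicit shape too small to pack the cells is an error.
#' @return a \linkS4class{SimulatedCellField}.
#' @examples
#' fld <- simulateCellField(makePreset("control"), seed = 1, nCells = 9)
#' mean(groundTruth(fld)$f)  # 0.6 for control transferrin
#' @export
simulateCellField <- function(params, seed,
                              nCells = params@endo$n_cells, shape = NULL) {
  stopifnot(is(params, "MemPreset"))
  en <- params@endo
  rc <- en$cell_radius; rn <- en$nucleus_radius
  mt <- en$membrane_thickness
  g <- ceiling(sqrt(nCells))
  spacing <- 2 * rc + 6
  margin <- rc + 8
  need <- 2 * margin + (g - 1) * spacing
  if (is.null(shape)) shape <- c(need, need)
  if (any(shape < need))
    stop("infeasible packing: ", nCells, " cells need at least ", need,
         " x ", need, " pixels")

  bgLevels <- c(dapi = 20, membrane = 15, ligand = 10)
  withSeed(seed, {
    centers <- matrix(NA_real_, nCells, 2)
    for (i in seq_len(nCells)) {
      gr <- (i - 1) %/% g; gc <- (i - 1) %% g
      centers[i, ] <- c(margin + gr * spacing, margin + gc * spacing) +
        runif(2, -2, 2)
    }
    nucLab <- matrix(0L, shape[1], shape[2])
    memLab <- matrix(0L, shape[1], shape[2])
    intLab <- matrix(0L, shape[1], shape[2])
    ligDisk <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(nCells)) {
      nucLab <- .paintLabelDisk(nucLab, centers[i, ], rn, i)
      memLab <- .paintLabelDisk(memLab, centers[i, ], rc, i,
                                rInner = rc - mt)
      intLab <- .paintLabelDisk(intLab, centers[i, ], rc - mt, i)
      ligDisk <- .paintLabelDisk(ligDisk, centers[i, ], rc - mt - 3, i)
    }
    f <- rep(en$f_endo, nCells)
    total <- 20000
    dapi <- bgLevels["dapi"] + 200 * (nucLab > 0) +
      rnorm(prod(shape), sd = 4)
    membrane <- bgLevels["membrane"] + 180 * (memLab > 0) +
      rnorm(prod(shape), sd = 4)
    ligand <- matrix(bgLevels["ligand"], shape[1], shape[2])
    for (i in seq_len(nCells)) {
      inIdx <- ligDisk == i
      anIdx <- memLab == i
      ligand[inIdx] <- ligand[inIdx] + f[i] * total / sum(inIdx)
      ligand[anIdx] <- ligand[anIdx] + (1 - f[i]) * total / sum(anIdx)
    }
    ligand <- ligand + rnorm(prod(shape), sd = 2)
    new("SimulatedCellField",
        dapi = pmax(matrix(dapi, shape[1], shape[2]), 0),
        membrane = pmax(matrix(membrane, shape[1], shape[2]), 0),
        ligand = pmax(ligand, 0),
        truth = list(centers = centers, f = f,
                     nucleusLabels = nucLab, membraneLabels = memLab,
                     interiorLabels = intLab, background = bgLevels,
                     preset = params@name, ligand = en$ligand, seed = seed))
  })
}
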