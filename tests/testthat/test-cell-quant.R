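test_that("nucleus detection finds isolated nuclei at their true positions", {
  expect_equal(max(detectNuclei(matrix(0, 64, 64))), 0)  # blank image
  fld <- simulateCellField(makePreset("control"), seed = 1, nCells = 10)
  lab <- detectNuclei(fld@dapi)
  expect_equal(max(lab), 10L)
  found <- labelCent <- memphys:::labelCentroids(lab)
  truthC <- groundTruth(fld)$centers
  ## each true center has a detected centroid within 1 px
  for (i in seq_len(nrow(truthC))) {
    d <- sqrt((found[, 1] - truthC[i, 1])^2 + (found[, 2] - truthC[i, 2])^2)
    expect_lt(min(d), 1)
  }
  expect_error(detectNuclei(fld@dapi, smoothing = 0), "degenerate")
})

test_that("overlapping nuclei are split by the distance-transform watershed", {
  img <- matrix(20, 120, 120)
  img <- paintDisk(img, c(60, 48), 16, 220)
  img <- paintDisk(img, c(60, 69), 16, 220)   # ~20% overlap
  set.seed(5)
  img <- img + matrix(rnorm(120 * 120, sd = 3), 120, 120)
  expect_equal(max(detectNuclei(img)), 2L)
  expect_equal(max(detectNuclei(img, shapeSplit = FALSE)), 1L)
})

test_that("seeded watershed segmentation recovers membrane and interior", {
  fld <- simulateCellField(makePreset("control"), seed = 2, nCells = 1)
  nuc <- detectNuclei(fld@dapi)
  seg <- segmentCells(fld@membrane, nuc, thickenPx = 5)
  tr <- groundTruth(fld)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(iou(seg@membraneLabels > 0, tr$membraneLabels > 0), 0.9)
  expect_gte(iou(seg@intracellularLabels > 0, tr$interiorLabels > 0), 0.9)
  expect_error(segmentCells(fld@membrane, nuc, thickenPx = 0), ">= 1")
  expect_error(segmentCells(fld@membrane, nuc * 0L), "zero seeds")
})

test_that("adjacent cells are separated into disjoint masks", {
  img <- matrix(15, 100, 140)
  img <- paintDisk(img, c(50, 50), 20, 195, rInner = 15)
  img <- paintDisk(img, c(50, 88), 20, 195, rInner = 15)  # touching annuli
  dapi <- matrix(20, 100, 140)
  dapi <- paintDisk(dapi, c(50, 50), 8, 220)
  dapi <- paintDisk(dapi, c(50, 88), 8, 220)
  seg <- segmentCells(img, detectNuclei(dapi), thickenPx = 5)
  expect_equal(length(seg@cellIds), 2L)
  expect_false(any(seg@membraneLabels > 0 & seg@intracellularLabels > 0))
  ## each nucleus sits in its own cell
  expect_equal(seg@cellLabels[50, 50] != seg@cellLabels[50, 88], TRUE)
})

test_that("membrane plus intracellular intensity equals the cell total", {
  fld <- simulateCellField(makePreset("control"), seed = 3, nCells = 9)
  seg <- segmentCells(fld@membrane, detectNuclei(fld@dapi))
  corr <- pmax(fld@ligand - groundTruth(fld)$background["ligand"], 0)
  for (id in seg@cellIds) {
    cellMask <- seg@membraneLabels == id | seg@intracellularLabels == id
    expect_equal(sum(corr[seg@membraneLabels == id]) +
                 sum(corr[seg@intracellularLabels == id]),
                 sum(corr[cellMask]))
  }
})

test_that("pure-compartment ligand gives fractions 0 and 1", {
  fld <- simulateCellField(makePreset("control"), seed = 4, nCells = 4)
  seg <- segmentCells(fld@membrane, detectNuclei(fld@dapi))
  tr <- groundTruth(fld)
  memOnly <- matrix(0, nrow(fld@ligand), ncol(fld@ligand))
  memOnly[tr$membraneLabels > 0] <- 100
  fr0 <- endocytosedFraction(memOnly, seg)
  expect_true(all(fr0$fraction[!fr0$excluded] < 0.02))
  inOnly <- matrix(0, nrow(fld@ligand), ncol(fld@ligand))
  inOnly[tr$interiorLabels > 0 & tr$membraneLabels == 0] <- 100
  fr1 <- endocytosedFraction(inOnly, seg)
  expect_true(all(fr1$fraction[!fr1$excluded] > 0.95))
})

test_that("endocytosed fractions are recovered across the dynamic range", {
  for (f in c(0.1, 0.5, 0.9)) {
    p <- presetWith(endo = list(f_endo = f))
    fld <- simulateCellField(p, seed = round(100 * f), nCells = 100)
    seg <- segmentCells(fld@membrane, detectNuclei(fld@dapi))
    fr <- endocytosedFraction(fld@ligand, seg,
                              background = groundTruth(fld)$background["ligand"])
    ok <- !fr$excluded
    expect_gt(sum(ok), 90)
    expect_lt(abs(mean(fr$fraction[ok]) - f), 0.03)
  }
})

test_that("fractions are invariant to global intensity scaling", {
  fld <- simulateCellField(makePreset("control"), seed = 6, nCells = 9)
  seg <- segmentCells(fld@membrane, detectNuclei(fld@dapi))
  bg <- groundTruth(fld)$background["ligand"]
  f1 <- endocytosedFraction(fld@ligand, seg, background = bg)
  f2 <- endocytosedFraction(fld@ligand * 4, seg, background = bg * 4)
  expect_equal(f1$fraction, f2$fraction, tolerance = 1e-12)
})

test_that("segmentation is deterministic", {
  fld <- simulateCellField(makePreset("gaucher"), seed = 7, nCells = 9)
  n1 <- detectNuclei(fld@dapi); n2 <- detectNuclei(fld@dapi)
  expect_identical(n1, n2)
  s1 <- segmentCells(fld@membrane, n1); s2 <- segmentCells(fld@membrane, n2)
  expect_identical(s1@cellLabels, s2@cellLabels)
  expect_identical(s1@membraneLabels, s2@membraneLabels)
})

test_that("nuclear fractions follow the signal distribution", {
  fld <- simulateCellField(makePreset("control"), seed = 8, nCells = 9)
  tr <- groundTruth(fld)
  seg <- segmentCells(fld@membrane, detectNuclei(fld@dapi))
  dims <- dim(fld@dapi)
  cellMaskT <- tr$membraneLabels > 0 | tr$interiorLabels > 0
  ## signal confined to nuclei: fraction 1
  nucOnly <- matrix(0, dims[1], dims[2]); nucOnly[tr$nucleusLabels > 0] <- 80
  nf1 <- nuclearFraction(nucOnly, seg)
  expect_true(all(nf1$fraction[!nf1$excluded] > 0.98))
  ## spatially uniform signal: fraction = nuclear area / cell area,
  ## measured on the segmentation's own masks
  unif <- matrix(0, dims[1], dims[2]); unif[cellMaskT] <- 50
  nf2 <- nuclearFraction(unif, seg)
  for (i in which(!nf2$excluded)) {
    cid <- nf2$cellId[i]; nid <- nf2$nucleusId[i]
    cellMask <- seg@membraneLabels == cid | seg@intracellularLabels == cid
    aRatio <- sum(seg@nucleusLabels == nid & cellMask & cellMaskT) /
      sum(cellMask & cellMaskT)
    expect_equal(nf2$fraction[i], aRatio, tolerance = 1e-9)
  }
  ## a known 70/30 nuclear/cytoplasmic split is recovered
  mix <- matrix(0, dims[1], dims[2])
  nCellPix <- tabulate(tr$nucleusLabels)  # per-nucleus pixel counts
  for (id in seq_along(nCellPix)) {
    nucM <- tr$nucleusLabels == id
    cytM <- (tr$membraneLabels == id | tr$interiorLabels == id) & !nucM
    mix[nucM] <- 0.7 * 1000 / sum(nucM)
    mix[cytM] <- 0.3 * 1000 / sum(cytM)
  }
  nf3 <- nuclearFraction(mix, seg)
  expect_equal(mean(nf3$fraction[!nf3$excluded]), 0.70, tolerance = 0.02)
})
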