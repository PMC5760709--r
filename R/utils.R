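## Internal helpers shared across modules.

# Evaluate expr with a locally-seeded RNG, restoring global RNG state after.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

# Otsu threshold on a numeric vector, delegated to EBImage over the
# observed value range.
otsuThreshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values for threshold estimation")
  r <- range(values)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(EBImage::Image(values, dim = c(length(values), 1L)),
                range = r, levels = levels)
}

# Gaussian blur of a plain matrix via EBImage, returned as a matrix.
gaussianBlur <- function(x, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x),
                                              sigma = sigma)))
}

# Centroids (row, col) of a label image; rows named by label.
labelCentroids <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  nr <- nrow(labels)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  lab <- labels[idx]
  out <- cbind(row = tapply(rr, lab, mean), col = tapply(cc, lab, mean))
  out
}

# Robust noise scale of a series from the MAD of first differences.
robustNoiseSd <- function(x) {
  d <- diff(x)
  if (!length(d)) return(0)
  mad(d, constant = 1.4826) / sqrt(2)
}
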