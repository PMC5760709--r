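#' Double-normalize a FRAP record
#'
#' Computes the double-normalized recovery
#' R(t) = (I(t) - bg(t)) / (I(0) - bg(0)) * (T(0) - bg(0)) / (T(t) - bg(t)),
#' where the "(0)" quantities are means over all pre-bleach frames. The
#' first factor normalizes the bleached-ROI signal to its pre-bleach level;
#' the second cancels acquisition bleaching through the whole-membrane
#' intensity. Pre-bleach frames are retained in the output.
#'
#' @param record a \linkS4class{FrapRecord}.
#' @return a \linkS4class{NormalizedCurve}.
#' @examples
#' rec <- simulateFrapRecord(makePreset("control"), seed = 1, noiseSd = 0)
#' curve <- doubleNormalize(rec)
#' max(abs(recovery(curve) - groundTruth(rec)$R))  # ~1e-16
#' @export
doubleNormalize <- function(record) {
  stopifnot(is(record, "FrapRecord"))
  pre <- seq_len(record@bleachIndex - 1L)
  I0 <- mean(record@I[pre]); T0 <- mean(record@T[pre])
  bg0 <- mean(record@bg[pre])
  if (I0 - bg0 <= 0)
    stop("non-positive pre-bleach denominator I(0) - bg(0)")
  Tden <- record@T - record@bg
  bad <- which(Tden <= 0)
  if (length(bad))
    stop("non-positive denominator T(t) - bg(t) at frame ", bad[1])
  R <- (record@I - record@bg) / (I0 - bg0) * (T0 - bg0) / Tden
  new("NormalizedCurve", t = record@t, R = R,
      sem = rep(NA_real_, length(R)), bleachIndex = record@bleachIndex,
      nAveraged = 1L)
}

#' Average double-normalized recovery curves
#'
#' Pointwise mean of curves on identical time grids, with per-point
#' standard error of the mean. With \code{resample = TRUE}, curves are
#' linearly interpolated onto the grid of the first curve before averaging.
#'
#' @param curves a list of \linkS4class{NormalizedCurve} objects.
#' @param resample interpolate onto the first curve's grid when grids
#'   differ.
#' @return a \linkS4class{NormalizedCurve} with \code{nAveraged} set and
#'   per-point SEM.
#' @export
averageCurves <- function(curves, resample = FALSE) {
  if (!length(curves)) stop("empty curve list")
  stopifnot(all(vapply(curves, is, logical(1), "NormalizedCurve")))
  ref <- curves[[1]]
  Rmat <- vapply(curves, function(cv) {
    if (isTRUE(all.equal(cv@t, ref@t))) return(cv@R)
    if (!resample)
      stop("incompatible time grids; set resample = TRUE to interpolate")
    approx(cv@t, cv@R, xout = ref@t, rule = 2)$y
  }, numeric(length(ref@t)))
  Rmat <- matrix(Rmat, nrow = length(ref@t))
  n <- length(curves)
  Rm <- rowMeans(Rmat)
  sem <- if (n > 1) apply(Rmat, 1, sd) / sqrt(n) else rep(NA_real_, nrow(Rmat))
  new("NormalizedCurve", t = ref@t, R = Rm, sem = sem,
      bleachIndex = ref@bleachIndex, nAveraged = as.integer(n))
}

#' Fit the empirical FRAP recovery model
#'
#' Fits R(t) = R(0) - a + a (1 - b) (1 - exp(-t / tau)) to the post-bleach
#' frames of a recovery curve by bounded trust-region least squares
#' (Levenberg-Marquardt). Post-bleach times are shifted so t = 0 at the
#' first post-bleach frame. R(0) is fixed to the pre-bleach mean: the model
#' has three unknowns (a, b, tau) and a free offset degrades their
#' identifiability. 95% confidence bounds come from the fit covariance,
#' with the sampling uncertainty of the fixed R(0) (variance of the
#' pre-bleach mean) propagated into each parameter by the delta method -
#' without this term the intervals are anticonservative, since an error in
#' R(0) shifts a and b coherently.
#'
#' Bounds are a, b in [0, 1] and tau in (0, 10 t_max]; the start point is
#' a = 1 - R(first post-bleach frame), b = 0.2 and tau from the half-rise
#' time. A parameter converging onto a bound (e.g. b = 1 for a fully
#' immobile, flat curve, where tau is unidentifiable) is flagged.
#'
#' @param curve a \linkS4class{NormalizedCurve} with >= 10 post-bleach
#'   points.
#' @return a \linkS4class{FrapFit}.
#' @examples
#' rec <- simulateFrapRecord(makePreset("control"), seed = 1, noiseSd = 0)
#' coef(fitRecovery(doubleNormalize(rec)))  # recovers a, b, tau exactly
#' @export
fitRecovery <- function(curve) {
  stopifnot(is(curve, "NormalizedCurve"))
  bi <- curve@bleachIndex
  post <- seq_along(curve@t) >= bi
  if (sum(post) < 10) stop("need >= 10 post-bleach points")
  R0 <- mean(curve@R[seq_len(bi - 1L)])
  tp <- curve@t[post] - curve@t[bi]
  Rp <- curve@R[post]
  tmax <- max(tp)

  aStart <- min(max(R0 - Rp[1], 1e-3), 1)
  ## half-rise time of the observed recovery as a tau start
  span <- Rp[length(Rp)] - Rp[1]
  tauStart <- if (span > 1e-8) {
    ihalf <- which(Rp - Rp[1] >= span / 2)[1]
    max(tp[ihalf], tmax / 50, 1e-3)
  } else tmax / 5
  start <- list(a = aStart, b = 0.2, tau = tauStart)

  doFit <- function(R0val, startList)
    minpack.lm::nlsLM(
      Rp ~ R0val - a + a * (1 - b) * (1 - exp(-tp / tau)),
      data = data.frame(tp = tp, Rp = Rp, R0val = R0val),
      start = startList,
      lower = c(a = 0, b = 0, tau = 1e-6),
      upper = c(a = 1, b = 1, tau = 10 * tmax),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  fitErr <- NULL
  fit <- tryCatch(doFit(R0, start),
                  error = function(e) { fitErr <<- e; NULL })
  if (is.null(fit)) {
    if (diff(range(Rp)) <= 1e-8 * max(abs(Rp), 1)) {
      ## exactly flat recovery: a = R0 - R(post), b at its upper bound,
      ## tau unidentifiable
      aHat <- R0 - mean(Rp)
      q <- qt(0.975, df = length(Rp) - 1L)
      seA <- sd(Rp) / sqrt(length(Rp))
      ci <- rbind(a = c(aHat - q * seA, aHat + q * seA),
                  b = c(NA_real_, NA_real_),
                  tau = c(NA_real_, NA_real_))
      colnames(ci) <- c("lower", "upper")
      return(new("FrapFit",
                 estimates = c(R0 = unname(R0), a = unname(aHat), b = 1,
                               tau = NA_real_),
                 ci95 = ci,
                 flags = c("degenerate flat recovery",
                           "b pinned at bound; tau unidentifiable"),
                 fit = NULL, nPost = as.integer(sum(post))))
    }
    stop("recovery fit failed to converge: ", conditionMessage(fitErr))
  }
  est <- coef(fit)
  flags <- character()
  tolb <- 1e-6
  if (est["a"] <= tolb || est["a"] >= 1 - tolb)
    flags <- c(flags, "a pinned at bound")
  if (est["b"] <= tolb || est["b"] >= 1 - tolb)
    flags <- c(flags, "b pinned at bound; tau may be unidentifiable")
  if (est["tau"] >= 10 * tmax - tolb)
    flags <- c(flags, "tau pinned at upper bound")

  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  ## delta-method propagation of the sampling error of the fixed R0
  preR <- curve@R[seq_len(bi - 1L)]
  if (bi > 2L && sd(preR) > 0) {
    seR0 <- sd(preR) / sqrt(bi - 1L)
    h <- max(seR0, 1e-4)
    grad <- tryCatch({
      estH <- coef(doFit(R0 + h, as.list(est)))
      (estH - est) / h
    }, error = function(e) rep(0, 3))
    se <- sqrt(se^2 + grad^2 * seR0^2)
  }
  q <- qt(0.975, df = length(Rp) - 3L)
  ci <- cbind(lower = est - q * se, upper = est + q * se)
  rownames(ci) <- names(est)

  new("FrapFit",
      estimates = c(R0 = unname(R0), est),
      ci95 = ci, flags = flags, fit = fit, nPost = as.integer(sum(post)))
}

#' Do two fitted parameters have overlapping 95% confidence intervals?
#'
#' Significance between two conditions is assessed by the extent of overlap
#' between the confidence intervals of the fitted parameters: disjoint
#' intervals indicate a significant difference.
#'
#' @param fit1,fit2 \linkS4class{FrapFit} objects.
#' @param param parameter name: "a", "b" or "tau".
#' @return TRUE if the 95% intervals overlap.
#' @export
ciOverlaps <- function(fit1, fit2, param = "b") {
  c1 <- fit1@ci95[param, ]; c2 <- fit2@ci95[param, ]
  c1["lower"] <= c2["upper"] && c2["lower"] <= c1["upper"]
}

setMethod("show", "NormalizedCurve", function(object) {
  cat(sprintf(
    "NormalizedCurve: %d frames (%d pre-bleach), %d curve(s) averaged\n",
    length(object@t), object@bleachIndex - 1L, object@nAveraged))
  cat(sprintf("  pre-bleach mean R = %.4f, final R = %.4f\n",
              mean(object@R[seq_len(object@bleachIndex - 1L)]),
              object@R[length(object@R)]))
})

setMethod("show", "FrapFit", function(object) {
  e <- object@estimates
  cat("FrapFit (R0 fixed to pre-bleach mean)\n")
  cat(sprintf("  R0 = %.4f\n", e["R0"]))
  for (p in c("a", "b", "tau"))
    cat(sprintf("  %-3s = %.4f  [95%% CI %.4f, %.4f]\n", p, e[p],
                object@ci95[p, "lower"], object@ci95[p, "upper"]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
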