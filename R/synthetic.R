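#' @include AllClasses.R
NULL

#' Construct a synthetic-wound specification
#'
#' Defaults describe a 128 x 128 photograph of a granulation-dominant
#' chronic wound: a flat skin-toned background (high S-channel contrast
#' against the wound bed), an elliptical wound partitioned into
#' contiguous angular sectors of granulation (light red), slough
#' (yellow fibrinous) and necrotic (black) tissue at proportions
#' 64.3 / 16.6 / 19.1 percent, per-pixel Gaussian color jitter, a
#' sinusoidal texture inside the wound, and image-wide salt-and-pepper
#' impulses emulating rapid photography.
#'
#' @param width,height image size (at least 16).
#' @param skin background RGB color.
#' @param center ellipse center \code{c(row, col)}.
#' @param axes ellipse semi-axes \code{c(a, b)} in pixels.
#' @param rotation ellipse rotation in degrees.
#' @param fractions tissue fractions (granulation, slough, necrotic)
#'   summing to 1.
#' @param tissueColors 3 x 3 matrix of mean RGB colors (rows in tissue
#'   order).
#' @param jitterSd per-pixel Gaussian color jitter SD (gray levels).
#' @param impulseFrac fraction of pixels replaced by impulses.
#' @param textureAmp sinusoidal texture amplitude (gray levels).
#' @param seed RNG seed.
#' @return a \linkS4class{WoundSpec}.
#' @export
woundSpec <- function(width = 128, height = 128,
                      skin = c(225, 190, 160),
                      center = c(height / 2, width / 2),
                      axes = c(0.3 * width, 0.22 * height),
                      rotation = 0,
                      fractions = c(0.643, 0.166, 0.191),
                      tissueColors = rbind(granulation = c(180, 40, 50),
                                           slough = c(200, 180, 80),
                                           necrotic = c(30, 25, 25)),
                      jitterSd = 8, impulseFrac = 0.02,
                      textureAmp = 10, seed = 1) {
  new("WoundSpec", width = width, height = height, skin = skin,
      center = center, axes = axes, rotation = rotation,
      fractions = fractions, tissueColors = as.matrix(tissueColors),
      jitterSd = jitterSd, impulseFrac = impulseFrac,
      textureAmp = textureAmp, seed = seed)
}

#' Generate a synthetic wound image with ground truth
#'
#' Renders the specification deterministically (bit-identical for a fixed
#' seed). The wound ellipse is partitioned into contiguous angular
#' sectors whose pixel counts match the tissue fractions to within
#' rounding; tissue masks are pairwise disjoint and union to the wound
#' mask. Jitter and texture are applied inside the wound only; impulses
#' hit the whole image.
#'
#' @param spec a \linkS4class{WoundSpec}.
#' @param id identifier for the generated image.
#' @return list with \code{image} (\linkS4class{RGBImage}),
#'   \code{woundMask}, \code{tissueMasks} (named list of three logical
#'   matrices) and \code{regions} (list of \linkS4class{TissueRegion}s
#'   for the non-empty tissues).
#' @export
generateWound <- function(spec, id = sprintf("synthetic_%d", spec@seed)) {
  stopifnot(is(spec, "WoundSpec"))
  validObject(spec)
  set.seed(spec@seed)
  h <- spec@height; w <- spec@width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  th <- spec@rotation * pi / 180
  dy <- rows - spec@center[1]; dx <- cols - spec@center[2]
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  wound <- (xr / spec@axes[1])^2 + (yr / spec@axes[2])^2 <= 1
  n <- sum(wound)
  if (n < 48) stop("infeasible geometry: wound too small for three regions")

  ## contiguous angular sectors with pixel counts matching the fractions
  ang <- atan2(yr[wound], xr[wound])
  ord <- order(ang)
  cuts <- round(cumsum(spec@fractions) * n)
  sector <- integer(n)
  sector[ord] <- rep.int(1:3, times = diff(c(0, cuts)))
  tissueMasks <- lapply(1:3, function(k) {
    m <- matrix(FALSE, h, w); m[wound][sector == k] <- TRUE; m
  })
  names(tissueMasks) <- tissueClasses()

  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- spec@skin[k]
  tex <- spec@textureAmp * sin(2 * pi * rows / 8) * sin(2 * pi * cols / 8)
  for (t in 1:3) {
    m <- tissueMasks[[t]]
    nm <- sum(m)
    if (nm == 0) next
    for (k in 1:3)
      px[, , k][m] <- spec@tissueColors[t, k] + tex[m] +
        stats::rnorm(nm, 0, spec@jitterSd)
  }
  ## salt-and-pepper impulses, image-wide
  nImp <- round(spec@impulseFrac * h * w)
  if (nImp > 0) {
    at <- sample.int(h * w, nImp)
    val <- sample(c(0, 255), nImp, replace = TRUE)
    for (k in 1:3) { pl <- px[, , k]; pl[at] <- val; px[, , k] <- pl }
  }
  px <- round(pmin(pmax(px, 0), 255))

  regions <- list()
  for (t in 1:3)
    if (sum(tissueMasks[[t]]) >= 16)
      regions[[length(regions) + 1]] <-
        tissueRegion(tissueMasks[[t]], tissueClasses()[t], id)
  list(image = rgbImage(px, id = id), woundMask = wound,
       tissueMasks = tissueMasks, regions = regions)
}

#' Generate a reproducible multi-image benchmark suite
#'
#' Draws \code{n} wound specifications with randomized geometry and
#' tissue fractions and renders each. Fractions emulate the tissue
#' balance of clinical chronic-wound corpora, where necrotic tissue is
#' the minority class: granulation is drawn uniformly in
#' \code{[0.45, 0.60]}, necrotic in \code{[0.05, 0.12]}, slough takes the
#' remainder.
#'
#' @param n number of images (at least 1).
#' @param seed RNG seed; all per-image seeds derive from it.
#' @param width,height image size passed to every spec.
#' @return list of \code{n} results of \code{\link{generateWound}}.
#' @export
makeBenchmark <- function(n, seed = 1, width = 128, height = 128) {
  if (n < 1) stop("'n' must be at least 1")
  set.seed(seed)
  draws <- data.frame(
    g = stats::runif(n, 0.45, 0.60),
    nec = stats::runif(n, 0.05, 0.12),
    a = stats::runif(n, 0.24, 0.34) * width,
    b = stats::runif(n, 0.16, 0.26) * height,
    rot = stats::runif(n, 0, 180),
    cy = height / 2 + stats::runif(n, -0.05, 0.05) * height,
    cx = width / 2 + stats::runif(n, -0.05, 0.05) * width)
  lapply(seq_len(n), function(i) {
    sp <- woundSpec(width = width, height = height,
                    center = c(draws$cy[i], draws$cx[i]),
                    axes = c(draws$a[i], draws$b[i]),
                    rotation = draws$rot[i],
                    fractions = c(draws$g[i], 1 - draws$g[i] - draws$nec[i],
                                  draws$nec[i]),
                    seed = (seed %% 100000L) * 1000L + i)
    generateWound(sp, id = sprintf("bench_%d_%d", seed, i))
  })
}
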