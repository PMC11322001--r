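# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in pN um / K
#'
#' `1.380649e-23 J/K = 1.380649e-5 pN um / K`; all mechanics in this package
#' use pN, um, s so that bending stiffness comes out in pN um^2 and diffusion
#' coefficients in um^2/s.
#' @keywords internal
.kB <- 1.380649e-5  # pN um / K

#' Thermal energy k_B T in pN um
#'
#' @param temperature temperature in kelvin.
#' @return thermal energy in pN um (4.045e-3 pN um at 293 K).
#' @export
kBT <- function(temperature = 293) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

stop_if_not_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (y rows, x columns)", name),
         call. = FALSE)
  invisible(x)
}

# Bilinear interpolation of raster `im` (rows = y, cols = x) at 0-based
# pixel-center coordinates (x, y) in pixel units. Points outside return `fill`.
bilinear <- function(im, x, y, fill = 0) {
  nr <- nrow(im); nc <- ncol(im)
  j <- x; i <- y                       # 0-based continuous indices
  j0 <- floor(j); i0 <- floor(i)
  fj <- j - j0; fi <- i - i0
  j0 <- j0 + 1L; i0 <- i0 + 1L        # to 1-based corner index
  out <- numeric(length(x)); out[] <- fill
  ok <- j0 >= 1 & i0 >= 1 & j0 + 1 <= nc & i0 + 1 <= nr
  # clamp points on the last row/col onto the edge cell
  edge <- (j0 == nc & fj == 0) | (i0 == nr & fi == 0)
  ok <- ok | (edge & j0 >= 1 & i0 >= 1 & j0 <= nc & i0 <= nr)
  j1 <- pmin(j0 + 1L, nc); i1 <- pmin(i0 + 1L, nr)
  k <- which(ok)
  if (length(k)) {
    v00 <- im[cbind(i0[k], j0[k])]; v01 <- im[cbind(i0[k], j1[k])]
    v10 <- im[cbind(i1[k], j0[k])]; v11 <- im[cbind(i1[k], j1[k])]
    out[k] <- (1 - fi[k]) * ((1 - fj[k]) * v00 + fj[k] * v01) +
      fi[k] * ((1 - fj[k]) * v10 + fj[k] * v11)
  }
  out
}

# Mode of the lowest-intensity quartile, used as the default background level.
estimate_background <- function(image) {
  stop_if_not_raster(image)
  v <- as.numeric(image)
  low <- v[v <= quantile(v, 0.25)]
  if (length(unique(low)) == 1L) return(low[1])
  d <- density(low, n = 512)
  d$x[which.max(d$y)]
}

# Otsu threshold on an arbitrary-range raster (EBImage works on [0, 1]).
otsu_threshold <- function(image) {
  stop_if_not_raster(image)
  r <- range(image)
  if (diff(r) == 0)
    stop("Otsu threshold undefined for a constant image; use a fixed threshold",
         call. = FALSE)
  th01 <- EBImage::otsu(EBImage::Image((image - r[1]) / diff(r)),
                        range = c(0, 1), levels = 256)
  r[1] + th01 * diff(r)
}

ebi <- function(m) EBImage::Image(m)
as_matrix <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}
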