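## Small shared helpers.

## Earth mean radius in km used for all great-circle distances.
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix between populations
#'
#' Haversine distances (km, Earth radius 6371.0088 km) between rows of a
#' coordinate table.
#'
#' @param coords data.frame with columns `pop`, `lat`, `lon` in decimal
#'   degrees.
#' @return a [DistancePair-class] of kind `"geographic_km"`.
#' @export
geographicDistances <- function(coords) {
  stopifnot(all(c("pop", "lat", "lon") %in% colnames(coords)))
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(coords$pop, coords$pop))
  if (n > 1) {
    pts <- cbind(coords$lon, coords$lat)
    for (i in seq_len(n - 1)) {
      d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                    pts[(i + 1):n, , drop = FALSE],
                                    r = .EARTH_RADIUS_KM * 1000) / 1000
      m[i, (i + 1):n] <- d
      m[(i + 1):n, i] <- d
    }
  }
  new("DistancePair", matrix = m, kind = "geographic_km")
}

## Weighted quantiles (type-7-like interpolation on the weighted ECDF).
.weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  })
}

## Draw independent child seeds (31-bit) from the current RNG stream.
.childSeeds <- function(n) sample.int(.Machine$integer.max, n)

## Nei's unbiased gene diversity from allele counts (gene copies).
.neiUnbiased <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' @keywords internal
"_PACKAGE"

#' @useDynLib peonypop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dist lm optim prcomp pgamma quantile rnorm runif
#'   rbinom rpois rexp rmultinom sd var vcov predict coef setNames
#'   na.omit complete.cases p.adjust pt dpois as.dist
#' @importFrom utils read.csv write.csv head
NULL
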