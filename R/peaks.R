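# Local-maximum detection with topographic prominence.
#
# A peak's prominence is its height above the higher of the two minima
# separating it from the nearest higher terrain on either side (or from the
# signal boundary). Plateau maxima report their middle bin.

peak_prominence <- function(counts, p) {
  n <- length(counts)
  h <- counts[p]
  left_min <- h
  i <- p - 1L
  while (i >= 1L && counts[i] <= h) {
    if (counts[i] < left_min) left_min <- counts[i]
    i <- i - 1L
  }
  right_min <- h
  i <- p + 1L
  while (i <= n && counts[i] <= h) {
    if (counts[i] < right_min) right_min <- counts[i]
    i <- i + 1L
  }
  h - max(left_min, right_min)
}

# Returns a data.frame(index, height, prominence) of interior local maxima.
find_profile_peaks <- function(counts) {
  n <- length(counts)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)
  pk <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (counts[i] > counts[i - 1L]) {
      j <- i
      while (j < n && counts[j + 1L] == counts[i]) j <- j + 1L
      if (j <= n - 1L && counts[j + 1L] < counts[i]) {
        pk <- c(pk, as.integer((i + j) %/% 2L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(pk) == 0) return(empty)
  data.frame(
    index = pk,
    height = counts[pk],
    prominence = vapply(pk, function(p) peak_prominence(counts, p), numeric(1))
  )
}
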