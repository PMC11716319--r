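# Shared fixtures, built in code.

# Binary annulus matrix: pixels whose center radius lies in [rIn, rOut]
# (pixel units), centered in an n x n grid.
ringMatrix <- function(n, rIn, rOut) {
  c0 <- n / 2
  x <- (seq_len(n) - 0.5) - c0
  r <- sqrt(outer(x^2, x^2, `+`))
  matrix(as.integer(r >= rIn & r <= rOut), n, n)
}

# A straight tract list as stored in a TractSet.
straightTract <- function(from, to, n = 20, status = "raw",
                          extrapolated = NA_real_) {
  pts <- cbind(seq(from[1], to[1], length.out = n),
               seq(from[2], to[2], length.out = n),
               seq(from[3], to[3], length.out = n))
  list(points = pts, raw_length = sqrt(sum((to - from)^2)),
       extrapolated_length = extrapolated, status = status,
       reason = NA_character_)
}

newTractSet <- function(tracts, stepMm = 1) {
  new("TractSet", tracts = tracts, stepMm = stepMm, seed = NA_integer_,
      nSeeded = length(tracts))
}

# ThicknessMap built directly from a sample vector.
mapFromSamples <- function(th) {
  new("ThicknessMap",
      samples = data.frame(slice = 1L, x_mm = seq_along(th), y_mm = 0,
                           thickness_mm = th),
      spacing = c(0.3, 0.3, 3), flags = list())
}
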