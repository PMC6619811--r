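# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Resize an intensity matrix to size x size with bilinear
# interpolation, back on the integer grid.
resize_crop <- function(m, size, i_max = 255L) {
  if (nrow(m) == size && ncol(m) == size) {
    storage.mode(m) <- "integer"
    return(m)
  }
  out <- EBImage::resize(matrix(as.numeric(m) / i_max, nrow(m), ncol(m)),
                         w = size, h = size)
  out <- round_half_up(pmin(pmax(out, 0), 1) * i_max)
  storage.mode(out) <- "integer"
  out
}
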