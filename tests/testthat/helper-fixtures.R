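# Shared fixtures: all synthetic, built in code at test time.

# small slide used across stain-model tests (cached per session)
small_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- slide_spec(400, 400, nucleus_count = 40, particle_count = 15,
                         seed = 3)
      cache <<- generate_slide(spec)
    }
    cache
  }
})

# recursive flood-fill labeling oracle, 8-connectivity, for tiny rasters
flood_label_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        for (di in -1:1) for (dj in -1:1) {
          if (di != 0 || dj != 0) stack[[length(stack) + 1]] <- c(p[1] + di, p[2] + dj)
        }
      }
    }
  }
  lab
}

# nearest-ground-truth matching error for recovered centroids
centroid_errors <- function(found, truth) {
  vapply(seq_len(nrow(found)), function(i) {
    min(sqrt((truth$x - found$x[i])^2 + (truth$y - found$y[i])^2))
  }, numeric(1))
}
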