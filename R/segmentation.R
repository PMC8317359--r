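# 26-connected neighbourhood offsets (excluding the centre voxel)
offsets26 <- function() {
  g <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Vectorised BFS over a logical array starting from linear index `start`.
# Returns a logical array marking the 26-connected component of `start`.
connected_component26 <- function(candidate, start) {
  d <- dim(candidate)
  visited <- array(FALSE, d)
  if (!candidate[start]) return(visited)
  offs <- offsets26()
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    co <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nr <- co[, 1] + offs[k, 1]
      nc <- co[, 2] + offs[k, 2]
      ns <- co[, 3] + offs[k, 3]
      ok <- nr >= 1L & nr <= d[1] & nc >= 1L & nc <= d[2] &
        ns >= 1L & ns <= d[3]
      if (!any(ok)) next
      lin <- nr[ok] + (nc[ok] - 1L) * d[1] + (ns[ok] - 1L) * d[1] * d[2]
      lin <- lin[candidate[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  visited
}

#' Segment a tumour VOI at a fixed fraction of SUVmax
#'
#' Thresholds the volume at `fraction * max(SUV)` (the clinical default
#' is 42% SUVmax) and keeps the 26-connected component containing the
#' hottest voxel, so that disjoint avid structures elsewhere in the field
#' of view are not swept into the tumour VOI.
#'
#' @param volume a [pet_volume()] with a strictly positive maximum.
#' @param fraction threshold as a fraction of the global SUVmax
#'   (default 0.42).
#' @return a [voi_mask()] marking the segmented tumour.
#' @export
#' @examples
#' v <- pet_volume(array(c(1, 5, 10, 5, 1), c(5, 1, 1)), c(1, 1, 1))
#' sum(segment_voi(v)$mask)  # 3 voxels at threshold 4.2
segment_voi <- function(volume, fraction = 0.42) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("`fraction` must be a single number in (0, 1)")
  mx <- max(volume$suv)
  if (mx <= 0) stop("volume has no positive uptake; cannot segment")
  candidate <- volume$suv >= fraction * mx
  start <- which.max(volume$suv)
  voi_mask(connected_component26(candidate, start))
}
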