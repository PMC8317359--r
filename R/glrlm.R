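# Extract all maximal same-level runs along one in-plane direction,
# pooled across axial slices.  Runs are broken by out-of-mask voxels.
# Returns a two-column matrix (grey level, run length); one row per run.
glrlm_runs <- function(q, angle) {
  lev <- q$levels
  d <- dim(lev)
  collect <- function(v) {
    r <- rle(as.vector(v))
    keep <- !is.na(r$values)
    cbind(g = r$values[keep], l = r$lengths[keep])
  }
  if (angle == 0L) {
    # runs along columns: lines indexed by (row, slice)
    ap <- aperm(lev, c(2L, 1L, 3L))
    m <- rbind(matrix(ap, nrow = d[2]), NA_integer_)
    return(collect(m))
  }
  if (angle == 90L) {
    # runs along rows: lines indexed by (col, slice)
    m <- rbind(matrix(lev, nrow = d[1]), NA_integer_)
    return(collect(m))
  }
  # diagonals, per slice
  out <- vector("list", d[3])
  for (s in seq_len(d[3])) {
    sl <- lev[, , s]
    key <- if (angle == 45L) row(sl) + col(sl) else row(sl) - col(sl)
    grp <- split(sl, key)              # within a diagonal: column-major order
    v <- unlist(lapply(grp, function(x) c(x, NA_integer_)),
                use.names = FALSE)
    out[[s]] <- collect(v)
  }
  do.call(rbind, out)
}

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
  "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
  "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
  "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
  "LongRunHighGreyLevelEmphasis")

#' Grey-level run-length features along one direction
#'
#' Counts maximal constant-level runs along the given in-plane direction
#' (pooled across axial slices; runs break at mask boundaries) and
#' returns the ten standard normalised run-length features.  The
#' `offset` argument is a direction-family label carried so that feature
#' names of the form `..._offset4` parse uniformly with the
#' co-occurrence family; it does not change the computation.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 10 features.
#' @export
#' @examples
#' q <- quantized_voi(array(c(1L, 1L, 2L), c(1, 3, 1)), 2)
#' glrlm_features(q, 0)[c("ShortRunEmphasis", "LongRunEmphasis")]
glrlm_features <- function(q, angle, offset = 1L) {
  stopifnot(inherits(q, "quantized_voi"))
  runs <- glrlm_runs(q, as.integer(angle))
  if (is.null(runs) || nrow(runs) == 0L) {
    out <- rep(0, length(glrlm_feature_names))
    names(out) <- glrlm_feature_names
    return(out)
  }
  g <- runs[, "g"]
  l <- runs[, "l"]
  nr <- nrow(runs)
  c(ShortRunEmphasis = sum(1 / l^2) / nr,
    LongRunEmphasis = sum(l^2) / nr,
    GreyLevelNonuniformity = sum(tabulate(g)^2) / nr,
    RunLengthNonuniformity = sum(tabulate(l)^2) / nr,
    LowGreyLevelRunEmphasis = sum(1 / g^2) / nr,
    HighGreyLevelRunEmphasis = sum(g^2) / nr,
    ShortRunLowGreyLevelEmphasis = sum(1 / (g^2 * l^2)) / nr,
    ShortRunHighGreyLevelEmphasis = sum(g^2 / l^2) / nr,
    LongRunLowGreyLevelEmphasis = sum(l^2 / g^2) / nr,
    LongRunHighGreyLevelEmphasis = sum(g^2 * l^2) / nr)
}
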