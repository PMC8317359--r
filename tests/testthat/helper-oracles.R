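# Independent brute-force oracles.  These enumerate pairs, runs and
# zones with explicit loops and never share code with the package's
# vectorised implementations.

# --- co-occurrence ---------------------------------------------------

oracle_glcm_matrix <- function(slice, angle, offset) {
  step <- switch(as.character(angle),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(-1L, 0L), "135" = c(-1L, -1L)) * offset
  ng <- max(slice, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(slice))) {
    for (c in seq_len(ncol(slice))) {
      for (sgn in c(1L, -1L)) {
        r2 <- r + sgn * step[1]
        c2 <- c + sgn * step[2]
        if (r2 < 1 || r2 > nrow(slice) || c2 < 1 || c2 > ncol(slice))
          next
        a <- slice[r, c]
        b <- slice[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a, b] <- counts[a, b] + 1
      }
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

oracle_glcm_features <- function(slice, angle, offset) {
  p <- oracle_glcm_matrix(slice, angle, offset)
  if (is.null(p)) return(setNames(rep(0, 8), c(
    "GLCMEnergy", "GLCMEntropy", "Inertia", "Correlation",
    "InverseDifferenceMoment", "ClusterShade", "ClusterProminence",
    "HaralickCorrelation")))
  ng <- nrow(p)
  energy <- entropy <- inertia <- idm <- shade <- prom <- 0
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  s2 <- 0
  for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * p[i, j]
  cor_num <- hc_num <- 0
  for (i in 1:ng) {
    for (j in 1:ng) {
      v <- p[i, j]
      energy <- energy + v^2
      if (v > 0) entropy <- entropy - v * log2(v)
      inertia <- inertia + v * (i - j)^2
      idm <- idm + v / (1 + (i - j)^2)
      shade <- shade + v * (i + j - 2 * mu)^3
      prom <- prom + v * (i + j - 2 * mu)^4
      cor_num <- cor_num + (i - mu) * (j - mu) * v
      hc_num <- hc_num + i * j * v
    }
  }
  corr <- if (s2 > 0) cor_num / s2 else 0
  hcorr <- if (s2 > 0) (hc_num - mu^2) / s2 else 0
  c(GLCMEnergy = energy, GLCMEntropy = entropy, Inertia = inertia,
    Correlation = corr, InverseDifferenceMoment = idm,
    ClusterShade = shade, ClusterProminence = prom,
    HaralickCorrelation = hcorr)
}

# --- run length ------------------------------------------------------

# walk every line of the slice in the given direction and enumerate
# maximal runs explicitly
oracle_glrlm_runs <- function(slice, angle) {
  step <- switch(as.character(angle),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(1L, 0L), "135" = c(1L, 1L))
  nr <- nrow(slice)
  nc <- ncol(slice)
  # line starts: cells with no predecessor along -step
  starts <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      pr <- r - step[1]
      pc <- c - step[2]
      if (pr < 1 || pr > nr || pc < 1 || pc > nc)
        starts[[length(starts) + 1L]] <- c(r, c)
    }
  }
  runs <- NULL
  for (st in starts) {
    r <- st[1]; c <- st[2]
    cur <- NA_integer_
    len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- slice[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
        cur <- v
        len <- if (is.na(v)) 0L else 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
  }
  runs
}

oracle_glrlm_features <- function(slice, angle) {
  runs <- oracle_glrlm_runs(slice, angle)
  g <- runs[, 1]
  l <- runs[, 2]
  n <- nrow(runs)
  gl_counts <- table(g)
  rl_counts <- table(l)
  c(ShortRunEmphasis = sum(1 / l^2) / n,
    LongRunEmphasis = sum(l^2) / n,
    GreyLevelNonuniformity = sum(as.numeric(gl_counts)^2) / n,
    RunLengthNonuniformity = sum(as.numeric(rl_counts)^2) / n,
    LowGreyLevelRunEmphasis = sum(1 / g^2) / n,
    HighGreyLevelRunEmphasis = sum(g^2) / n,
    ShortRunLowGreyLevelEmphasis = sum(1 / (g^2 * l^2)) / n,
    ShortRunHighGreyLevelEmphasis = sum(g^2 / l^2) / n,
    LongRunLowGreyLevelEmphasis = sum(l^2 / g^2) / n,
    LongRunHighGreyLevelEmphasis = sum(g^2 * l^2) / n)
}

# --- zone size -------------------------------------------------------

# recursive flood fill (8-connected within the 2-D slice)
oracle_zones <- function(slice) {
  nr <- nrow(slice)
  nc <- ncol(slice)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (seen[r, c] || is.na(slice[r, c])) next
      lev <- slice[r, c]
      stack <- list(c(r, c))
      seen[r, c] <- TRUE
      size <- 0L
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (dr in -1:1) {
          for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            r2 <- cur[1] + dr
            c2 <- cur[2] + dc
            if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
            if (seen[r2, c2] || is.na(slice[r2, c2])) next
            if (slice[r2, c2] == lev) {
              seen[r2, c2] <- TRUE
              stack[[length(stack) + 1L]] <- c(r2, c2)
            }
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(g = lev, s = size)
    }
  }
  do.call(rbind, zones)
}

oracle_glzsm_features <- function(slice) {
  z <- oracle_zones(slice)
  g <- as.numeric(z[, "g"])
  s <- as.numeric(z[, "s"])
  n <- nrow(z)
  nv <- sum(!is.na(slice))
  cellp <- as.numeric(table(paste(g, s))) / n
  pg <- as.numeric(table(g)) / n
  iv <- sum(as.numeric(table(g))^2) / n
  szv <- sum(as.numeric(table(s))^2) / n
  inv_gs <- 1 / (g * s)
  gs <- g * s
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    IntensityVariability = iv,
    SizeZoneVariability = szv,
    ZonePercentage = n / nv,
    LowIntensityEmphasis = mean(1 / g^2),
    HighIntensityEmphasis = mean(g^2),
    LowIntensitySmallAreaEmphasis = mean(1 / (g^2 * s^2)),
    HighIntensitySmallAreaEmphasis = mean(g^2 / s^2),
    LowIntensityLargeAreaEmphasis = mean(s^2 / g^2),
    HighIntensityLargeAreaEmphasis = mean(g^2 * s^2),
    GreyLevelVariance = mean((g - mean(g))^2),
    ZoneSizeVariance = mean((s - mean(s))^2),
    ZoneSizeEntropy = -sum(cellp * log2(cellp)),
    GreyLevelEntropy = -sum(pg * log2(pg)),
    SmallAreaLowIntensityVariance = mean((inv_gs - mean(inv_gs))^2),
    LargeAreaHighIntensityVariance = mean((gs - mean(gs))^2),
    ZoneMean = mean(s),
    ZoneMax = max(s),
    NormalizedIntensityVariability = iv / n,
    NormalizedSizeZoneVariability = szv / n)
}

# --- statistics ------------------------------------------------------

# AUC by explicit pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# exact permutation two-sided p for the Mann-Whitney U
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  nn <- length(pooled)
  rk <- rank(pooled)
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  obs_u <- min(u1, n1 * (nn - n1) - u1)
  mu <- n1 * (nn - n1) / 2
  cmb <- utils::combn(nn, n1)
  us <- apply(cmb, 2, function(ix) {
    rr <- sum(rk[ix])
    uu <- rr - n1 * (n1 + 1) / 2
    min(uu, n1 * (nn - n1) - uu)
  })
  mean(abs(us - mu) >= abs(obs_u - mu))
}

# stratified case-bootstrap p for the DeLong AUC difference
oracle_delong_boot_p <- function(sa, sb, labels, B = 1e5, seed = 99) {
  set.seed(seed)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  psi <- function(s) outer(s[labels == 1], s[labels == 0], ">") +
    0.5 * outer(s[labels == 1], s[labels == 0], "==")
  pa <- psi(sa)
  pb <- psi(sb)
  R <- matrix(sample.int(m, B * m, replace = TRUE), B)
  C <- matrix(sample.int(n, B * n, replace = TRUE), B)
  acc <- numeric(B)
  for (a in seq_len(m)) {
    for (b in seq_len(n)) {
      ix <- cbind(R[, a], C[, b])
      acc <- acc + pa[ix] - pb[ix]
    }
  }
  diffs <- acc / (m * n)
  obs <- mean(pa) - mean(pb)
  2 * pnorm(-abs(obs) / sd(diffs))
}

# random 5x5x1 quantized fixture
random_quantized_slice <- function(seed, ng = 4L) {
  set.seed(seed)
  m <- matrix(sample.int(ng, 25L, replace = TRUE), 5L, 5L)
  mask_out <- matrix(runif(25) < 0.2, 5L, 5L)
  m[mask_out] <- NA_integer_
  if (all(is.na(m))) m[1, 1] <- 1L
  m
}
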