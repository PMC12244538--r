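# Shared fixtures and independent oracles, built in code at test time.

# filled disk mask
diskMask <- function(side, r, ctr = (side + 1) / 2) {
  m <- matrix(0, side, side)
  for (i in seq_len(side)) {
    span <- r^2 - (i - ctr)^2
    if (span >= 0) {
      j <- which((seq_len(side) - ctr)^2 <= span)
      m[i, j] <- 1
    }
  }
  m
}

# filled axis-aligned ellipse mask with semi-axes a (rows) and b (cols)
ellipseMask <- function(side, a, b, ctr = (side + 1) / 2) {
  idx <- expand.grid(i = seq_len(side), j = seq_len(side))
  m <- matrix(0, side, side)
  inside <- ((idx$i - ctr) / a)^2 + ((idx$j - ctr) / b)^2 <= 1
  m[cbind(idx$i[inside], idx$j[inside])] <- 1
  m
}

# brute-force LDP histogram: per-patch mask evaluation, independent of the
# vectorized implementation
bruteForceLDP <- function(gray, k = 3L) {
  masks <- mitoscope:::kirschMasks()
  adm <- mitoscope:::ldpAdmissibleCodes(k)
  codes <- integer(0)
  for (i in 2:(nrow(gray) - 1)) {
    for (j in 2:(ncol(gray) - 1)) {
      patch <- gray[(i - 1):(i + 1), (j - 1):(j + 1)]
      resp <- abs(vapply(masks, function(m) sum(m * patch), numeric(1)))
      top <- order(-resp, seq_along(resp))[seq_len(k)]
      codes <- c(codes, sum(2L^(top - 1L)))
    }
  }
  tabulate(match(codes, adm), length(adm)) / length(codes)
}

# brute-force connected-component labelling (4-connectivity BFS), used as
# the pixel-counting oracle for areas and component count
bruteForceComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  areas <- integer(0)
  for (si in seq_len(H)) for (sj in seq_len(W)) {
    if (mask[si, sj] == 1 && !seen[si, sj]) {
      queue <- list(c(si, sj)); seen[si, sj] <- TRUE; area <- 0L
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]; area <- area + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
              mask[q[1], q[2]] == 1 && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue <- c(queue, list(q))
          }
        }
      }
      areas <- c(areas, area)
    }
  }
  areas
}

# small preprocessed easy tiles for network tests
smokeTiles <- function(n, seedBase, side = 64L, nNuclei = 10L,
                       nMitotic = 2L, genSide = max(side, 48L)) {
  lapply(seq_len(n), function(i)
    preprocessTile(genHETile(tileGenParams(side = genSide,
                                           nNuclei = nNuclei,
                                           nMitotic = nMitotic,
                                           seed = seedBase + i)),
                   side = side))
}

# empirical AUC of a score against binary labels
empiricalAUC <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
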