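# Fixtures shared across test files; everything is generated in code.

# small two-tumor phantom on a coarse grid (fast); noiseless by default
twoTumorSpec <- function(tnrs = c(1, 3), shape = 32L, spacingMM = 6,
                         ...) {
  ctr <- shape * spacingMM / 2
  tum <- data.frame(name = c("T1", "T2"),
                    xMM = ctr + c(-30, 30), yMM = rep(ctr, 2),
                    zMM = rep(ctr, 2), radiusMM = c(14, 11),
                    tnr = tnrs, stringsAsFactors = FALSE)
  phantomSpec(shape = rep(shape, 3L), spacingMM = spacingMM, tumors = tum,
              liverSemiAxesMM = c(85, 70, 60), ...)
}

# tiny hand-built VOI set: 10x10x10 all-liver grid, one cubic tumor
cubeVois <- function(spacingMM = 4.48, tumorIdx = list(4:5, 4:5, 4:5)) {
  g <- gridGeometry(c(10L, 10L, 10L), spacingMM)
  wl <- array(TRUE, dim = c(10, 10, 10))
  t1 <- array(FALSE, dim = c(10, 10, 10))
  t1[tumorIdx[[1]], tumorIdx[[2]], tumorIdx[[3]]] <- TRUE
  voiSet(wl, tumors = list(T1 = t1), geom = g)
}

# brute-force six-level-loop convolution oracle (zero padding), kept
# deliberately independent of the package implementation
bruteConv3d <- function(a, k) {
  d <- dim(a); kd <- dim(k); h <- (kd - 1L) %/% 2L
  out <- array(0, dim = d)
  for (tx in 1:d[1]) for (ty in 1:d[2]) for (tz in 1:d[3]) {
    acc <- 0
    for (sx in 1:d[1]) for (sy in 1:d[2]) for (sz in 1:d[3]) {
      ox <- tx - sx; oy <- ty - sy; oz <- tz - sz
      if (abs(ox) <= h[1] && abs(oy) <= h[2] && abs(oz) <= h[3])
        acc <- acc + a[sx, sy, sz] *
          k[h[1] + 1L + ox, h[2] + 1L + oy, h[3] + 1L + oz]
    }
    out[tx, ty, tz] <- acc
  }
  out
}
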