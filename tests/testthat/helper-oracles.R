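# Independent brute-force oracles and fixture builders. These share no code
# with the package implementation paths they check.

reflectIdx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i + 0  # mirror about the border (1-based)
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

# literal per-pixel Phansalkar evaluation: rescale, circular window with
# reflective padding, t = m (1 + p e^(-q m) + k ((s/r) - 1)), foreground iff
# value > t
oraclePhansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  mn <- min(img); mx <- max(img)
  x <- (img - mn) / (mx - mn)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0L, nr, nc)
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(nrow(offs))
    for (w in seq_len(nrow(offs)))
      vals[w] <- x[reflectIdx(i + offs$a[w], nr), reflectIdx(j + offs$b[w], nc)]
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    t <- m * (1 + p * exp(-q * m) + k * ((s / r) - 1))
    if (x[i, j] > t) out[i, j] <- 1L
  }
  out
}

# per-pixel majority vote in the disc with reflective padding
oracleMedianDisc <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cntF <- 0L
    for (w in seq_len(nrow(offs)))
      if (mask[reflectIdx(i + offs$a[w], nr), reflectIdx(j + offs$b[w], nc)] != 0)
        cntF <- cntF + 1L
    if (2 * cntF > nrow(offs)) out[i, j] <- 1L
  }
  out
}

# exact two-sided Mann-Whitney by full enumeration, with U computed by pair
# counting (greater = 1, tie = 1/2) rather than rank sums
oracleMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  uOf <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  uObs <- uOf(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  allU <- apply(combn(n, n1), 2, uOf)
  list(U = uObs, p = mean(abs(allU - mu) >= abs(uObs - mu) - 1e-9))
}

# noise-free stack with Gaussian nuclei at given 0-based (row, col) centers
blobStack <- function(centers, shape = c(128L, 128L), sigmaPx = 1.5,
                      amplitude = 100, nSlices = 1L,
                      calibration = PixelCalibration(2, 10)) {
  arr <- array(0, dim = c(nSlices, shape[1], shape[2]))
  rows <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2])
  cols <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  for (s in seq_len(nSlices)) {
    sl <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(centers)))
      sl <- sl + amplitude *
        exp(-((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2) / (2 * sigmaPx^2))
    arr[s, , ] <- sl
  }
  ImageStack(arr, calibration)
}

regularPolygon <- function(center, r, n, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  cbind(center[1] + r * sin(th), center[2] + r * cos(th))
}

# small simulated recovery scene shared by several tests
recoveryParams <- function(seed, ...) {
  SimParams(seed = seed, coreRadius = 100, rimThickness = 25,
            maxInvasionDistance = 300, nCore = 250L, nRim = 150L,
            nInvading = 100L, imageShape = c(384L, 384L), depthOffset = 110,
            nSlices = 3L, ...)
}

# minimal stored-entry (uncompressed) ZIP writer for ImageJ ROI containers
crc32table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) else
        bitwShiftR(bitwAnd(c, -2L), 1)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(crc32table[bitwAnd(bitwXor(c, b), 255L) + 1], bitwShiftR(bitwAnd(c, -256L), 8))
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

writeStoredZip <- function(entries, path) {
  out <- raw(0); central <- raw(0); offsets <- integer(length(entries))
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i]); data <- entries[[i]]
    crc <- crc32(data)
    offsets[i] <- length(out)
    local <- c(u32(0x04034b50), u16(20), u16(0), u16(0), u16(0), u16(0),
               u32(crc), u32(length(data)), u32(length(data)),
               u16(length(nm)), u16(0), nm, data)
    out <- c(out, local)
    central <- c(central, u32(0x02014b50), u16(20), u16(20), u16(0), u16(0),
                 u16(0), u16(0), u32(crc), u32(length(data)), u32(length(data)),
                 u16(length(nm)), u16(0), u16(0), u16(0), u16(0), u32(0),
                 u32(offsets[i]), nm)
  }
  cdOff <- length(out)
  out <- c(out, central,
           u32(0x06054b50), u16(0), u16(0), u16(length(entries)),
           u16(length(entries)), u32(length(central)), u32(cdOff), u16(0))
  writeBin(out, path)
  invisible(path)
}
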