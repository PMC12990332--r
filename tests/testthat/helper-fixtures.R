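# Analytic test contours ----------------------------------------------------

make_circle <- function(R = 100, n = 2048L) {
  th <- 2 * pi * (0:(n - 1L)) / n
  as_contour(cbind(R * cos(th), R * sin(th)))
}

# axis-aligned square with corners on the vertex grid
make_square <- function(side = 100, per_side = 64L) {
  t <- seq(0, side, length.out = per_side + 1L)[-(per_side + 1L)]
  pts <- rbind(cbind(t, 0), cbind(side, t), cbind(side - t, side), cbind(0, side - t))
  as_contour(pts)
}

make_ellipse <- function(a = 200, b = 100, n = 2048L) {
  th <- 2 * pi * (0:(n - 1L)) / n
  as_contour(cbind(a * cos(th), b * sin(th)))
}

measure_exact <- function(contour, n = 2048L)
  measure_organoid(contour, config = geometry_config(n_samples = n, smooth_frac = 0))

# polar curvature closed form: shapes r = R (1 + a cos(n theta)) have
# concavities iff a > 1/(1 + n^2) (curvature numerator minimum is
# (1-a)(1 - a (1 + n^2)) at cos(n theta) = -1)
expected_inflections <- function(n_lobes, amplitude)
  if (amplitude > 1 / (1 + n_lobes^2)) 2L * n_lobes else 0L

# Minimal stored-entry ZIP writer (no external zip binary needed) -----------

crc32_tab <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L)) bitwXor(bitwShiftR(cc, 1L), -306674912L) else bitwShiftR(cc, 1L)
    tab[i + 1L] <- cc
  }
  tab
})

crc32 <- function(raw) {
  cc <- -1L
  for (b in as.integer(raw))
    cc <- bitwXor(bitwShiftR(cc, 8L), crc32_tab[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  bitwXor(cc, -1L)
}

zip_store <- function(entries, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    dat <- entries[[i]]
    offsets[i] <- pos
    w4(67324752L)                       # local header signature
    w2(c(20L, 0L, 0L, 0L, 0L))          # version, flags, method=store, time, date
    w4(c(crc32(dat), length(dat), length(dat)))
    w2(c(length(nm), 0L))
    writeBin(nm, con); writeBin(dat, con)
    pos <- pos + 30L + length(nm) + length(dat)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    dat <- entries[[i]]
    w4(33639248L)                       # central directory signature
    w2(c(20L, 20L, 0L, 0L, 0L, 0L))
    w4(c(crc32(dat), length(dat), length(dat)))
    w2(c(length(nm), 0L, 0L, 0L, 0L)); w4(0L)
    w4(offsets[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  w4(101010256L)                        # end of central directory
  w2(c(0L, 0L, length(entries), length(entries)))
  w4(c(pos - cd_start, cd_start)); w2(0L)
  invisible(zipfile)
}
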