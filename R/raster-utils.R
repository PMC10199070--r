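# Internal raster helpers shared by the morphometrics and simulation code.
# Masks are integer/logical matrices indexed [row, col]; foreground = 1.

# Translate a matrix so that out[r, c] == m[r + dr, c + dc], zero padded.
shift_mat <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0L, n1, n2)
  rs <- (1:n1) + dr
  cs <- (1:n2) + dc
  ok_r <- rs >= 1 & rs <= n1
  ok_c <- cs >= 1 & cs <= n2
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Offsets of a disc structuring element of radius r (r = 0 -> single pixel).
disc_offsets <- function(r) {
  if (r <= 0) return(matrix(0L, 1, 2))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, ])
}

dilate_mask <- function(m, offsets) {
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_mat(m, offsets[i, 1], offsets[i, 2]))
  }
  out
}

erode_mask <- function(m, offsets) {
  out <- matrix(1L, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets))) {
    out <- pmin(out, shift_mat(m, offsets[i, 1], offsets[i, 2]))
  }
  out
}

# Morphological closing with a disc of radius r (dilate then erode).
close_mask <- function(m, r) {
  if (r <= 0) return(m)
  off <- disc_offsets(r)
  erode_mask(dilate_mask(m, off), off)
}

# Square (chamfer) dilation used for vessel width: width w (odd) means a
# (w x w) structuring element, radius (w-1)/2.
dilate_square <- function(m, r) {
  if (r <= 0) return(m)
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr != 0L || dc != 0L) out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}

# Connected component of `value` pixels containing seed (4-connectivity),
# via vectorized frontier expansion.  Returns a logical matrix.
flood_component <- function(m, seed_r, seed_c, value = 0L) {
  target <- m == value
  if (!target[seed_r, seed_c]) return(NULL)
  comp <- matrix(FALSE, nrow(m), ncol(m))
  comp[seed_r, seed_c] <- TRUE
  repeat {
    grown <- comp |
      shift_mat(comp * 1L, 1L, 0L) == 1L |
      shift_mat(comp * 1L, -1L, 0L) == 1L |
      shift_mat(comp * 1L, 0L, 1L) == 1L |
      shift_mat(comp * 1L, 0L, -1L) == 1L
    grown <- grown & target
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Fill holes: background components not connected to the border become fg.
fill_holes <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- matrix(0L, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- m
  outside <- flood_component(pad, 1L, 1L, value = 0L)
  filled <- 1L - (outside * 1L)
  matrix(as.integer(filled[2:(n1 + 1L), 2:(n2 + 1L)]), n1, n2)
}

# TRUE where a 2x2 all-foreground block starts (top-left corners).
has_2x2_block <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) return(FALSE)
  b <- m[-nrow(m), -ncol(m)] & m[-1L, -ncol(m)] & m[-nrow(m), -1L] & m[-1L, -1L]
  any(b)
}
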