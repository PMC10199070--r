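# Core OCTA morphometrics: frame averaging, quality gating, binarization,
# topological thinning and the two density metrics.

#' Average repeated OCTA frames of the same eye
#'
#' Pixel-wise mean of co-registered en-face frames, improving signal-to-noise
#' by about sqrt(n).  Frames are assumed pre-registered; an optional integer
#' translation alignment (maximizing cross-correlation against the first
#' frame) is available for small residual shifts.
#'
#' @param frames list of [en_face_angiogram()] objects of identical shape.
#' @param align if `TRUE`, align frames 2..n to the first by integer shift
#'   within `max_shift` pixels before averaging.
#' @param max_shift maximum absolute shift searched per axis (px).
#' @return An [en_face_angiogram()] with the averaged raster; metadata is
#'   taken from the first frame.  A single frame is returned unchanged.
#' @export
average_frames <- function(frames, align = FALSE, max_shift = 5L) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of angiograms")
  if (inherits(frames, "en_face_angiogram")) frames <- list(frames)
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical shape")
  if (length(frames) == 1L) return(frames[[1L]])
  ref <- frames[[1L]]$pixels
  acc <- ref
  for (i in 2:length(frames)) {
    px <- frames[[i]]$pixels
    if (align) px <- align_to(ref, px, max_shift)
    acc <- acc + px
  }
  out <- frames[[1L]]
  out$pixels <- pmin(pmax(acc / length(frames), 0), 1)
  out
}

# Integer-shift alignment by exhaustive cross-correlation search.
align_to <- function(ref, img, max_shift) {
  best <- c(0L, 0L); best_cc <- -Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    sh <- shift_mat(img, dr, dc)
    cc <- sum(ref * sh)
    if (cc > best_cc) { best_cc <- cc; best <- c(dr, dc) }
  }
  shift_mat(img, best[1L], best[2L])
}

#' Signal-strength quality gate
#'
#' An angiogram passes only when its recorded signal strength is strictly
#' greater than `min_signal` (the acquisition rule reads "above 50"
#' literally).  An absent signal strength fails the gate.
#'
#' @param a an [en_face_angiogram()].
#' @param min_signal threshold, default 50.
#' @return logical flag.
#' @export
passes_quality <- function(a, min_signal = 50) {
  ss <- a$signal_strength
  !is.null(ss) && !is.na(ss) && ss > min_signal
}

#' Binarize a vessel-probability raster into a vessel mask
#'
#' A pixel is foreground when its probability is greater than or equal to the
#' threshold (the `>=` boundary convention is pinned and documented).  The
#' physical pixel scale is attached from the nominal scan width; apply
#' [magnification_factor()] afterwards for axial-length correction.
#'
#' @param a an [en_face_angiogram()].
#' @param threshold scalar in (0, 1), default 0.5.
#' @return A `vessel_mask`: list with integer matrix `pixels` and
#'   `scale_um_per_px`.
#' @export
binarize <- function(a, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  m <- matrix(as.integer(a$pixels >= threshold), nrow(a$pixels), ncol(a$pixels))
  structure(list(
    pixels = m,
    scale_um_per_px = a$nominal_scan_width_mm * 1000 / ncol(m)
  ), class = "vessel_mask")
}

#' Vessel mask constructor (for programmatic masks)
#' @param pixels binary (0/1) integer matrix.
#' @param scale_um_per_px physical pixel scale in micrometers per pixel.
#' @export
vessel_mask <- function(pixels, scale_um_per_px = 3000 / ncol(pixels)) {
  if (!all(pixels %in% c(0L, 1L))) stop("mask must be binary")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
                 scale_um_per_px = scale_um_per_px),
            class = "vessel_mask")
}

#' Perfusion density of a vessel mask
#'
#' Ratio of pixels segmented as vasculature to the total number of pixels.
#'
#' @param m a `vessel_mask` (or binary matrix).
#' @return fraction in \[0, 1\].
#' @export
perfusion_density <- function(m) {
  px <- if (inherits(m, "vessel_mask")) m$pixels else m
  if (length(px) == 0L) stop("empty mask")
  sum(px != 0L) / length(px)
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Iterative two-subpass thinning to a 1-px-wide, 8-connectivity-preserving
#' medial skeleton, followed by a redundant-pixel pass that removes the
#' staircase corners the classic scheme can leave so that no 2x2
#' all-foreground block survives.  Connected components are preserved.
#'
#' @param m a `vessel_mask` or binary matrix.
#' @return A `skeleton_mask`: list with binary matrix `pixels`.
#' @export
skeletonize <- function(m) {
  px <- if (inherits(m, "vessel_mask")) m$pixels else m
  sk <- zhang_suen_thin(matrix(as.integer(px != 0L), nrow(px), ncol(px)))
  sk <- prune_2x2(sk)
  structure(list(pixels = sk), class = "skeleton_mask")
}

# Vectorized Zhang-Suen thinning.  Neighbor labels follow the classic scheme:
# p2 = N, p3 = NE, ..., p9 = NW; A = number of 0->1 transitions around p.
zhang_suen_thin <- function(m) {
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, -1L, 0L);  p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);   p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);   p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L);  p9 <- shift_mat(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- if (sub == 1L) {
        (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        # protection: simultaneous deletion must leave every deleted pixel a
        # surviving neighbor, else whole small components (isolated 2x2
        # squares) would vanish and connectivity would not be preserved
        surv <- m & !del
        nbsurv <- matrix(FALSE, nrow(m), ncol(m))
        for (dr in -1:1) for (dc in -1:1) {
          if (dr != 0L || dc != 0L)
            nbsurv <- nbsurv | shift_mat(surv * 1L, dr, dc) == 1L
        }
        del <- del & nbsurv
      }
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Remove pixels of residual 2x2 blocks when deletion is locally safe:
# the foreground 8-neighbors of the pixel must stay in a single 8-connected
# component within the 3x3 neighborhood after deletion.  Sequential scan;
# candidate counts are small after thinning.
prune_2x2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  locally_simple <- function(r, c) {
    fg <- NULL
    for (k in 1:8) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      if (rr >= 1L && cc >= 1L && rr <= n1 && cc <= n2 && m[rr, cc] == 1L)
        fg <- rbind(fg, c(rr, cc))
    }
    nf <- if (is.null(fg)) 0L else nrow(fg)
    if (nf < 2L) return(FALSE)  # endpoint or isolated: keep
    # components of the neighbors under 8-adjacency, excluding the pixel
    lab <- seq_len(nf)
    repeat {
      merged <- FALSE
      for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) {
        if (lab[i] != lab[j] &&
            max(abs(fg[i, ] - fg[j, ])) <= 1L) {
          lab[lab == lab[j]] <- lab[i]
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    length(unique(lab)) == 1L
  }
  repeat {
    if (n1 < 2L || n2 < 2L) break
    blk <- m[-n1, -n2] & m[-1L, -n2] & m[-n1, -1L] & m[-1L, -1L]
    if (!any(blk)) break
    idx <- which(blk, arr.ind = TRUE)
    removed <- FALSE
    for (k in seq_len(nrow(idx))) {
      for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- idx[k, 1L] + off[1L]; c <- idx[k, 2L] + off[2L]
        if (m[r, c] == 0L) next
        if (locally_simple(r, c)) {
          m[r, c] <- 0L
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }
  m
}

#' Vessel density and perfusion density of a mask
#'
#' Perfusion density (PD) is the foreground fraction of the mask; vessel
#' density (VD) is the foreground fraction of its 1-px skeleton
#' ([skeletonize()]), making VD independent of segmented vessel width.
#'
#' @param m a `vessel_mask` or binary matrix.
#' @return list with `perfusion_density`, `vessel_density` and the
#'   `skeleton_mask` used.
#' @export
vessel_density <- function(m) {
  px <- if (inherits(m, "vessel_mask")) m$pixels else m
  if (length(px) == 0L) stop("empty mask")
  sk <- skeletonize(m)
  list(
    perfusion_density = sum(px != 0L) / length(px),
    vessel_density = sum(sk$pixels) / length(px),
    skeleton = sk
  )
}
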