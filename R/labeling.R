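## Imaging primitives shared by the renderer checks and the quantifier.

## Otsu threshold on 8-bit gray values (0..255). Returns the threshold on
## the same scale; foreground-vs-background assignment is the caller's
## choice of side.
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_arg("cannot threshold an empty pixel set")
  if (diff(range(v)) < .Machine$double.eps) {
    ## constant input: no split exists; return a threshold below the value
    ## so that `x < threshold` selects nothing
    return(v[1] - 0.5)
  }
  img <- EBImage::Image(matrix(v / 255, nrow = length(v)))
  255 * EBImage::otsu(img, range = c(0, 1), levels = 256L)
}

## Shifted copy of a matrix: out[r, c] = m[r + dr, c + dc], zero-padded.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

## Fast connected-component labelling for solid regions (nucleus masks),
## delegating to EBImage's C implementation. EBImage labels with
## 4-connectivity, which is equivalent to 8-connectivity for filled
## elliptical blobs; dot counting, where diagonal adjacency matters, uses
## label_components() below instead.
label_components_solid <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)), n = 0L,
                sizes = integer(0)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  list(labels = lab, n = n, sizes = tabulate(lab[lab > 0L], nbins = n))
}

## Connected-component labelling of a logical mask with 4- or 8-connectivity
## (EBImage's labeller is 4-connected only; the fused-dot counting rule
## requires 8-connectivity, so diagonal-touching dots merge). Iterative
## minimum-label propagation; components here are small, so convergence is
## quick. Returns a list with the label matrix (0 = background), the number
## of components and their pixel sizes in label order.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(list(labels = lab, n = 0L, sizes = integer(0)))
  lab[mask] <- which(mask)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift_mat(new, s[1], s[2])
      upd <- mask & nb > 0L & nb < new
      if (any(upd)) new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  list(labels = lab, n = length(ids),
       sizes = tabulate(lab[mask], nbins = length(ids)))
}
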