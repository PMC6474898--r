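# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fadseed <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fadseed_error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fadseed(sprintf("`%s` must be a single finite number", name),
                 "fadseed_invalid_params")
  }
  if (x < min || x > max) {
    stop_fadseed(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x),
                 "fadseed_invalid_params")
  }
  invisible(x)
}

# Otsu's threshold on a numeric vector in [0, 1].  Maximizes between-class
# variance over a fixed histogram; returns the lower edge of the first bin
# of the upper class, so `v <= thr` selects the dark class.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_fadseed("no finite values for thresholding",
                                    "fadseed_invalid_input")
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(pmin(pmax(v, 0), 1), breaks,
                             rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  breaks[k + 1L]
}

# 8-connected component labeling of a logical matrix.  EBImage::bwlabel is
# 4-connected, so diagonally touching labels are merged with a union-find
# pass over label adjacencies.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs (down-right and down-left shifts)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]
  keep <- a > 0L & b > 0L & a != b
  if (any(keep)) mapply(union_, a[keep], b[keep])
  a <- lab[-nr, -1L]; b <- lab[-1L, -nc]
  keep <- a > 0L & b > 0L & a != b
  if (any(keep)) mapply(union_, a[keep], b[keep])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Disc-shaped structuring element with odd side 2*radius + 1.
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
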