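# internal geometry / RNG helpers

# minimum-image displacement components for an orthorhombic box
min_image <- function(d, box_len) d - box_len * round(d / box_len)

# minimum-image distance matrix between two coordinate sets (n x 3, m x 3)
min_image_dist <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# small deterministic integer hash for deriving per-slice seeds
mix_seed <- function(seed, ...) {
  v <- c(seed, ...)
  h <- 0
  for (x in v) h <- (h * 31 + as.numeric(x)) %% 2147483647
  as.integer(h)
}

# centered running mean, width w samples (odd); edges use shrunken windows
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# rotation matrix about a unit axis by angle (degrees)
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (a %o% a)
}

# centre of mass (unweighted mean) of selected rows of an n x 3 matrix
com <- function(pos, idx = NULL) {
  if (!is.null(idx)) pos <- pos[idx, , drop = FALSE]
  colMeans(pos)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
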