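# internal geometry / rng / chemistry tables

# monoisotopic-ish average atomic masses (Da) for the elements the package handles
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

.HETERO <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")

#' @noRd
.elementMass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# Kabsch least-squares superposition: rotation + translation mapping
# `from` (n x 3) onto `to` (n x 3). Returns list(R, t) with x %*% R + t.
.kabsch <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3L)
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = ct - drop(cf %*% R))
}

.applyTransform <- function(coords, tf) {
  sweep(coords %*% tf$R, 2, tf$t, `+`)
}

# random rigid transform (for property tests and generators)
.randomRotation <- function() {
  # QR of a Gaussian matrix gives a Haar-ish rotation; force det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rodrigues rotation of points about an axis through `origin`
.rotateAboutAxis <- function(coords, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(coords, 2, origin)
  cosa <- cos(angle); sina <- sin(angle)
  rot <- p * cosa +
    t(apply(p, 1L, function(v) pracma::cross(u, v))) * sina +
    outer(drop(p %*% u) * (1 - cosa), u)
  sweep(rot, 2, origin, `+`)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Seed derivation: one independent substream per (seed, key) pair so that
# adding a generator call never reshuffles another generator's draws.
.deriveSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147480017
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147480017)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic polynomial string hash into [0, nbits)
.stringHash <- function(s, nbits) {
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1048573
  as.integer(h %% nbits) + 1L
}

# best-fit plane normal of a point set (unit vector)
.planeNormal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  s <- svd(c0)
  .unit(s$v[, 3])
}

.angleBetween <- function(u, v) {
  cu <- .unit(u); cv <- .unit(v)
  acos(pmin(1, pmax(-1, sum(cu * cv)))) * 180 / pi
}
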