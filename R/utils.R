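# Small shared helpers: deterministic seed streams and 3D geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component-specific RNG seed from a master seed
#'
#' Stable polynomial string hash of the component name mixed with the master
#' seed, reduced modulo 2^31 - 1 so the result is always a valid R integer
#' seed. Adding new components never perturbs the streams of existing ones.
#'
#' @param seed master integer seed.
#' @param component character label of the consuming component.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "msa") != derive_seed(1, "helix")
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(component)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vunit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Bond angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Natural-extension (NeRF) placement: position atom D bonded to c with the
# given bond length, angle at c (b-c-D, degrees) and dihedral a-b-c-D
# (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  d_local <- bond * c(-cos(theta), sin(theta) * cos(chi), -sin(theta) * sin(chi))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d_local + c)
}

# Random proper rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
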