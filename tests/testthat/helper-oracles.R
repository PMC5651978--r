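# Independent oracles used by the geometry and force tests. These share no
# code with the package internals: crossings are located by dense boundary
# sampling plus stats::uniroot, and the two-body collision is integrated by
# classical RK4 in R.

oracle_implicit <- function(s, p) {
  co <- cos(s$orientation); sn <- sin(s$orientation)
  dx <- p[1] - s$center[1]; dy <- p[2] - s$center[2]
  ((dx * co + dy * sn) / s$a)^2 + ((-dx * sn + dy * co) / s$b)^2 - 1
}

oracle_boundary <- function(s, t) {
  co <- cos(s$orientation); sn <- sin(s$orientation)
  bx <- s$a * cos(t); by <- s$b * sin(t)
  c(s$center[1] + bx * co - by * sn, s$center[2] + bx * sn + by * co)
}

# both parameters of the intersection of the line m + x*u with the ellipse
# boundary (quadratic in the body frame), NULL if the line misses it
oracle_line_hits <- function(s, m, u) {
  co <- cos(s$orientation); sn <- sin(s$orientation)
  d <- m - s$center
  q <- c((d[1] * co + d[2] * sn) / s$a, (-d[1] * sn + d[2] * co) / s$b)
  e <- c((u[1] * co + u[2] * sn) / s$a, (-u[1] * sn + u[2] * co) / s$b)
  A <- sum(e^2); B <- 2 * sum(q * e); C <- sum(q^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
}

# brute-force penetration oracle: dense parametric sampling of boundary i,
# sign-change + uniroot refinement against the implicit form of j, then the
# chord/mid-normal overlap extent. Returns list(found, delta, normal) with
# the normal pointing from sj toward si.
oracle_ellipse_overlap <- function(si, sj, n_samp = 2048) {
  f <- function(t) oracle_implicit(sj, oracle_boundary(si, t))
  ts <- seq(0, 2 * pi, length.out = n_samp + 1)
  g <- vapply(ts, f, 0)
  roots <- numeric(0)
  for (k in seq_len(n_samp)) {
    if ((g[k] < 0) != (g[k + 1] < 0))
      roots <- c(roots, uniroot(f, c(ts[k], ts[k + 1]), tol = 1e-15)$root)
  }
  if (length(roots) == 0) {
    # a grazing lens can dip below zero between samples; refine the local
    # minimum and split it into two roots — only meaningful when the
    # bracket endpoints are outside (positive), not when the whole
    # boundary lies inside the other ellipse
    km <- which.min(g[seq_len(n_samp)])
    lo <- ts[max(1, km - 1)]; hi <- ts[min(n_samp + 1, km + 1)]
    op <- optimize(f, c(lo, hi), tol = 1e-15)
    if (op$objective < 0 && f(lo) > 0 && f(hi) > 0)
      roots <- c(uniroot(f, c(lo, op$minimum), tol = 1e-15)$root,
                 uniroot(f, c(op$minimum, hi), tol = 1e-15)$root)
  }
  dc <- si$center - sj$center
  if (length(roots) >= 2) {
    pts <- t(vapply(roots, function(t) oracle_boundary(si, t), c(0, 0)))
    dd <- as.matrix(dist(pts))
    ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    p1 <- pts[ij[1], ]; p2 <- pts[ij[2], ]
    if (sum((p1 - p2)^2) < 1e-24) return(list(found = FALSE))
    m <- (p1 + p2) / 2
    ch <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    n <- c(-ch[2], ch[1])
    orient <- sum(n * dc)
    if (abs(orient) < 1e-14) {
      h <- 1e-7
      if (oracle_implicit(sj, m + h * n) < oracle_implicit(sj, m - h * n))
        n <- -n
    } else if (orient < 0) n <- -n
    hi_i <- oracle_line_hits(si, m, n); hi_j <- oracle_line_hits(sj, m, n)
    if (is.null(hi_i) || is.null(hi_j)) return(list(found = FALSE))
    delta <- min(hi_i[2], hi_j[2]) - max(hi_i[1], hi_j[1])
    if (delta <= 0) return(list(found = FALSE))
    return(list(found = TRUE, delta = delta, normal = n))
  }
  inside <- oracle_implicit(sj, si$center) < 0 ||
    oracle_implicit(si, sj$center) < 0
  if (!inside) return(list(found = FALSE))
  d <- sqrt(sum(dc^2))
  u <- dc / d
  hi_i <- oracle_line_hits(si, sj$center, u)
  hi_j <- oracle_line_hits(sj, sj$center, u)
  delta <- min(hi_i[2], hi_j[2]) - max(hi_i[1], hi_j[1])
  list(found = delta > 0, delta = delta, normal = u)
}

# maximal penetration of a sampled ellipse boundary past a wall line
# (signed distance against the inward normal), refined by optimize
oracle_wall_penetration <- function(s, p1, n, n_samp = 4096) {
  pen <- function(t) {
    p <- oracle_boundary(s, t)
    -sum((p - p1) * n)
  }
  ts <- seq(0, 2 * pi, length.out = n_samp)
  vals <- vapply(ts, pen, 0)
  km <- which.max(vals)
  op <- optimize(pen, c(ts[max(1, km - 1)], ts[min(n_samp, km + 1)]),
                 maximum = TRUE, tol = 1e-15)
  max(op$objective, vals[km])
}

# RK4 integration of a head-on two-body collision of equal circles with the
# linear spring-dashpot law; returns the measured restitution ratio
oracle_restitution <- function(e, m = 0.030, k = 5e4, r = 0.03, v0 = 0.2,
                               dt = 1e-7) {
  meff <- m / 2
  eta <- 2 * (-log(e)) * sqrt(meff * k) / sqrt(pi^2 + log(e)^2)
  # integrate overlap q and its rate qd: meff q'' = -k q - eta q' while q > 0
  q <- 0; qd <- 2 * v0  # closing speed, starting just at touch
  repeat {
    acc <- function(q, qd) (-k * q - eta * qd) / meff
    k1q <- qd;                k1v <- acc(q, qd)
    k2q <- qd + dt / 2 * k1v; k2v <- acc(q + dt / 2 * k1q, qd + dt / 2 * k1v)
    k3q <- qd + dt / 2 * k2v; k3v <- acc(q + dt / 2 * k2q, qd + dt / 2 * k2v)
    k4q <- qd + dt * k3v;     k4v <- acc(q + dt * k3q, qd + dt * k3v)
    q <- q + dt / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
    qd <- qd + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (q <= 0) break
  }
  abs(qd) / (2 * v0)
}

random_ellipse_pair <- function() {
  a1 <- runif(1, 0.02, 0.05); b1 <- runif(1, 0.3, 1) * a1
  a2 <- runif(1, 0.02, 0.05); b2 <- runif(1, 0.3, 1) * a2
  d <- runif(1, 0.2, 1.1) * (a1 + a2)
  ang <- runif(1, 0, 2 * pi)
  list(ellipse_shape(c(0, 0), runif(1, 0, pi), a1, b1),
       ellipse_shape(d * c(cos(ang), sin(ang)), runif(1, 0, pi), a2, b2))
}
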