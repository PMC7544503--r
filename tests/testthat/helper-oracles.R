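# independent oracles, deliberately sharing no code with the implementation

# circumsphere of 4 points via a direct 3x3 solve
oracle_circumsphere <- function(v) {
  A <- 2 * sweep(v[2:4, , drop = FALSE], 2, v[1, ])
  b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
  if (abs(det(A)) < 1e-12) return(NULL)
  ctr <- solve(A, b)
  list(center = ctr, r2 = sum((v[1, ] - ctr)^2))
}

# brute-force Delaunay edge oracle: (a, b) is an edge iff some 4-subset
# containing a and b has an empty circumsphere (exact in general position)
oracle_delaunay_edges <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  rng <- max(apply(pts, 2, function(v) diff(range(v))))
  out <- NULL
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    others <- setdiff(1:n, c(a, b))
    found <- n == 4L
    if (!found) {
      for (ci in seq_along(others)) {
        for (di in seq_len(ci - 1L)) {
          cs <- oracle_circumsphere(pts[c(a, b, others[ci], others[di]), ])
          if (is.null(cs)) next
          d2 <- rowSums(sweep(pts, 2, cs$center)^2)
          inside <- d2 < cs$r2 - tol * rng^2
          inside[c(a, b, others[ci], others[di])] <- FALSE
          if (!any(inside)) { found <- TRUE; break }
        }
        if (found) break
      }
    }
    if (found) out <- rbind(out, c(a, b))
  }
  out
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

# textbook pooled-variance Student t (independent, two-sided)
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p_two = 2 * stats::pt(-abs(tt), df))
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tt, df = n - 1, p_two = 2 * stats::pt(-abs(tt), n - 1))
}
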