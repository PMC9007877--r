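## Independent oracles used across test files. Each deliberately uses a
## different computational route than the implementation it checks.

## Haralick measurements by explicit double loops over matrix entries.
oracle_haralick <- function(p) {
  G <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:G) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  l2 <- function(v) if (v > 0) log2(v) else 0
  asm <- 0; con <- 0; cor0 <- 0; ssq <- 0; idm <- 0; ent <- 0
  hxy1 <- 0; hxy2 <- 0
  psum <- rep(0, 2 * G); pdif <- rep(0, G)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + v * (i - j)^2
    cor0 <- cor0 + i * j * v
    ssq <- ssq + v * (i - mux)^2
    idm <- idm + v / (1 + (i - j)^2)
    ent <- ent - v * l2(v)
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
    if (v > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - v * l2(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  corr <- if (sx < 1e-12 || sy < 1e-12) 0 else (cor0 - mux * muy) / (sx * sy)
  sa <- 0; for (k in 2:(2 * G)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * G)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * G)) se <- se - psum[k] * l2(psum[k])
  mud <- 0; for (k in 0:(G - 1)) mud <- mud + k * pdif[k + 1]
  dv <- 0; for (k in 0:(G - 1)) dv <- dv + (k - mud)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(G - 1)) de <- de - pdif[k + 1] * l2(pdif[k + 1])
  hx <- 0; for (i in 1:G) hx <- hx - px[i] * l2(px[i])
  hy <- 0; for (j in 1:G) hy <- hy - py[j] * l2(py[j])
  imc1 <- if (max(hx, hy) < 1e-12) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm = asm, contrast = con, correlation = corr,
    sum_squares_variance = ssq, inv_diff_moment = idm, sum_average = sa,
    sum_variance = sv, sum_entropy = se, entropy = ent,
    diff_variance = dv, diff_entropy = de, imc1 = imc1, imc2 = imc2)
}

## random symmetric normalized co-occurrence matrix
random_cm <- function(G = 8) {
  m <- matrix(runif(G * G), G, G)
  m <- m + t(m)
  m / sum(m)
}

## Delaunay by brute-force empty-circumcircle enumeration over all triples
## (general position assumed).
brute_delaunay <- function(xy) {
  n <- nrow(xy)
  tris <- list()
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    A <- xy[a, ]; B <- xy[b, ]; C <- xy[cc, ]
    d <- 2 * (A[1] * (B[2] - C[2]) + B[1] * (C[2] - A[2]) +
              C[1] * (A[2] - B[2]))
    if (abs(d) < 1e-12) next
    a2 <- sum(A^2); b2 <- sum(B^2); c2 <- sum(C^2)
    ux <- (a2 * (B[2] - C[2]) + b2 * (C[2] - A[2]) + c2 * (A[2] - B[2])) / d
    uy <- (a2 * (C[1] - B[1]) + b2 * (A[1] - C[1]) + c2 * (B[1] - A[1])) / d
    r2 <- (A[1] - ux)^2 + (A[2] - uy)^2
    empty <- TRUE
    for (k in seq_len(n)) {
      if (k %in% c(a, b, cc)) next
      if ((xy[k, 1] - ux)^2 + (xy[k, 2] - uy)^2 < r2 * (1 - 1e-12)) {
        empty <- FALSE
        break
      }
    }
    if (empty) tris[[length(tris) + 1L]] <- c(a, b, cc)
  }
  if (!length(tris)) return(matrix(integer(0), 0, 3))
  do.call(rbind, tris)
}

tri_key <- function(tris) {
  if (!nrow(tris)) return(character(0))
  sort(apply(tris, 1, function(tt) paste(sort(tt), collapse = "-")))
}

## Exact two-sided Wilcoxon rank-sum p by enumerating all label
## assignments (no ties assumed).
oracle_wrst_exact <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  combs <- combn(length(pool), n1)
  us <- apply(combs, 2, function(idx) {
    rk <- rank(pool)
    sum(rk[idx]) - n1 * (n1 + 1) / 2
  })
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Product-limit survival by the direct formula at each event time.
oracle_km_surv <- function(time, event, at) {
  ev <- sort(unique(time[event == 1]))
  ev <- ev[ev <= at]
  s <- 1
  for (t in ev) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <- s * (1 - d / n)
  }
  s
}

## Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  ex <- si * sj / n
  (sij - ex) / ((si + sj) / 2 - ex)
}
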